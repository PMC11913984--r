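#' Assign a polygenic correlated trait architecture
#'
#' Samples `n_qtl` QTL without replacement from the map markers and draws
#' each QTL's row of additive allele-substitution effects from a
#' multivariate normal distribution with covariance proportional to
#' `target_genetic_corr`. Effect columns are then rescaled so that the
#' expected standard deviation of true breeding values in the founder
#' population (under linkage equilibrium and Hardy-Weinberg proportions,
#' `Var = sum_q 2 p_q (1 - p_q) e_q^2`) equals `trait_sds`.
#'
#' The default four traits emulate early plant height at two growth stages
#' (highly correlated), final plant height (intermediate correlation with
#' the early stages) and female flowering (uncorrelated).
#'
#' @param map A `genetic_map`.
#' @param n_qtl Number of QTL (<= number of markers).
#' @param target_genetic_corr Symmetric positive semi-definite correlation
#'   matrix (unit diagonal), one row/column per trait.
#' @param trait_sds Named numeric vector of target founder-population
#'   true-breeding-value standard deviations (trait units).
#' @param founder_freqs Per-marker allele frequencies of the founder
#'   population used for effect scaling (e.g. `allele_freqs(founders)`).
#' @param seed Integer seed.
#' @return Object of class `trait_architecture`: list with `trait_names`,
#'   `qtl_markers` (ids), `qtl_index` (column positions in the map),
#'   `effects` (QTL x traits matrix), `target_genetic_corr`.
#' @export
assign_architecture <- function(map, n_qtl, target_genetic_corr,
                                trait_sds, founder_freqs, seed = 1L) {
  m <- n_markers(map)
  stopifnot(n_qtl >= 1, n_qtl <= m, length(founder_freqs) == m)
  target_genetic_corr <- as.matrix(target_genetic_corr)
  t_n <- ncol(target_genetic_corr)
  stopifnot(nrow(target_genetic_corr) == t_n, length(trait_sds) == t_n)
  if (max(abs(target_genetic_corr - t(target_genetic_corr))) > 1e-10 ||
      max(abs(diag(target_genetic_corr) - 1)) > 1e-10) {
    stop("target_genetic_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(target_genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target_genetic_corr must be positive semi-definite")

  set.seed(seed)
  qtl_index <- sort(sample.int(m, n_qtl))
  # MVN draw via eigen square root (allows PSD, not just PD, targets)
  es <- eigen(target_genetic_corr, symmetric = TRUE)
  sqrt_c <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), t_n) %*% t(es$vectors)
  eff <- matrix(stats::rnorm(n_qtl * t_n), n_qtl, t_n) %*% sqrt_c
  # scale each trait column so expected founder TBV SD matches trait_sds
  w <- 2 * founder_freqs[qtl_index] * (1 - founder_freqs[qtl_index])
  for (tt in seq_len(t_n)) {
    sd0 <- sqrt(sum(w * eff[, tt]^2))
    if (sd0 > 0) eff[, tt] <- eff[, tt] * trait_sds[tt] / sd0
  }
  trait_names <- names(trait_sds)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(t_n))
  colnames(eff) <- trait_names
  out <- list(trait_names = trait_names,
              qtl_markers = map$markers$marker[qtl_index],
              qtl_index = qtl_index,
              effects = eff,
              target_genetic_corr = target_genetic_corr)
  class(out) <- "trait_architecture"
  out
}

#' Default trait architecture settings
#'
#' Four traits: early plant height at stages V4 and V6 (`PH_V4`, `PH_V6`,
#' cm), final plant height (`PH`, cm) and female flowering (`FF`, days).
#' The early-height pair is highly correlated (0.8), their correlation
#' with final height is intermediate (0.35) and flowering is uncorrelated.
#' Trait SDs are on the order of magnitude of landrace-derived DH
#' populations (a few cm for early height, ~12 cm final height, ~3 days
#' flowering).
#'
#' @return List with `target_corr` and `trait_sds`.
#' @export
default_traits <- function() {
  nm <- c("PH_V4", "PH_V6", "PH", "FF")
  corr <- diag(4)
  dimnames(corr) <- list(nm, nm)
  corr["PH_V4", "PH_V6"] <- corr["PH_V6", "PH_V4"] <- 0.8
  corr["PH_V4", "PH"] <- corr["PH", "PH_V4"] <- 0.35
  corr["PH_V6", "PH"] <- corr["PH", "PH_V6"] <- 0.35
  list(target_corr = corr,
       trait_sds = c(PH_V4 = 4, PH_V6 = 6, PH = 12, FF = 3))
}

#' True breeding values
#'
#' Additive model only: `TBV_it = sum_q g_iq * e_qt` with `g` the 0/1/2
#' alternate-allele count at QTL `q`.
#'
#' @param pop An `rg_pop` (or a 0/1/2 genotype matrix covering all QTL
#'   columns of the map).
#' @param arch A `trait_architecture`.
#' @return Numeric matrix (individuals x traits).
#' @export
true_breeding_values <- function(pop, arch) {
  g <- if (inherits(pop, "rg_pop")) genotypes(pop) else pop
  if (ncol(g) < max(arch$qtl_index)) stop("missing QTL genotypes")
  gq <- g[, arch$qtl_index, drop = FALSE]
  if (anyNA(gq)) stop("missing QTL genotypes")
  tbv <- gq %*% arch$effects
  rownames(tbv) <- rownames(g)
  tbv
}
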