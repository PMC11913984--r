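#' Construct a multi-environment trial design
#'
#' Alpha-lattice-like layout: in each environment x replication, the
#' entries are randomized into incomplete blocks of `block_size` plots.
#'
#' @param entries Character vector of genotype ids (including checks).
#' @param n_env Number of environments (location x year combinations).
#' @param n_rep Replications per environment.
#' @param block_size Plots per incomplete block (>= 2, default 10).
#' @return Object of class `trial_design`: list with `entries`,
#'   `environments`, `n_rep`, `block_size`.
#' @export
make_trial_design <- function(entries, n_env = 7L, n_rep = 2L,
                              block_size = 10L) {
  stopifnot(length(entries) >= 1, n_env >= 1, n_rep >= 1, block_size >= 2)
  structure(list(entries = as.character(entries),
                 environments = sprintf("env%02d", seq_len(n_env)),
                 n_rep = n_rep, block_size = block_size),
            class = "trial_design")
}

#' Nuisance variance components targeting an entry-mean heritability
#'
#' Given a genetic variance, returns genotype-by-environment and residual
#' variances such that `h2 = s2_g / (s2_g + s2_gxe/E + s2_e/(E R))`
#' equals the target, with `s2_gxe = ratio * s2_e` (default: G x E half
#' the residual). Environment, replication and block variances do not
#' enter the entry-mean heritability and are set relative to `s2_g`.
#'
#' @param sigma2_g Genetic variance.
#' @param h2 Target entry-mean heritability in (0, 1).
#' @param n_env,n_rep Design dimensions E and R.
#' @param ratio `s2_gxe / s2_e`.
#' @return Named vector: sigma2_env, sigma2_gxe, sigma2_rep, sigma2_block,
#'   sigma2_error.
#' @export
variance_for_h2 <- function(sigma2_g, h2, n_env = 7L, n_rep = 2L,
                            ratio = 0.5) {
  stopifnot(h2 > 0, h2 < 1)
  # s2_g (1 - h2)/h2 = s2_gxe/E + s2_e/(E R); s2_gxe = ratio * s2_e
  denom_units <- ratio / n_env + 1 / (n_env * n_rep)
  s2_e <- sigma2_g * (1 - h2) / h2 / denom_units
  c(sigma2_env = 2 * sigma2_g, sigma2_gxe = ratio * s2_e,
    sigma2_rep = 0.25 * sigma2_g, sigma2_block = 0.25 * sigma2_g,
    sigma2_error = s2_e)
}

#' Simulate plot-level multi-environment phenotypes
#'
#' Plot value = TBV + environment + G x E + replication + block +
#' residual, per trait. A fraction `outlier_rate` of plots has its
#' residual inflated tenfold (gross errors for the outlier filter to
#' find), and each plot carries a simulated plant count
#' (Binomial(20, 0.9), mirroring sowing of 20 kernels) so the
#' "at least five uniform plants" filter is exercisable.
#'
#' @param tbv Matrix of true breeding values (entries x traits), rows
#'   named by genotype id covering all design entries.
#' @param populations Named character vector mapping genotype id to
#'   population label (defaults to a single population).
#' @param design A `trial_design`.
#' @param variance_config Either a named vector (shared across traits) or
#'   a matrix/data.frame with one row per trait and columns `sigma2_env`,
#'   `sigma2_gxe`, `sigma2_rep`, `sigma2_block`, `sigma2_error`.
#' @param outlier_rate Fraction of plots receiving a tenfold-inflated
#'   residual (default 0).
#' @param seed Integer seed.
#' @return data.frame of plot records: genotype, population, environment,
#'   replication, block, plant_count, then one column per trait.
#' @export
simulate_trial <- function(tbv, populations = NULL, design,
                           variance_config, outlier_rate = 0,
                           seed = 1L) {
  tbv <- as.matrix(tbv)
  traits <- colnames(tbv)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(tbv)))
  entries <- design$entries
  if (length(entries) == 0) stop("empty design")
  if (!all(entries %in% rownames(tbv))) {
    stop("every design entry must be genotyped (have a TBV row)")
  }
  if (is.null(populations)) {
    populations <- stats::setNames(rep("pop", length(entries)), entries)
  }
  vc <- variance_config
  if (is.null(dim(vc))) {
    vc <- matrix(rep(as.numeric(vc[c("sigma2_env", "sigma2_gxe",
                                     "sigma2_rep", "sigma2_block",
                                     "sigma2_error")]),
                     each = length(traits)),
                 nrow = length(traits),
                 dimnames = list(traits, c("sigma2_env", "sigma2_gxe",
                                           "sigma2_rep", "sigma2_block",
                                           "sigma2_error")))
  } else {
    vc <- as.matrix(vc)[traits, , drop = FALSE]
  }
  if (any(vc < 0)) stop("variance components must be non-negative")

  set.seed(seed)
  n_g <- length(entries)
  envs <- design$environments
  n_env <- length(envs)
  n_rep <- design$n_rep
  n_blocks <- ceiling(n_g / design$block_size)

  recs <- vector("list", n_env * n_rep)
  k <- 0L
  # trait-level random effects shared across plots
  env_eff <- vapply(traits, function(tt)
    stats::rnorm(n_env, 0, sqrt(vc[tt, "sigma2_env"])),
    numeric(n_env))
  env_eff <- matrix(env_eff, nrow = n_env,
                    dimnames = list(envs, traits))
  gxe_eff <- lapply(traits, function(tt)
    matrix(stats::rnorm(n_g * n_env, 0, sqrt(vc[tt, "sigma2_gxe"])),
           n_g, n_env, dimnames = list(entries, envs)))
  names(gxe_eff) <- traits
  for (e in seq_len(n_env)) {
    for (r in seq_len(n_rep)) {
      ord <- sample.int(n_g)
      block <- rep(seq_len(n_blocks), each = design$block_size)[
        seq_len(n_g)]
      rep_eff <- sapply(traits, function(tt)
        stats::rnorm(1, 0, sqrt(vc[tt, "sigma2_rep"])))
      blk_eff <- vapply(traits, function(tt)
        stats::rnorm(n_blocks, 0, sqrt(vc[tt, "sigma2_block"])),
        numeric(n_blocks))
      blk_eff <- matrix(blk_eff, nrow = n_blocks,
                        dimnames = list(NULL, traits))
      g_idx <- ord
      df <- data.frame(
        genotype = entries[g_idx],
        population = unname(populations[entries[g_idx]]),
        environment = envs[e],
        replication = paste0("rep", r),
        block = sprintf("%s_rep%d_b%02d", envs[e], r, block),
        plant_count = stats::rbinom(n_g, 20L, 0.9),
        stringsAsFactors = FALSE
      )
      for (tt in traits) {
        res_sd <- sqrt(vc[tt, "sigma2_error"])
        res <- stats::rnorm(n_g, 0, res_sd)
        if (outlier_rate > 0) {
          out_i <- stats::runif(n_g) < outlier_rate
          res[out_i] <- res[out_i] * 10
        }
        df[[tt]] <- tbv[entries[g_idx], tt] + env_eff[e, tt] +
          gxe_eff[[tt]][cbind(g_idx, e)] + rep_eff[tt] +
          blk_eff[block, tt] + res
      }
      k <- k + 1L
      recs[[k]] <- df
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "traits") <- traits
  out
}
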