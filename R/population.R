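#' Population container
#'
#' A population is stored as two phased haplotype matrices (individuals x
#' markers, 0/1 integer counts of the alternate allele) plus a pedigree
#' table. Founders have `NA` parents; doubled-haploid (DH) individuals
#' carry two identical haplotypes. The `founders` column tracks, for every
#' individual, the set of base-cycle founder ancestors (semicolon-joined
#' ids) used by contribution caps during selection.
#'
#' @param h1,h2 Integer matrices (n x m) of phased haplotypes.
#' @param info data.frame with columns `id`, `mother`, `father`, `stage`,
#'   `population`, `family`, `founders`.
#' @param map A `genetic_map` the haplotypes are indexed by.
#' @return An object of class `rg_pop`.
#' @export
new_population <- function(h1, h2, info, map) {
  stopifnot(is.matrix(h1), is.matrix(h2),
            all(dim(h1) == dim(h2)),
            nrow(h1) == nrow(info),
            ncol(h1) == n_markers(map))
  stopifnot(all(c("id", "mother", "father", "stage", "population",
                  "family", "founders") %in% names(info)))
  if (anyDuplicated(info$id)) stop("individual ids must be unique")
  rownames(h1) <- rownames(h2) <- info$id
  structure(list(h1 = h1, h2 = h2, info = info, map = map),
            class = "rg_pop")
}

#' @export
print.rg_pop <- function(x, ...) {
  cat(sprintf("<population> %d individuals x %d markers; stages: %s\n",
              nrow(x$info), ncol(x$h1),
              paste(unique(x$info$stage), collapse = ", ")))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop An `rg_pop`.
#' @export
pop_size <- function(pop) nrow(pop$info)

#' Genotype matrix of a population
#'
#' @param pop An `rg_pop`.
#' @return Integer matrix (n x m) of alternate-allele counts in 0/1/2
#'   coding, rows named by individual id, columns by marker id.
#' @export
genotypes <- function(pop) {
  g <- pop$h1 + pop$h2
  colnames(g) <- pop$map$markers$marker
  g
}

#' Alternate-allele frequencies of a population
#' @param pop An `rg_pop`.
#' @return Numeric vector of length m (mean allele count / 2).
#' @export
allele_freqs <- function(pop) {
  p <- colMeans(pop$h1 + pop$h2) / 2
  names(p) <- pop$map$markers$marker
  p
}

#' Subset a population by individual index or id
#' @param pop An `rg_pop`.
#' @param i Integer indices or character ids.
#' @export
subset_population <- function(pop, i) {
  if (is.character(i)) i <- match(i, pop$info$id)
  if (anyNA(i)) stop("unknown individual id in subset")
  new_population(pop$h1[i, , drop = FALSE], pop$h2[i, , drop = FALSE],
                 pop$info[i, , drop = FALSE], pop$map)
}

#' Combine populations sharing a map
#' @param ... `rg_pop` objects on the identical map.
#' @export
bind_populations <- function(...) {
  pops <- list(...)
  stopifnot(length(pops) >= 1)
  new_population(do.call(rbind, lapply(pops, `[[`, "h1")),
                 do.call(rbind, lapply(pops, `[[`, "h2")),
                 do.call(rbind, lapply(pops, `[[`, "info")),
                 pops[[1]]$map)
}

pop_info_frame <- function(ids, mother = NA_character_,
                           father = NA_character_, stage, population,
                           family = NA_character_, founders) {
  data.frame(id = ids, mother = mother, father = father, stage = stage,
             population = population, family = family, founders = founders,
             stringsAsFactors = FALSE)
}

#' Simulate a panmictic heterozygous founder population
#'
#' Emulates open-pollinated landrace S0 plants: a per-marker alternate
#' allele frequency is drawn from a Beta(a, b) distribution truncated to
#' \[0.05, 0.95\] (so no marker is near-monomorphic), and haplotypes are
#' drawn independently per individual under linkage equilibrium and
#' Hardy-Weinberg proportions. By default no ancestral linkage
#' disequilibrium is simulated (LD subsequently arises through selection
#' and mating); the `ancestral` option instead descends the founders
#' from a small random-mating pool, which creates ancestral LD.
#'
#' @param map A `genetic_map`.
#' @param n Number of S0 plants (>= 2).
#' @param maf_beta Length-2 numeric `(a, b)` of the Beta distribution for
#'   allele frequencies; both must be positive and finite.
#' @param seed Integer seed.
#' @param ancestral Optional list `(n_pool, n_gen)`: instead of linkage
#'   equilibrium, founders descend from a small ancestral pool of
#'   `n_pool` LE individuals through `n_gen` generations of random
#'   mating, which builds up ancestral linkage disequilibrium. Default
#'   `NULL` (off) for testability.
#' @return An `rg_pop` of heterozygous S0 founders with attribute
#'   `"freqs"` holding the sampled per-marker allele frequencies.
#' @export
simulate_founders <- function(map, n, maf_beta = c(1, 1), seed = 1L,
                              ancestral = NULL) {
  stopifnot(n >= 2, length(maf_beta) == 2)
  if (any(!is.finite(maf_beta)) || any(maf_beta <= 0)) {
    stop("degenerate Beta parameters: both must be positive and finite")
  }
  m <- n_markers(map)
  set.seed(seed)
  p <- stats::rbeta(m, maf_beta[1], maf_beta[2])
  p <- pmin(pmax(p, 0.05), 0.95)
  h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  if (!is.null(ancestral)) {
    n_pool <- ancestral$n_pool
    n_gen <- ancestral$n_gen
    stopifnot(n_pool >= 2, n_gen >= 1)
    # ancestral pool under LE, then random mating builds up LD
    pool_h1 <- matrix(stats::rbinom(n_pool * m, 1L, rep(p, each = n_pool)),
                      n_pool, m)
    pool_h2 <- matrix(stats::rbinom(n_pool * m, 1L, rep(p, each = n_pool)),
                      n_pool, m)
    storage.mode(pool_h1) <- "integer"
    storage.mode(pool_h2) <- "integer"
    ci <- map_chrom_index(map)
    for (g in seq_len(n_gen)) {
      n_next <- if (g == n_gen) n else n_pool
      nh1 <- matrix(0L, n_next, m)
      nh2 <- matrix(0L, n_next, m)
      for (k in seq_len(n_next)) {
        par <- sample.int(nrow(pool_h1), 2L, replace = FALSE)
        nh1[k, ] <- gamete(pool_h1[par[1], ], pool_h2[par[1], ], map, ci)
        nh2[k, ] <- gamete(pool_h1[par[2], ], pool_h2[par[2], ], map, ci)
      }
      pool_h1 <- nh1
      pool_h2 <- nh2
    }
    h1 <- pool_h1
    h2 <- pool_h2
  }
  ids <- sprintf("S0_%04d", seq_len(n))
  info <- pop_info_frame(ids, stage = "S0", population = "landrace",
                         founders = ids)
  pop <- new_population(h1, h2, info, map)
  attr(pop, "freqs") <- stats::setNames(p, map$markers$marker)
  pop
}
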