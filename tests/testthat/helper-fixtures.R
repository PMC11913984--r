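# shared fixtures; everything generated in code, sizes kept small

tiny_map <- function(n_chrom = 2, m = 25, len = 100, seed = 11) {
  make_genetic_map(n_chrom, m, len, seed = seed)
}

tiny_world <- function(n = 120, n_qtl = 40, seed = 5, m = 25,
                       n_chrom = 2) {
  map <- tiny_map(n_chrom = n_chrom, m = m, seed = seed)
  founders <- simulate_founders(map, n, c(1, 1), seed = seed + 1)
  n_qtl <- min(n_qtl, nrow(map$markers))
  arch <- assign_architecture(map, n_qtl, default_traits()$target_corr,
                              default_traits()$trait_sds,
                              allele_freqs(founders), seed = seed + 2)
  list(map = map, founders = founders, arch = arch)
}

# DH training population with phenotypes at a target genomic h2
dh_training_set <- function(n = 150, m = 300, n_qtl = 100, h2 = 0.5,
                            seed = 1, trait = "PH_V4") {
  w <- tiny_world(n = n, n_qtl = n_qtl, seed = seed, m = m / 2,
                  n_chrom = 2)
  set.seed(seed + 100)
  dh <- extract_dh(w$founders, n, population = "C0")
  g <- genotypes(dh)
  p <- colMeans(g) / 2
  K <- suppressWarnings(vanraden_grm(g, p))
  tbv <- true_breeding_values(dh, w$arch)[, trait]
  y <- tbv + stats::rnorm(n, 0, stats::sd(tbv) * sqrt((1 - h2) / h2))
  list(dh = dh, geno = g, freqs = p, K = K, tbv = tbv, y = y,
       arch = w$arch, map = w$map, founders = w$founders)
}

# memoized scaled scheme runs shared across test files
.scheme_cache <- new.env(parent = emptyenv())
cached_scheme <- function(seed = 42, scale = 10, n_dh = 20L, ...) {
  key <- paste(seed, scale, n_dh, ..., sep = "_")
  if (is.null(.scheme_cache[[key]])) {
    cfg <- default_scheme_config(scale = scale, n_dh = n_dh, ...)
    .scheme_cache[[key]] <- run_scheme(cfg, seed = seed)
  }
  .scheme_cache[[key]]
}
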