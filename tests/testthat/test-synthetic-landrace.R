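test_that("genetic map: structure, bounds, determinism", {
  gm <- make_genetic_map(1, 2, 100, seed = 3)
  expect_equal(nrow(gm$markers), 2)
  expect_equal(nrow(gm$chromosomes), 1)

  gm1 <- make_genetic_map(10, 200, 160, seed = 1)
  gm2 <- make_genetic_map(10, 200, 160, seed = 1)
  expect_identical(gm1, gm2)
  expect_equal(nrow(gm1$markers), 2000)
  expect_true(all(gm1$markers$pos_cM >= 0 & gm1$markers$pos_cM <= 160))
  expect_false(is.unsorted(gm1$markers$pos_cM[gm1$markers$chrom == 3]))

  expect_error(make_genetic_map(2, 10, -5), "positive")
})

test_that("founders: HWE heterozygosity, shape, determinism", {
  map <- tiny_map(m = 50)
  f1 <- simulate_founders(map, 1000, c(1, 1), seed = 9)
  f2 <- simulate_founders(map, 1000, c(1, 1), seed = 9)
  expect_identical(f1$h1, f2$h1)
  expect_identical(f1$h2, f2$h2)

  g <- genotypes(f1)
  expect_true(all(g %in% 0:2))
  p <- attr(f1, "freqs")
  expect_true(all(p >= 0.05 & p <= 0.95))
  # per-marker heterozygosity ~ Binomial(n, 2p(1-p)): 5-sigma envelope
  het <- colMeans(g == 1)
  exp_het <- 2 * p * (1 - p)
  tol <- 5 * sqrt(exp_het * (1 - exp_het) / 1000)
  expect_true(all(abs(het - exp_het) <= tol))

  f3 <- simulate_founders(map, 2, c(1, 1), seed = 1)
  expect_equal(dim(genotypes(f3)), c(2, 100))

  expect_error(simulate_founders(map, 10, c(0, 1)), "degenerate")
  expect_error(simulate_founders(map, 10, c(1, Inf)), "degenerate")
})

test_that("architecture: QTL sampling, effect scaling, correlations", {
  w <- tiny_world(n = 1000, n_qtl = 60, seed = 2, m = 40)
  # realized TBV SDs within 15% of targets at n = 1000
  tbv <- true_breeding_values(w$founders, w$arch)
  sds <- apply(tbv, 2, sd)
  target <- default_traits()$trait_sds
  expect_true(all(abs(sds / target - 1) < 0.15))

  # all markers as QTL
  arch_all <- assign_architecture(w$map, 80, diag(2),
                                  c(a = 1, b = 1),
                                  allele_freqs(w$founders), seed = 1)
  expect_equal(length(arch_all$qtl_markers), 80)

  # non-PSD correlation rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(assign_architecture(w$map, 10, bad, c(a = 1, b = 1),
                                   allele_freqs(w$founders)),
               "semi-definite")
})

test_that("architecture: realized TBV correlations track targets over seeds", {
  # corr(PH_V4, PH_V6) targeted at 0.8; identity target stays near 0
  r_corr <- r_null <- numeric(10)
  map <- tiny_map(m = 40, seed = 77)
  f <- simulate_founders(map, 1000, c(1, 1), seed = 78)
  p <- allele_freqs(f)
  for (s in 1:10) {
    arch <- assign_architecture(map, 50, default_traits()$target_corr,
                                default_traits()$trait_sds, p, seed = s)
    tbv <- true_breeding_values(f, arch)
    r_corr[s] <- cor(tbv[, "PH_V4"], tbv[, "PH_V6"])
    arch0 <- assign_architecture(map, 50, diag(2), c(a = 1, b = 2), p,
                                 seed = s)
    tbv0 <- true_breeding_values(f, arch0)
    r_null[s] <- cor(tbv0[, 1], tbv0[, 2])
  }
  expect_gt(mean(r_corr), 0.7)
  expect_lt(mean(r_corr), 0.9)
  expect_lt(mean(abs(r_null)), 0.1)
})

test_that("true breeding values: hand table, linearity, zero case", {
  map <- make_genetic_map(1, 3, 50, seed = 4)
  g <- matrix(c(0, 1, 2,
                2, 0, 1,
                1, 1, 1,
                0, 0, 0,
                2, 2, 2), 5, 3, byrow = TRUE,
              dimnames = list(paste0("i", 1:5), map$markers$marker))
  eff <- matrix(c(0.5, -1, 2), 3, 1, dimnames = list(NULL, "t"))
  arch <- list(trait_names = "t", qtl_markers = map$markers$marker,
               qtl_index = 1:3, effects = eff)
  class(arch) <- "trait_architecture"
  # brute-force oracle: per-individual sum of count * effect
  oracle <- apply(g, 1, function(row) sum(row * eff[, 1]))
  expect_equal(drop(true_breeding_values(g, arch)), oracle)
  expect_equal(unname(oracle["i4"]), 0)  # homozygous reference everywhere

  arch2 <- arch
  arch2$effects <- eff * 2
  expect_equal(true_breeding_values(g, arch2),
               2 * true_breeding_values(g, arch))

  g_na <- g; g_na[1, 2] <- NA
  expect_error(true_breeding_values(g_na, arch), "missing")
})

test_that("simulate_trial: degenerate variances give TBV plus constant", {
  tbv <- matrix(rnorm(30), ncol = 1,
                dimnames = list(sprintf("g%02d", 1:30), "y"))
  des <- make_trial_design(rownames(tbv), n_env = 1, n_rep = 1,
                           block_size = 10)
  vc <- c(sigma2_env = 0, sigma2_gxe = 0, sigma2_rep = 0,
          sigma2_block = 0, sigma2_error = 0)
  rec <- simulate_trial(tbv, design = des, variance_config = vc, seed = 1)
  expect_equal(nrow(rec), 30)
  off <- rec$y - tbv[rec$genotype, 1]
  expect_lt(diff(range(off)), 1e-12)   # constant offset only
  expect_error(simulate_trial(tbv, design = des,
                              variance_config = vc * NA),
               "non-negative|missing", ignore.case = TRUE)
})

test_that("simulate_trial: round-trip h2 recovery and outlier-free Grubbs", {
  h2_hat <- numeric(3)
  for (s in 1:3) {
    tbv <- matrix(rnorm(200, 0, 2), ncol = 1,
                  dimnames = list(sprintf("g%03d", 1:200), "y"))
    des <- make_trial_design(rownames(tbv), n_env = 7, n_rep = 2)
    vc <- variance_for_h2(var(tbv[, 1]), 0.8)
    rec <- simulate_trial(tbv, design = des, variance_config = vc,
                          seed = s)
    v <- fit_trial_model(rec, "y", "varcomp")
    h2_hat[s] <- heritability(v)$h2
  }
  expect_gt(mean(h2_hat), 0.7)
  expect_lt(mean(h2_hat), 0.9)

  # outlier_rate = 0: Grubbs flags are rare across trait x environment
  tbv <- matrix(rnorm(100), ncol = 1,
                dimnames = list(sprintf("g%03d", 1:100), "y"))
  des <- make_trial_design(rownames(tbv), n_env = 6, n_rep = 1)
  vc <- c(sigma2_env = 1, sigma2_gxe = 0.3, sigma2_rep = 0,
          sigma2_block = 0.2, sigma2_error = 1)
  clean <- 0
  for (s in 1:5) {
    rec <- simulate_trial(tbv, design = des, variance_config = vc,
                          outlier_rate = 0, seed = s)
    fl <- grubbs_filter_trial(rec, traits = "y")
    clean <- clean + attr(fl, "flagged")
  }
  # 30 trait x environment strata; false flags occur at ~ alpha rate
  expect_lt(clean, 10)
})

test_that("ancestral random-mating option creates linkage disequilibrium", {
  map <- make_genetic_map(1, 30, 50, seed = 201)  # one dense chromosome
  f_le <- simulate_founders(map, 150, c(1, 1), seed = 202)
  f_ld <- simulate_founders(map, 150, c(1, 1), seed = 202,
                            ancestral = list(n_pool = 12, n_gen = 4))
  mean_r2 <- function(pop) {
    g <- genotypes(pop)
    keep <- apply(g, 2, var) > 0
    cc <- cor(g[, keep])
    adj <- cc[cbind(seq_len(sum(keep) - 1), seq_len(sum(keep) - 1) + 1)]
    mean(adj^2)
  }
  expect_gt(mean_r2(f_ld), mean_r2(f_le) + 0.02)
  expect_equal(pop_size(f_ld), 150)
})
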