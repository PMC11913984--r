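test_that("plot_filter: boundary at five plants, recount oracle", {
  rec <- data.frame(genotype = paste0("g", 1:6), population = "p",
                    environment = rep(c("e1", "e2"), each = 3),
                    replication = "rep1", block = "b1",
                    plant_count = c(5, 4, 20, 0, 5, 6),
                    y = rnorm(6))
  out <- plot_filter(rec)
  expect_equal(out$plant_count, c(5, 20, 5, 6))
  expect_equal(as.vector(attr(out, "removed")), c(1, 1))
  all_ok <- rec; all_ok$plant_count <- 10
  expect_equal(nrow(plot_filter(all_ok)), 6)

  # recount oracle on a simulated trial
  tbv <- matrix(rnorm(50), ncol = 1,
                dimnames = list(sprintf("g%02d", 1:50), "y"))
  des <- make_trial_design(rownames(tbv), n_env = 2, n_rep = 2)
  vc <- c(sigma2_env = 1, sigma2_gxe = 1, sigma2_rep = 0.1,
          sigma2_block = 0.1, sigma2_error = 1)
  trial <- simulate_trial(tbv, design = des, variance_config = vc,
                          seed = 31)
  filt <- plot_filter(trial, 5)
  expect_equal(nrow(trial) - nrow(filt), sum(trial$plant_count < 5))
})

test_that("grubbs_filter: textbook outlier, constant vector, iteration", {
  x <- c(10, 11, 12, 11, 10, 50)
  # standard Grubbs oracle: G and t-based critical value computed directly
  G <- max(abs(x - mean(x))) / sd(x)
  n <- length(x)
  tq <- qt(1 - 0.05 / (2 * n), n - 2)
  Gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(G, Gcrit)   # the oracle itself flags 50
  res <- grubbs_filter(x)
  expect_equal(which(res$outlier), 6)
  expect_equal(res$kept, x[1:5])

  expect_equal(grubbs_filter(rep(3, 10))$n_flagged, 0)
  expect_equal(grubbs_filter(c(1, 2))$n_flagged, 0)

  # two gross outliers removed iteratively
  res2 <- grubbs_filter(c(rnorm(30), 40, -40))
  expect_gte(res2$n_flagged, 2)
})

test_that("trial model: degenerate balanced data reproduces plot values", {
  tbv <- matrix(rnorm(25), ncol = 1,
                dimnames = list(sprintf("g%02d", 1:25), "y"))
  des <- make_trial_design(rownames(tbv), n_env = 1, n_rep = 1,
                           block_size = 5)
  vc <- c(sigma2_env = 0, sigma2_gxe = 0, sigma2_rep = 0,
          sigma2_block = 0, sigma2_error = 0)
  rec <- simulate_trial(tbv, design = des, variance_config = vc, seed = 2)
  m <- fit_trial_model(rec, "y", "means")
  expect_equal(m$mean[match(rec$genotype, m$genotype)], rec$y,
               tolerance = 1e-4)
})

test_that("trial model: heterogeneous variances recover the ordering", {
  # two populations, sigma2_g = 4 vs 1
  hits <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    tbv <- matrix(c(rnorm(80, 0, 2), rnorm(80, 0, 1)), ncol = 1,
                  dimnames = list(sprintf("g%03d", 1:160), "y"))
    popmap <- setNames(rep(c("A", "B"), each = 80), rownames(tbv))
    des <- make_trial_design(rownames(tbv), n_env = 4, n_rep = 2)
    vc <- c(sigma2_env = 2, sigma2_gxe = 1, sigma2_rep = 0.2,
            sigma2_block = 0.2, sigma2_error = 2)
    rec <- simulate_trial(tbv, popmap, des, vc, seed = s + 100)
    v <- fit_trial_model(rec, "y", "varcomp")
    if (v$sigma2_g[["A"]] > v$sigma2_g[["B"]]) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("means and varcomp modes agree on population contrasts", {
  set.seed(33)
  tbv <- matrix(c(rnorm(40, 0, 1), rnorm(40, 3, 1)), ncol = 1,
                dimnames = list(sprintf("g%03d", 1:80), "y"))
  popmap <- setNames(rep(c("A", "B"), each = 40), rownames(tbv))
  des <- make_trial_design(rownames(tbv), n_env = 3, n_rep = 2)
  vc <- c(sigma2_env = 1, sigma2_gxe = 0.5, sigma2_rep = 0.1,
          sigma2_block = 0.1, sigma2_error = 1)
  rec <- simulate_trial(tbv, popmap, des, vc, seed = 34)
  m <- fit_trial_model(rec, "y", "means")
  v <- fit_trial_model(rec, "y", "varcomp")
  contrast_means <- mean(m$mean[m$population == "B"]) -
    mean(m$mean[m$population == "A"])
  contrast_vc <- v$beta[["B"]] - v$beta[["A"]]
  expect_equal(contrast_means, contrast_vc, tolerance = 0.15)
})

test_that("heritability: closed form, zero case, bounds", {
  h <- heritability(list(sigma2_g = 1, sigma2_gxe = 1, sigma2_error = 1),
                    n_env = 7, n_rep = 2, n_genotypes = 100)
  expect_equal(h$h2, 1 / (1 + 1 / 7 + 1 / 14), tolerance = 1e-12)
  expect_equal(round(h$h2, 4), 0.8235)
  expect_true(h$ci[1] < h$h2 && h$h2 < h$ci[2])
  expect_true(all(h$ci >= 0 & h$ci <= 1))

  h0 <- heritability(list(sigma2_g = 0, sigma2_gxe = 1,
                          sigma2_error = 1), n_env = 7, n_rep = 2)
  expect_equal(h0$h2, 0)
})

test_that("compare_populations: single population, null and power", {
  single <- data.frame(genotype = paste0("g", 1:10), population = "A",
                       mean = rnorm(10))
  expect_message(res <- compare_populations(single), "skipped")
  expect_null(res$global)

  # shifted populations detected
  set.seed(35)
  dat <- data.frame(
    genotype = paste0("g", 1:200),
    population = rep(c("A", "B"), each = 100),
    mean = c(rnorm(100), rnorm(100, 3)))
  res2 <- compare_populations(dat)
  expect_lt(res2$global$p, 1e-6)
  expect_lt(res2$pairwise$p_adj[1], 1e-6)
  expect_true(res2$letters[["A"]] != res2$letters[["B"]])

  # identical populations: usually non-significant
  set.seed(36)
  p0 <- replicate(40, {
    d <- data.frame(genotype = paste0("g", 1:60),
                    population = rep(c("A", "B"), each = 30),
                    mean = rnorm(60))
    compare_populations(d)$global$p
  })
  expect_gt(mean(p0 > 0.05), 0.85)
})

test_that("variance-heterogeneity LRT: non-negative and detects 4x ratio", {
  set.seed(37)
  tbv <- matrix(c(rnorm(60, 0, 2), rnorm(60, 0, 1)), ncol = 1,
                dimnames = list(sprintf("g%03d", 1:120), "y"))
  popmap <- setNames(rep(c("A", "B"), each = 60), rownames(tbv))
  des <- make_trial_design(rownames(tbv), n_env = 3, n_rep = 2)
  vc <- c(sigma2_env = 1, sigma2_gxe = 0.5, sigma2_rep = 0.1,
          sigma2_block = 0.1, sigma2_error = 1)
  rec <- simulate_trial(tbv, popmap, des, vc, seed = 38)
  lrt <- lrt_variance_heterogeneity(rec, "y", c("A", "B"))
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$p, 0.2)   # 4-fold ratio usually detected at this size
})

test_that("disconnected designs are rejected with group names", {
  rec <- data.frame(genotype = rep(c("g1", "g2"), each = 2),
                    population = "p",
                    environment = rep(c("e1", "e2"), each = 2),
                    replication = "rep1",
                    block = paste0("b", 1:4),
                    plant_count = 10, y = rnorm(4))
  expect_error(fit_trial_model(rec, "y", "means"), "disconnected")
})
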