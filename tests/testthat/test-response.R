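# printed population mean GEBVs and sizes of the reference experiment's
# report (DH sets, cycles 1-3, and heterozygous selection units, cycles
# 1-2, per replication) used as regression worked examples
table1_dh <- list(
  N = list(R1 = c(100, 104, 90), R2 = c(100, 111, 78)),
  PH_V4 = list(R1 = c(5.66, 7.15, 7.97), R2 = c(5.97, 8.18, 9.66)),
  PH_V6 = list(R1 = c(8.99, 11.96, 13.09), R2 = c(9.65, 13.76, 16.08)),
  PH    = list(R1 = c(7.03, 8.37, 7.72), R2 = c(10.25, 12.24, 15.53)),
  FF    = list(R1 = c(-0.35, -0.56, -0.01), R2 = c(-1.38, -1.52, -2.20))
)
table1_dh_slopes <- list(
  PH_V4 = c(R1 = 1.2, R2 = 1.9), PH_V6 = c(R1 = 2.1, R2 = 3.3),
  PH = c(R1 = 0.4, R2 = 2.6), FF = c(R1 = 0.2, R2 = -0.4)
)
table1_s <- list(
  N = list(R1 = c(1003, 1005), R2 = c(1001, 906)),
  PH_V4 = list(R1 = c(5.25, 7.14), R2 = c(6.39, 8.34)),
  PH_V6 = list(R1 = c(8.60, 11.74), R2 = c(10.67, 14.09)),
  PH    = list(R1 = c(6.14, 7.49), R2 = c(10.90, 14.25)),
  FF    = list(R1 = c(0.57, 0.30), R2 = c(-0.95, -1.61))
)
table1_s_slopes <- list(
  PH_V4 = c(R1 = 1.9, R2 = 2.0), PH_V6 = c(R1 = 3.1, R2 = 3.4),
  PH = c(R1 = 1.4, R2 = 3.4), FF = c(R1 = -0.3, R2 = -0.7)
)

resp_data <- function(means, N, cycles, rep_label) {
  data.frame(value = means, cycle = cycles, replication = rep_label,
             weight = N)
}

test_that("response regression reproduces the printed per-cycle slopes", {
  # agreement at the printed precision (one decimal): |diff| <= 0.05,
  # with an epsilon for exact half-way cases (e.g. a slope of 1.95
  # printed as 2.0)
  for (tt in c("PH_V4", "PH_V6", "PH", "FF")) {
    for (rl in c("R1", "R2")) {
      fit_dh <- response_regression(
        resp_data(table1_dh[[tt]][[rl]], table1_dh$N[[rl]], 1:3, rl))
      expect_lt(abs(fit_dh$slopes$slope - table1_dh_slopes[[tt]][rl]),
                0.05 + 1e-9, label = paste("DH", tt, rl, "slope error"))
      fit_s <- response_regression(
        resp_data(table1_s[[tt]][[rl]], table1_s$N[[rl]], 1:2, rl))
      expect_lt(abs(fit_s$slopes$slope - table1_s_slopes[[tt]][rl]),
                0.05 + 1e-9, label = paste("S", tt, rl, "slope error"))
    }
  }
})

test_that("two-cycle slope equals the difference of cycle means", {
  d <- resp_data(c(2.5, 4.0), c(37, 91), 1:2, "R1")
  fit <- response_regression(d)
  expect_equal(fit$slopes$slope, 1.5, tolerance = 1e-12)
})

test_that("weighted-group-mean regression equals individual-level OLS", {
  set.seed(41)
  for (k in 1:5) {
    N <- c(30, 25, 40)
    vals <- lapply(N, function(n) rnorm(n, mean = runif(1, 0, 3)))
    ind <- data.frame(value = unlist(vals),
                      cycle = rep(1:3, times = N), replication = "R1")
    grp <- data.frame(value = sapply(vals, mean), cycle = 1:3,
                      replication = "R1", weight = N)
    f_ind <- response_regression(ind)
    f_grp <- response_regression(grp)
    expect_equal(f_ind$slopes$slope, f_grp$slopes$slope,
                 tolerance = 1e-12)
    expect_equal(f_ind$slopes$intercept, f_grp$slopes$intercept,
                 tolerance = 1e-12)
  }
})

test_that("nested-slope LRT is calibrated and errors on one cycle", {
  expect_error(response_regression(
    data.frame(value = rnorm(10), cycle = 1, replication = "R1")),
    "2 distinct cycles")

  set.seed(42)
  rej <- replicate(400, {
    d <- data.frame(value = c(0.5 * rep(1:3, each = 20) + rnorm(60),
                              0.5 * rep(1:3, each = 20) + rnorm(60)),
                    cycle = rep(rep(1:3, each = 20), 2),
                    replication = rep(c("R1", "R2"), each = 60))
    response_regression(d)$lrt$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("standardize_to_c0: origin, unit step, explicit divisor", {
  c0 <- c(1, 2, 3, 4)
  expect_equal(mean(standardize_to_c0(c0, c0)), 0)
  expect_equal(standardize_to_c0(mean(c0) + sd(c0), c0), 1)
  expect_equal(standardize_to_c0(4.5, c0, sd = 0.5), (4.5 - 2.5) / 0.5)
})

test_that("prediction accuracy: ratio definition and bounds", {
  expect_equal(prediction_accuracy(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8),
                                   h2 = 1)$accuracy,
               cor(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)))
  set.seed(43)
  g <- rnorm(50)
  m <- 0.4 * g + rnorm(50, 0, sqrt(1 - 0.16))
  pa <- prediction_accuracy(g, m, h2 = 0.64)
  expect_equal(pa$accuracy, pa$ability / 0.8)
  expect_error(prediction_accuracy(g[1:2], m[1:2], 0.5), ">= 3")
  expect_error(prediction_accuracy(g, m, 0), "h2")
})

test_that("retrain: check adjustment and newest-record precedence", {
  era1 <- data.frame(genotype = c("chk1", "chk2", "a", "b"),
                     value = c(10, 12, 5, 6))
  era2 <- data.frame(genotype = c("chk1", "chk2", "b", "c"),
                     value = c(10, 12, 7, 8))
  comb <- retrain(list(era1, era2), c("chk1", "chk2"))
  expect_equal(comb$value[comb$genotype == "c"], 8)
  # identical check means: values unchanged
  expect_equal(comb$value[comb$genotype == "a"], 5)
  # duplicated genotype b keeps the newest era's record
  expect_equal(comb$value[comb$genotype == "b"], 7)
  expect_equal(comb$era[comb$genotype == "b"], 2)

  # era shifted by +delta: checks agree exactly, differences preserved
  era2s <- era2
  era2s$value <- era2s$value + 4.2
  comb2 <- retrain(list(era1, era2s), c("chk1", "chk2"))
  expect_equal(comb2$value, comb$value)

  era_bad <- data.frame(genotype = c("x", "y"), value = c(1, 2))
  expect_error(retrain(list(era1, era_bad), c("chk1", "chk2")),
               "checks")
})

test_that("bootstrap_compare: identity, determinism, interval widening", {
  set.seed(44)
  a <- data.frame(id = 1:30, gebv = rnorm(30), mean = rnorm(30))
  res <- bootstrap_compare(a, a, mode = "paired", B = 200, seed = 7)
  expect_equal(unname(res$quantiles), c(0, 0))
  expect_false(res$significant)

  b <- data.frame(id = 1:30, gebv = rnorm(30), mean = rnorm(30))
  r1 <- bootstrap_compare(a, b, mode = "independent", B = 300, seed = 9)
  r2 <- bootstrap_compare(a, b, mode = "independent", B = 300, seed = 9)
  expect_identical(r1$quantiles, r2$quantiles)

  expect_warning(bootstrap_compare(a, b, B = 50, seed = 1), "B < 100")
  expect_error(bootstrap_compare(a[1:3, ], b[1:3, ], B = 200), ">= 5")

  # interval widens as n decreases (nested subsamples, on average)
  set.seed(45)
  big <- data.frame(id = 1:100, gebv = rnorm(100))
  big$mean <- 0.5 * big$gebv + rnorm(100)
  other <- data.frame(id = 1:100, gebv = rnorm(100), mean = rnorm(100))
  w_big <- diff(bootstrap_compare(big, other, "independent", B = 400,
                                  seed = 2)$quantiles)
  w_small <- diff(bootstrap_compare(big[1:25, ], other[1:25, ],
                                    "independent", B = 400,
                                    seed = 2)$quantiles)
  expect_gt(w_small, w_big)
})

test_that("trait correlations and Holm adjustment", {
  # Holm by hand: (0.01, 0.04), family of 2 at alpha 0.05 -> both reject
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_true(all(holm_adjust(c(0.01, 0.04)) < 0.05))

  set.seed(46)
  w <- tiny_world(n = 400, n_qtl = 60, seed = 47, m = 40)
  tbv <- true_breeding_values(w$founders, w$arch)
  means <- data.frame(population = "C0", tbv +
                        matrix(rnorm(length(tbv), 0, 1), nrow(tbv)))
  tc <- trait_correlations(means)
  r_v4v6 <- tc$r[tc$trait_a == "PH_V4" & tc$trait_b == "PH_V6"]
  expect_gt(r_v4v6, 0.5)
  p_ff <- tc$p_adj[tc$trait_a == "FF" | tc$trait_b == "FF"]
  r_ff <- tc$r[tc$trait_a == "FF" | tc$trait_b == "FF"]
  expect_lt(max(abs(r_ff)), 0.35)
  # a trait against itself
  means2 <- means
  means2$PH_V4_copy <- means2$PH_V4
  tc2 <- trait_correlations(means2)
  expect_equal(tc2$r[tc2$trait_a == "PH_V4" &
                       tc2$trait_b == "PH_V4_copy"], 1)
})
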