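test_that("GBLUP equals ridge-regression SNP-BLUP on K = ZZ'/c", {
  ts <- dh_training_set(n = 120, m = 200, n_qtl = 60, h2 = 0.5, seed = 3)
  fit <- fit_gblup(ts$y, K = ts$K)
  keep <- ts$K$keep
  Z <- sweep(ts$geno[, keep], 2, 2 * ts$freqs[keep])
  c_den <- ts$K$denom
  r <- ts$y - fit$beta
  # dual-form ridge with shrinkage c/lambda
  a <- crossprod(Z, solve(tcrossprod(Z) + diag(c_den / fit$lambda,
                                               nrow(Z)), r))
  gebv_ridge <- drop(Z %*% a)
  expect_lt(max(abs(gebv_ridge - fit$gebv)), 1e-6)
})

test_that("REML h2 recovery and shrinkage limits", {
  # lambda -> 0 limit: pure-noise response gives ~zero GEBVs
  set.seed(16)
  ts <- dh_training_set(n = 100, m = 120, n_qtl = 40, seed = 5)
  y_noise <- rnorm(100)
  fit0 <- fit_gblup(y_noise, K = ts$K)
  expect_lt(fit0$h2, 0.3)
  expect_lt(max(abs(fit0$gebv)), max(abs(y_noise)))

  # constant y warns and returns zero genetic variance
  expect_warning(fitc <- fit_gblup(rep(1, 100), K = ts$K), "constant")
  expect_equal(fitc$sigma2_g, 0)

  # quick recovery check at h2 = 0.5 (full grid lives in acceptance)
  h2s <- sapply(1:5, function(s) {
    ts <- dh_training_set(n = 150, m = 200, n_qtl = 80, h2 = 0.5,
                          seed = s)
    fit_gblup(ts$y, K = ts$K)$h2
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.12)
})

test_that("REML invariance to constant shifts of y", {
  ts <- dh_training_set(n = 100, m = 150, n_qtl = 50, seed = 7)
  f1 <- fit_gblup(ts$y, K = ts$K)
  f2 <- fit_gblup(ts$y + 100, K = ts$K)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-6)
  expect_equal(unname(f2$beta - f1$beta), 100, tolerance = 1e-6)
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-6)
})

test_that("shrinkage is monotone in lambda", {
  ts <- dh_training_set(n = 80, m = 100, n_qtl = 30, seed = 9)
  fit <- fit_gblup(ts$y, K = ts$K)
  norms <- sapply(c(1e-4, 1e-2, 1, 100), function(lam) {
    w <- lam * fit$d + 1
    r <- fit$resid_rot
    sqrt(sum((lam * fit$d / w * r)^2))
  })
  expect_true(all(diff(norms) > 0))
})

test_that("prediction: identical and unrelated candidates, dual routes", {
  ts <- dh_training_set(n = 80, m = 300, n_qtl = 60, seed = 11)
  fit <- fit_gblup(ts$y, K = ts$K)
  keep <- ts$K$keep
  # candidate identical to training line 1
  Kx <- suppressWarnings(cross_grm(ts$geno, ts$geno[1, , drop = FALSE],
                                   ts$freqs))
  colnames(Kx) <- "cand1"
  pred <- predict_unphenotyped(fit, Kx)
  expect_equal(unname(pred), unname(fit$gebv[1]), tolerance = 1e-8)

  # zero-relationship candidate: GEBV 0
  K0 <- matrix(0, 80, 1)
  expect_equal(unname(predict_unphenotyped(fit, K0)), 0)

  # the cross-block formula and the joint MME agree
  f2 <- simulate_founders(ts$map, 10, c(1, 1), seed = 99)
  g_new <- genotypes(f2)
  rownames(g_new) <- paste0("cand_", seq_len(10))
  Kx2 <- suppressWarnings(cross_grm(ts$geno, g_new, ts$freqs))
  p1 <- predict_unphenotyped(fit, Kx2)
  g_joint <- rbind(ts$geno, g_new)
  K_joint <- suppressWarnings(vanraden_grm(g_joint, ts$freqs))
  # regularize only if numerically singular (m >> n keeps it PD here)
  p2 <- predict_unphenotyped(fit, Kx2, method = "mme", K_joint = K_joint)
  expect_lt(max(abs(p1 - p2)), 1e-8)

  # overlapping candidate ids rejected
  K_bad <- K_joint
  rownames(K_bad$K)[81] <- fit$ids[1]
  expect_error(predict_unphenotyped(fit, Kx2, method = "mme",
                                    K_joint = K_bad), "overlap")
})

test_that("predicted candidates track true breeding values", {
  rs <- sapply(1:5, function(s) {
    ts <- dh_training_set(n = 200, m = 300, n_qtl = 80, h2 = 0.7,
                          seed = s + 40)
    fit <- fit_gblup(ts$y, K = ts$K)
    set.seed(s)
    s1 <- diallel(subset_population(ts$founders, 1:10), 20)
    g_new <- genotypes(s1)
    Kx <- suppressWarnings(cross_grm(ts$geno, g_new, ts$freqs))
    pred <- predict_unphenotyped(fit, Kx)
    tbv_new <- true_breeding_values(s1, ts$arch)[, "PH_V4"]
    cor(pred, tbv_new)
  })
  expect_gt(mean(rs), 0)
})

test_that("multi-trait GBLUP: degenerate duplicate and single-trait match", {
  ts <- dh_training_set(n = 120, m = 200, n_qtl = 60, h2 = 0.6, seed = 21)
  # duplicate trait: genetic correlation -> 1
  Y <- cbind(t1 = ts$y, t2 = ts$y)
  fit_dup <- fit_gblup_multitrait(Y, K = ts$K)
  expect_gt(fit_dup$gcor[1, 2], 0.98)

  # weakly correlated traits: single- and multi-trait GEBVs correlate
  set.seed(22)
  tbv2 <- true_breeding_values(ts$dh, ts$arch)[, "FF"]
  y2 <- tbv2 + rnorm(120, 0, sd(tbv2) * sqrt(2 / 3))
  Y2 <- cbind(PH_V4 = ts$y, FF = y2)
  fit_mt <- fit_gblup_multitrait(Y2, K = ts$K)
  fit_st <- fit_gblup(ts$y, K = ts$K)
  expect_gt(cor(fit_mt$gebv[, "PH_V4"], fit_st$gebv), 0.95)
})

test_that("multi-trait GBLUP recovers near-zero genetic correlation", {
  offd <- sapply(1:6, function(s) {
    w <- tiny_world(n = 150, n_qtl = 60, seed = s + 60, m = 60)
    set.seed(s)
    dh <- extract_dh(w$founders, 150, population = "C0")
    g <- genotypes(dh)
    K <- suppressWarnings(vanraden_grm(g, colMeans(g) / 2))
    tbv <- true_breeding_values(dh, w$arch)[, c("PH_V4", "FF")]
    Y <- tbv + sapply(colnames(tbv), function(tt)
      rnorm(150, 0, sd(tbv[, tt])))
    fit_gblup_multitrait(Y, K = K)$gcor[1, 2]
  })
  expect_lt(abs(mean(offd)), 0.2)
})

test_that("multi-trait prediction is consistent with training BLUPs", {
  ts <- dh_training_set(n = 80, m = 150, n_qtl = 50, seed = 31)
  tbvs <- true_breeding_values(ts$dh, ts$arch)
  set.seed(31)
  Y <- tbvs[, c("PH_V4", "PH_V6")] +
    sapply(c("PH_V4", "PH_V6"), function(tt)
      rnorm(80, 0, sd(tbvs[, tt])))
  fit <- fit_gblup_multitrait(Y, K = ts$K)
  # predicting the training set itself returns the fitted GEBVs
  pred <- predict_unphenotyped(fit, ts$K$K)
  expect_equal(unname(pred), unname(fit$gebv), tolerance = 1e-6)
})

test_that("fits serialize to CSV tables and JSON", {
  ts <- dh_training_set(n = 60, m = 100, n_qtl = 30, seed = 51)
  fit <- fit_gblup(ts$y, K = ts$K)
  tab <- gebv_table(fit, population = "C0")
  expect_equal(nrow(tab), 60)
  expect_equal(tab$gebv, unname(fit$gebv))
  path <- withr::local_tempfile(fileext = ".json")
  write_gblup_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$type, "single_trait")
  expect_equal(back$variance$sigma2_g, fit$sigma2_g, tolerance = 1e-9)
  expect_equal(back$gebv[[ts$dh$info$id[3]]], unname(fit$gebv[3]),
               tolerance = 1e-9)
})
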