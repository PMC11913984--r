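#' Drop plots with too few plants
#'
#' Removes plot records whose `plant_count` is below `min_plants`
#' (boundary retained: a plot with exactly `min_plants` plants stays).
#' Removal counts per environment are attached as attribute `"removed"`.
#'
#' @param records Plot-record data.frame (see [simulate_trial()]).
#' @param min_plants Minimum plant count (default 5).
#' @return Filtered data.frame.
#' @export
plot_filter <- function(records, min_plants = 5L) {
  drop <- records$plant_count < min_plants
  removed <- tapply(drop, records$environment, sum)
  out <- records[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

grubbs_critical <- function(n, alpha) {
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Grubbs outlier test
#'
#' Computes `G = max |x - mean| / sd` and compares it with the t-based
#' critical value at level `alpha`; the most extreme value is removed and
#' the test repeated until no further rejection. Intended to be applied
#' per trait x environment. Degenerate inputs (n < 3 or zero SD) pass
#' through unflagged.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return List with `kept` (values), `outlier` (logical flags on the
#'   input), `n_flagged`.
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  flag <- rep(FALSE, length(values))
  active <- which(!is.na(values))
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3) break
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g > grubbs_critical(n, alpha)) {
      worst <- active[which.max(dev)]
      flag[worst] <- TRUE
      active <- setdiff(active, worst)
    } else break
  }
  list(kept = values[!flag & !is.na(values)], outlier = flag,
       n_flagged = sum(flag))
}

#' Apply the Grubbs filter per trait x environment of a trial
#'
#' @param records Plot records.
#' @param traits Trait columns to filter (default: attribute `"traits"`).
#' @param alpha Level per test.
#' @return Records with flagged observations set to `NA`; counts in
#'   attribute `"flagged"`.
#' @export
grubbs_filter_trial <- function(records, traits = NULL, alpha = 0.05) {
  if (is.null(traits)) traits <- attr(records, "traits")
  flagged <- 0L
  for (tt in traits) {
    for (ee in unique(records$environment)) {
      i <- which(records$environment == ee)
      res <- grubbs_filter(records[[tt]][i], alpha)
      records[[tt]][i[res$outlier]] <- NA
      flagged <- flagged + res$n_flagged
    }
  }
  attr(records, "traits") <- traits
  attr(records, "flagged") <- flagged
  records
}

# ---- sparse REML machinery -------------------------------------------------

sparse_incidence <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# connectivity of the genotype-environment bipartite graph
check_connected <- function(genotype, environment) {
  ge <- unique(data.frame(g = as.character(genotype),
                          e = as.character(environment)))
  comp <- stats::setNames(seq_along(unique(ge$g)), unique(ge$g))
  repeat {
    new <- tapply(comp[ge$g], ge$e, min)[ge$e]
    new <- tapply(new, ge$g, min)[names(comp)]
    if (all(new == comp)) break
    comp <- new
  }
  if (length(unique(comp)) > 1) {
    grp <- split(names(comp), comp)
    stop(sprintf(
      "disconnected design: %d isolated genotype groups (first: %s)",
      length(grp), paste(utils::head(grp[[2]], 3), collapse = ", ")))
  }
  invisible(TRUE)
}

# REML for y = X b + sum_k Z_k u_k + e, u_k ~ N(0, s2_k I).
# Returns variance components, loglik, BLUEs with covariance.
reml_sparse <- function(y, X, Zlist, init = NULL, control = list()) {
  ok <- !is.na(y)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  Zlist <- lapply(Zlist, function(Z) Z[ok, , drop = FALSE])
  # drop rank-deficient fixed-effect columns
  qrX <- qr(as.matrix(X))
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  n <- length(y)
  p <- ncol(X)
  q_k <- vapply(Zlist, ncol, integer(1))
  Z <- do.call(cbind, Zlist)
  W <- cbind(X, Z)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- Matrix::crossprod(W, y)
  yty <- sum(y^2)
  col_group <- rep(seq_along(Zlist), q_k)
  vy <- stats::var(y)
  lower <- log(vy * 1e-8)
  upper <- log(vy * 1e3)
  n_par <- length(Zlist) + 1L

  chfact <- NULL
  neg2 <- function(theta) {
    s2 <- exp(theta)
    s2e <- s2[n_par]
    dinv <- 1 / s2[col_group]
    Cmat <- WtW / s2e + Matrix::Diagonal(
      x = c(rep(0, p), dinv))
    ch <- tryCatch({
      if (is.null(chfact)) {
        chfact <<- Matrix::Cholesky(Cmat, LDL = FALSE, perm = TRUE)
        chfact
      } else Matrix::update(chfact, Cmat)
    }, error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldC <- 2 * Matrix::determinant(ch, logarithm = TRUE,
                                   sqrt = TRUE)$modulus
    sol <- Matrix::solve(ch, Wty / s2e)
    yPy <- yty / s2e - sum(sol * Wty) / s2e
    obj <- as.numeric(n * log(s2e) + sum(q_k * theta[-n_par]) +
                        ldC + yPy)
    if (!is.finite(obj)) 1e10 else obj
  }
  if (is.null(init)) init <- rep(log(vy / n_par), n_par)
  opt <- stats::optim(init, neg2, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = utils::modifyList(
                        list(maxit = 200, factr = 1e4), control))
  s2 <- exp(opt$par)
  names(s2) <- c(names(Zlist), "residual")
  # effects at the optimum
  s2e <- s2[n_par]
  Cmat <- WtW / s2e + Matrix::Diagonal(x = c(rep(0, p), 1 / s2[col_group]))
  sol <- Matrix::solve(Cmat, Wty / s2e)
  beta <- stats::setNames(as.numeric(sol[seq_len(p)]), colnames(X))
  u <- as.numeric(sol[-seq_len(p)])
  # covariance of BLUEs: s2e-free form, [C^{-1}]_XX
  Cinv_x <- Matrix::solve(Cmat, Matrix::Diagonal(nrow(Cmat))[, seq_len(p),
                                                             drop = FALSE])
  vbeta <- as.matrix(Cinv_x[seq_len(p), , drop = FALSE])
  dimnames(vbeta) <- list(colnames(X), colnames(X))
  # near-boundary components are reported as zero
  s2_rep <- ifelse(s2 <= exp(lower) * 1.01, 0, s2)
  list(varcomp = s2_rep, varcomp_raw = s2, loglik = -0.5 * opt$value,
       beta = beta, vbeta = vbeta, u = u, u_index = col_group,
       converged = opt$convergence == 0, n = n, p = p)
}

# ---- the trial model -------------------------------------------------------

#' Fit the multi-environment trial model
#'
#' Fits the plot-level mixed model: population mean + genotype within
#' population + environment + genotype x environment within population +
#' replication within environment + block within replication + residual.
#' Environment, G x E, replication and block are always random; the
#' genotype effect is fixed in `"means"` mode (yielding adjusted entry
#' means, i.e. BLUEs per genotype) and random in `"varcomp"` mode with a
#' separate (heterogeneous) genetic and G x E variance per population.
#' Genotypes of `fixed_populations` (e.g. checks) stay fixed in both
#' modes. REML estimates are obtained by direct maximization of the
#' restricted likelihood via the sparse mixed-model equations.
#'
#' @param records Plot-record data.frame (columns genotype, population,
#'   environment, replication, block, plus trait columns).
#' @param trait Name of the trait column to analyse.
#' @param genotype_mode `"means"` or `"varcomp"`.
#' @param fixed_populations Populations whose genotypes are treated as
#'   fixed in both modes (checks).
#' @param var_groups Optional named character vector mapping population
#'   to variance group; populations sharing a group share their genetic
#'   variance (used by the heterogeneity LRT). Default: each population
#'   its own group.
#' @return In means mode, an object of class `adjusted_means` (data.frame
#'   genotype, population, mean, se) with attributes `varcomp` and
#'   `loglik`. In varcomp mode, an object of class `trial_varcomp`: list
#'   with per-group `sigma2_g`, `sigma2_gxe`, shared `sigma2_env`,
#'   `sigma2_rep`, `sigma2_block`, `sigma2_error`, `loglik`, design
#'   dimensions and genotype counts.
#' @export
fit_trial_model <- function(records, trait,
                            genotype_mode = c("means", "varcomp"),
                            fixed_populations = NULL,
                            var_groups = NULL) {
  genotype_mode <- match.arg(genotype_mode)
  stopifnot(trait %in% names(records))
  records <- records[!is.na(records[[trait]]), , drop = FALSE]
  if (nrow(records) == 0) stop("no records for trait ", trait)
  check_connected(records$genotype, records$environment)
  y <- records[[trait]]
  gf <- factor(records$genotype)
  pf <- factor(records$population)
  ef <- factor(records$environment)
  rf <- factor(paste(records$environment, records$replication, sep = ":"))
  bf <- factor(records$block)
  gxe <- factor(paste(as.character(gf), as.character(ef), sep = ":"))
  geno_pop <- tapply(as.character(pf), gf, function(x) x[1])

  rand_pops <- setdiff(levels(pf), fixed_populations)
  if (is.null(var_groups)) {
    var_groups <- stats::setNames(rand_pops, rand_pops)
  }

  Zlist <- list()
  # genotype effects
  if (genotype_mode == "varcomp") {
    Zg_all <- sparse_incidence(gf)
    for (vg in unique(var_groups)) {
      pops <- names(var_groups)[var_groups == vg]
      cols <- which(geno_pop[colnames(Zg_all)] %in% pops)
      if (length(cols) > 0) {
        Zlist[[paste0("genotype:", vg)]] <-
          Zg_all[, cols, drop = FALSE]
      }
    }
  }
  # G x E, heterogeneous per population group (same grouping)
  Zgxe_all <- sparse_incidence(gxe)
  gxe_geno <- sub(":[^:]*$", "", colnames(Zgxe_all))
  for (vg in unique(var_groups)) {
    pops <- names(var_groups)[var_groups == vg]
    cols <- which(geno_pop[gxe_geno] %in% pops)
    if (length(cols) > 0) {
      Zlist[[paste0("gxe:", vg)]] <- Zgxe_all[, cols, drop = FALSE]
    }
  }
  # G x E of fixed populations: pooled into one extra component
  fixed_cols <- which(geno_pop[gxe_geno] %in% fixed_populations)
  if (length(fixed_cols) > 0) {
    Zlist[["gxe:fixed"]] <- Zgxe_all[, fixed_cols, drop = FALSE]
  }
  if (nlevels(ef) > 1) Zlist[["env"]] <- sparse_incidence(ef)
  if (nlevels(rf) > nlevels(ef)) Zlist[["rep"]] <- sparse_incidence(rf)
  if (nlevels(bf) > nlevels(rf)) Zlist[["block"]] <- sparse_incidence(bf)

  if (genotype_mode == "means") {
    X <- sparse_incidence(gf)
  } else {
    Xp <- sparse_incidence(pf)
    fixed_geno <- which(geno_pop[levels(gf)] %in% fixed_populations)
    if (length(fixed_geno) > 0) {
      Zg_all <- sparse_incidence(gf)
      # drop one genotype per fixed population (absorbed by its mean)
      drop_one <- !duplicated(geno_pop[levels(gf)][fixed_geno])
      X <- cbind(Xp, Zg_all[, fixed_geno[!drop_one], drop = FALSE])
    } else {
      X <- Xp
    }
  }

  fit <- reml_sparse(y, X, Zlist)

  E <- nlevels(ef)
  R <- round(nlevels(rf) / E)
  if (genotype_mode == "means") {
    ids <- levels(gf)
    means <- fit$beta[ids]
    se <- sqrt(pmax(diag(fit$vbeta)[ids], 0))
    out <- data.frame(genotype = ids,
                      population = unname(geno_pop[ids]),
                      mean = unname(means), se = unname(se),
                      stringsAsFactors = FALSE)
    class(out) <- c("adjusted_means", "data.frame")
    attr(out, "varcomp") <- fit$varcomp
    attr(out, "loglik") <- fit$loglik
    attr(out, "n_env") <- E
    attr(out, "n_rep") <- R
    return(out)
  }
  vc <- fit$varcomp
  groups <- unique(var_groups)
  s2g <- stats::setNames(vc[paste0("genotype:", groups)], groups)
  s2gxe <- stats::setNames(vc[paste0("gxe:", groups)], groups)
  n_geno <- table(factor(unname(var_groups[geno_pop[levels(gf)]]),
                         levels = groups))
  out <- list(sigma2_g = s2g, sigma2_gxe = s2gxe,
              sigma2_env = unname(vc["env"]),
              sigma2_rep = unname(vc["rep"]),
              sigma2_block = unname(vc["block"]),
              sigma2_error = unname(vc["residual"]),
              var_groups = var_groups,
              n_genotypes = stats::setNames(as.integer(n_geno), groups),
              n_env = E, n_rep = R,
              loglik = fit$loglik, beta = fit$beta,
              vbeta = fit$vbeta, converged = fit$converged)
  class(out) <- "trial_varcomp"
  out
}

#' @export
print.trial_varcomp <- function(x, ...) {
  cat("<trial_varcomp>\n  sigma2_g:  ",
      paste(sprintf("%s=%.3f", names(x$sigma2_g), x$sigma2_g),
            collapse = ", "),
      "\n  sigma2_gxe:", paste(sprintf("%s=%.3f", names(x$sigma2_gxe),
                                       x$sigma2_gxe), collapse = ", "),
      sprintf("\n  env=%.3f rep=%.3f block=%.3f error=%.3f  logLik=%.2f\n",
              x$sigma2_env, x$sigma2_rep, x$sigma2_block, x$sigma2_error,
              x$loglik))
  invisible(x)
}

#' Entry-mean heritability with confidence interval
#'
#' `h2 = s2_g / (s2_g + s2_gxe / E + s2_e / (E R))`, with an F-quantile
#' (Knapp-style) confidence interval on the balanced-design
#' approximation: on entry means, `F = 1 / (1 - h2)` with
#' `df1 = n_g - 1`, `df2 = (n_g - 1)(E - 1)`.
#'
#' @param varcomp A `trial_varcomp` or a named vector/list with
#'   `sigma2_g`, `sigma2_gxe`, `sigma2_error`.
#' @param group Variance group (population) to report when `varcomp` is a
#'   `trial_varcomp` with several groups.
#' @param n_env,n_rep Design dimensions (defaults taken from `varcomp`).
#' @param n_genotypes Number of genotypes (for the CI dfs).
#' @param alpha CI level (default 0.05 for a 95% CI).
#' @return List with `h2`, `ci` (length 2), `dfs`.
#' @export
heritability <- function(varcomp, group = NULL, n_env = NULL, n_rep = NULL,
                         n_genotypes = NULL, alpha = 0.05) {
  if (inherits(varcomp, "trial_varcomp")) {
    if (is.null(group)) group <- names(varcomp$sigma2_g)[1]
    s2g <- varcomp$sigma2_g[[group]]
    s2gxe <- varcomp$sigma2_gxe[[group]]
    s2e <- varcomp$sigma2_error
    if (is.null(n_env)) n_env <- varcomp$n_env
    if (is.null(n_rep)) n_rep <- varcomp$n_rep
    if (is.null(n_genotypes)) n_genotypes <- varcomp$n_genotypes[[group]]
  } else {
    s2g <- varcomp[["sigma2_g"]]
    s2gxe <- varcomp[["sigma2_gxe"]]
    s2e <- varcomp[["sigma2_error"]]
  }
  stopifnot(!is.null(n_env), !is.null(n_rep))
  denom <- s2g + s2gxe / n_env + s2e / (n_env * n_rep)
  h2 <- if (denom > 0) max(0, min(1, s2g / denom)) else 0
  ci <- c(NA_real_, NA_real_)
  if (!is.null(n_genotypes) && n_genotypes > 2 && h2 < 1) {
    df1 <- n_genotypes - 1
    df2 <- (n_genotypes - 1) * (n_env - 1)
    Fobs <- 1 / (1 - h2)
    lo <- 1 - 1 / (Fobs / stats::qf(1 - alpha / 2, df1, df2))
    hi <- 1 - 1 / (Fobs / stats::qf(alpha / 2, df1, df2))
    ci <- c(max(0, lo), min(1, hi))
  }
  list(h2 = h2, ci = ci,
       dfs = if (!is.null(n_genotypes))
         c(df1 = n_genotypes - 1,
           df2 = (n_genotypes - 1) * (n_env - 1)) else NULL)
}

# compact-letter display from a logical "significantly different" matrix
letter_display <- function(diff_mat) {
  nms <- rownames(diff_mat)
  groups <- list(nms)  # start with one letter covering everything
  for (i in seq_along(nms)) for (j in seq_len(i - 1)) {
    if (!diff_mat[i, j]) next
    for (g in seq_along(groups)) {
      if (all(c(nms[i], nms[j]) %in% groups[[g]])) {
        groups <- c(groups, list(setdiff(groups[[g]], nms[i])),
                    list(setdiff(groups[[g]], nms[j])))
        groups[g] <- NULL
        break
      }
    }
  }
  # absorb subsets
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a != b && keep[a] && all(groups[[a]] %in% groups[[b]])) {
      keep[a] <- FALSE
    }
  }
  groups <- groups[keep]
  letters_out <- stats::setNames(rep("", length(nms)), nms)
  for (g in seq_along(groups)) {
    for (nm in groups[[g]]) {
      letters_out[nm] <- paste0(letters_out[nm], letters[g])
    }
  }
  letters_out
}

#' Compare population means
#'
#' Global Welch-type test on the population means of adjusted entry
#' means; if significant at `alpha`, pairwise Welch-Satterthwaite t-tests
#' (heterogeneous variances and degrees of freedom) with Bonferroni-Holm
#' adjustment, plus a compact letter display.
#'
#' @param means An `adjusted_means` object or data.frame with columns
#'   `genotype`, `population`, `mean`.
#' @param alpha Level for the global gate and the letter display.
#' @return List with `global` (statistic, df, p), `pairwise` (data.frame
#'   a, b, estimate, t, df, p, p_adj) or `NULL`, `letters`.
#' @export
compare_populations <- function(means, alpha = 0.05) {
  pops <- unique(means$population)
  if (length(pops) < 2) {
    message("single population: global test skipped")
    return(list(global = NULL, pairwise = NULL,
                letters = stats::setNames("a", pops)))
  }
  gt <- stats::oneway.test(mean ~ population, data = means,
                           var.equal = FALSE)
  global <- list(statistic = unname(gt$statistic),
                 df = unname(gt$parameter), p = gt$p.value)
  pw <- NULL
  diff_mat <- matrix(FALSE, length(pops), length(pops),
                     dimnames = list(pops, pops))
  if (global$p < alpha) {
    cmb <- utils::combn(pops, 2)
    rows <- lapply(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      tt <- stats::t.test(means$mean[means$population == a],
                          means$mean[means$population == b],
                          var.equal = FALSE)
      data.frame(a = a, b = b,
                 estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$p_adj <- stats::p.adjust(pw$p, method = "holm")
    for (k in seq_len(nrow(pw))) {
      if (pw$p_adj[k] < alpha) {
        diff_mat[pw$a[k], pw$b[k]] <- diff_mat[pw$b[k], pw$a[k]] <- TRUE
      }
    }
  }
  list(global = global, pairwise = pw, letters = letter_display(diff_mat))
}

#' Likelihood ratio test for heterogeneity of genetic variance
#'
#' Compares the trial-model REML fit with separate genetic variances for
#' the two populations against the fit with a pooled genetic variance
#' (G x E variances stay population-specific in both fits, so the models
#' are nested). Statistic `2 * (logLik_sep - logLik_pooled)` referred to
#' chi-square with 1 df.
#'
#' @param records Plot records.
#' @param trait Trait column.
#' @param pair Length-2 character vector of population labels.
#' @param fixed_populations Passed through to [fit_trial_model()].
#' @return List with `statistic`, `p`, and the two fits.
#' @export
lrt_variance_heterogeneity <- function(records, trait, pair,
                                       fixed_populations = NULL) {
  stopifnot(length(pair) == 2)
  pops <- setdiff(unique(records$population), fixed_populations)
  sep_groups <- stats::setNames(pops, pops)
  pooled_groups <- sep_groups
  pooled_groups[pair] <- paste(sort(pair), collapse = "+")
  # pooled sigma2_g but separate gxe: build groups only for genotype term
  fit_sep <- fit_trial_model(records, trait, "varcomp",
                             fixed_populations, var_groups = sep_groups)
  fit_pool <- fit_trial_model_pooled_g(records, trait, fixed_populations,
                                       sep_groups, pooled_groups)
  stat <- max(0, 2 * (fit_sep$loglik - fit_pool$loglik))
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE),
       fit_separate = fit_sep, fit_pooled = fit_pool)
}

# varcomp fit with genotype-variance groups decoupled from gxe groups
fit_trial_model_pooled_g <- function(records, trait, fixed_populations,
                                     gxe_groups, g_groups) {
  records <- records[!is.na(records[[trait]]), , drop = FALSE]
  y <- records[[trait]]
  gf <- factor(records$genotype)
  pf <- factor(records$population)
  ef <- factor(records$environment)
  rf <- factor(paste(records$environment, records$replication, sep = ":"))
  bf <- factor(records$block)
  gxe <- factor(paste(as.character(gf), as.character(ef), sep = ":"))
  geno_pop <- tapply(as.character(pf), gf, function(x) x[1])
  Zlist <- list()
  Zg_all <- sparse_incidence(gf)
  for (vg in unique(g_groups)) {
    pops <- names(g_groups)[g_groups == vg]
    cols <- which(geno_pop[colnames(Zg_all)] %in% pops)
    if (length(cols)) {
      Zlist[[paste0("genotype:", vg)]] <- Zg_all[, cols, drop = FALSE]
    }
  }
  Zgxe_all <- sparse_incidence(gxe)
  gxe_geno <- sub(":[^:]*$", "", colnames(Zgxe_all))
  for (vg in unique(gxe_groups)) {
    pops <- names(gxe_groups)[gxe_groups == vg]
    cols <- which(geno_pop[gxe_geno] %in% pops)
    if (length(cols)) {
      Zlist[[paste0("gxe:", vg)]] <- Zgxe_all[, cols, drop = FALSE]
    }
  }
  if (nlevels(ef) > 1) Zlist[["env"]] <- sparse_incidence(ef)
  if (nlevels(rf) > nlevels(ef)) Zlist[["rep"]] <- sparse_incidence(rf)
  if (nlevels(bf) > nlevels(rf)) Zlist[["block"]] <- sparse_incidence(bf)
  X <- sparse_incidence(pf)
  fit <- reml_sparse(y, X, Zlist)
  list(varcomp = fit$varcomp, loglik = fit$loglik)
}
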