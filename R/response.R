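#' Selection-response regression with replication-specific slopes
#'
#' Fits `y_ijr = beta_r + gamma_r * c_j(r) + e_ijr`: ordinary least
#' squares with a separate intercept and slope per replication, the
#' predictor being the (numeric) cycle. Because the predictor is constant
#' within a cycle, the individual-level OLS slope is identical to the
#' regression of cycle means weighted by cycle sizes; the function
#' therefore accepts either individual values (weight 1) or cycle means
#' with `weight = N`. A likelihood ratio test compares the model with a
#' common slope across replications against the nested-slope model.
#'
#' One-sided p-values for `gamma_r > 0` are reported (per the selection-
#' response null); set `two_sided = TRUE` for two-sided. p-values and the
#' LRT are only meaningful for individual-level data.
#'
#' @param data data.frame with columns `value`, `cycle` (numeric),
#'   `replication`; optional `weight`.
#' @param two_sided Report two-sided slope p-values instead.
#' @return Object of class `response_fit`: data.frame `slopes` (one row
#'   per replication: intercept, slope, se, p), `lrt` (statistic, df, p
#'   for equal slopes), `n`.
#' @export
response_regression <- function(data, two_sided = FALSE) {
  stopifnot(all(c("value", "cycle", "replication") %in% names(data)))
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  reps <- unique(as.character(data$replication))
  rows <- lapply(reps, function(rr) {
    d <- data[data$replication == rr, , drop = FALSE]
    wr <- w[data$replication == rr]
    if (length(unique(d$cycle)) < 2) {
      stop("need >= 2 distinct cycles per replication")
    }
    fit <- stats::lm(value ~ cycle, data = d, weights = wr)
    cf <- summary(fit)$coefficients
    se <- cf["cycle", "Std. Error"]
    tval <- cf["cycle", "t value"]
    df <- fit$df.residual
    p <- if (two_sided) 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
         else stats::pt(tval, df, lower.tail = FALSE)
    data.frame(replication = rr, intercept = cf["(Intercept)", "Estimate"],
               slope = cf["cycle", "Estimate"], se = se, p = p,
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, rows)
  # LRT: common slope (per-rep intercepts) vs per-rep slopes
  lrt <- NULL
  if (length(reps) > 1) {
    f0 <- stats::lm(value ~ 0 + replication + cycle, data = data,
                    weights = w)
    f1 <- stats::lm(value ~ 0 + replication + replication:cycle,
                    data = data, weights = w)
    n <- sum(w)  # effective observations (sum of weights)
    rss0 <- sum(w * stats::residuals(f0)^2)
    rss1 <- sum(w * stats::residuals(f1)^2)
    stat <- max(0, n * log(rss0 / rss1))
    dfq <- length(reps) - 1
    lrt <- list(statistic = stat, df = dfq,
                p = stats::pchisq(stat, dfq, lower.tail = FALSE))
  }
  structure(list(slopes = slopes, lrt = lrt, n = nrow(data)),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("<response_fit>\n")
  print(x$slopes, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat(sprintf("equal-slope LRT: chi2 = %.3f (df %d), p = %.4f\n",
                x$lrt$statistic, x$lrt$df, x$lrt$p))
  }
  invisible(x)
}

#' Express values in units of the base-cycle standard deviation
#'
#' `(value - mean(c0)) / sd`, where `sd` defaults to the (sample)
#' standard deviation of the base-cycle values; for realized means, pass
#' the genetic standard deviation of the random base-cycle sample via
#' `sd` (square root of its genetic variance component).
#'
#' @param values Numeric vector to standardize.
#' @param c0_values Base-cycle values defining the origin (and default
#'   scale).
#' @param sd Optional explicit divisor.
#' @return Standardized values.
#' @export
standardize_to_c0 <- function(values, c0_values, sd = NULL) {
  if (is.null(sd)) sd <- stats::sd(c0_values)
  (values - mean(c0_values)) / sd
}

#' Prediction ability and accuracy
#'
#' Ability is the Pearson correlation between GEBVs and adjusted entry
#' means; accuracy divides the ability by the square root of the trait
#' heritability and may exceed 1 (reported as computed).
#'
#' @param gebvs,adjusted_means Paired numeric vectors (matched ids).
#' @param h2 Entry-mean heritability in (0, 1].
#' @return List with `ability`, `accuracy`, `h2`, `n`.
#' @export
prediction_accuracy <- function(gebvs, adjusted_means, h2) {
  stopifnot(length(gebvs) == length(adjusted_means), h2 > 0, h2 <= 1)
  ok <- !is.na(gebvs) & !is.na(adjusted_means)
  if (sum(ok) < 3) stop("need >= 3 paired observations")
  r <- stats::cor(gebvs[ok], adjusted_means[ok])
  list(ability = r, accuracy = r / sqrt(h2), h2 = h2, n = sum(ok))
}

#' Combine training sets across eras via common checks
#'
#' Each era's means are shifted by (reference-era check mean - era check
#' mean) so the common checks agree with the reference era; entry
#' differences within an era are preserved. After shifting, the eras are
#' concatenated; genotypes present in several eras keep their newest
#' record (later list elements are newer).
#'
#' @param training_sets List of data.frames with columns `genotype`,
#'   `value`; ordered oldest to newest. The first element is the
#'   reference era.
#' @param check_ids Genotype ids of the common checks.
#' @return Combined data.frame (genotype, value, era).
#' @export
retrain <- function(training_sets, check_ids) {
  stopifnot(length(training_sets) >= 1)
  ref <- training_sets[[1]]
  ref_checks <- ref$value[ref$genotype %in% check_ids]
  if (length(ref_checks) == 0) stop("no common checks in reference era")
  ref_mean <- mean(ref_checks)
  shifted <- lapply(seq_along(training_sets), function(k) {
    d <- training_sets[[k]]
    ck <- d$value[d$genotype %in% check_ids]
    if (length(ck) == 0) stop(sprintf("era %d shares no checks", k))
    d$value <- d$value + (ref_mean - mean(ck))
    d$era <- k
    d
  })
  comb <- do.call(rbind, shifted)
  # newest record wins: reverse, keep first occurrence, restore order
  comb <- comb[rev(seq_len(nrow(comb))), ]
  comb <- comb[!duplicated(comb$genotype), ]
  comb[order(comb$era, comb$genotype), c("genotype", "value", "era")]
}

#' Bootstrap comparison of prediction abilities
#'
#' Resamples with replacement `B` times; per resample, the difference of
#' Pearson abilities (cor(gebv, mean)) between the two prediction sets is
#' recorded. In `"paired"` mode both sets are resampled with the same
#' indices (they must contain the same ids in the same order, e.g. one
#' population phenotyped in two eras); in `"independent"` mode each set
#' is resampled separately. The difference is declared significant when
#' zero lies outside the interval spanned by the 2.5% and 97.5% empirical
#' quantiles.
#'
#' @param set_a,set_b data.frames with columns `gebv`, `mean` (and `id`
#'   for paired mode).
#' @param mode "paired" or "independent".
#' @param B Number of bootstrap resamples (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @return Object of class `bootstrap_result`: `difference` (point
#'   estimate a - b), `quantiles` (2.5%, 97.5%), `significant`, `B`,
#'   `seed`.
#' @export
bootstrap_compare <- function(set_a, set_b,
                              mode = c("paired", "independent"),
                              B = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  if (B < 100) warning("B < 100 gives unstable quantiles")
  na <- nrow(set_a); nb <- nrow(set_b)
  if (na < 5 || nb < 5) stop("need >= 5 observations per set")
  if (mode == "paired") {
    if (na != nb) stop("paired mode requires equal-size sets")
    if (!is.null(set_a$id) && !is.null(set_b$id) &&
        !identical(as.character(set_a$id), as.character(set_b$id))) {
      stop("paired mode requires identical ids in both sets")
    }
  }
  set.seed(seed)
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    if (mode == "paired") {
      i <- sample.int(na, na, replace = TRUE)
      ra <- stats::cor(set_a$gebv[i], set_a$mean[i])
      rb <- stats::cor(set_b$gebv[i], set_b$mean[i])
    } else {
      i <- sample.int(na, na, replace = TRUE)
      j <- sample.int(nb, nb, replace = TRUE)
      ra <- stats::cor(set_a$gebv[i], set_a$mean[i])
      rb <- stats::cor(set_b$gebv[j], set_b$mean[j])
    }
    diffs[b] <- ra - rb
  }
  q <- stats::quantile(diffs, c(0.025, 0.975), na.rm = TRUE)
  structure(list(difference = stats::cor(set_a$gebv, set_a$mean) -
                   stats::cor(set_b$gebv, set_b$mean),
                 quantiles = q,
                 significant = q[1] > 0 || q[2] < 0,
                 B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> diff = %.3f, 95%% interval [%.3f, %.3f], %s\n",
    x$difference, x$quantiles[1], x$quantiles[2],
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Per-population trait correlations with Holm adjustment
#'
#' Pearson correlations among trait columns computed within each
#' population; the Bonferroni-Holm step-down correction is applied
#' across the whole family of tested pairs.
#'
#' @param means data.frame with a `population` column and trait columns.
#' @param traits Trait column names (default: all numeric columns except
#'   `population`).
#' @return data.frame (population, trait_a, trait_b, r, p, p_adj).
#' @export
trait_correlations <- function(means, traits = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(names(means)[vapply(means, is.numeric,
                                          logical(1))], "population")
  }
  rows <- list()
  for (pp in unique(means$population)) {
    d <- means[means$population == pp, traits, drop = FALSE]
    cmb <- utils::combn(traits, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ct <- stats::cor.test(d[[a]], d[[b]])
      rows[[length(rows) + 1]] <- data.frame(
        population = pp, trait_a = a, trait_b = b,
        r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Holm step-down adjustment (explicit helper)
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values (equals `p.adjust(p, "holm")`).
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
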