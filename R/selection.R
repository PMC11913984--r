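#' Center and scale GEBVs over a candidate set
#'
#' Mean-centers and scales by the population standard deviation (divisor
#' n, not n - 1) so that the scaled values have exactly mean 0 and SD 1
#' over the candidate set. Affine transformations of the input leave the
#' result unchanged.
#'
#' @param x Numeric vector (one trait's GEBVs over the candidate set) or
#'   a matrix with one column per trait.
#' @return Same shape as `x`, scaled per trait.
#' @export
scale_gebvs <- function(x) {
  scale1 <- function(v, nm) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) {
      stop(sprintf("trait %s has zero standard deviation; cannot scale", nm))
    }
    (v - mean(v)) / s
  }
  if (is.matrix(x)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- scale1(x[, j], nm[j])
    out
  } else {
    scale1(x, "1")
  }
}

#' Stabilizing transform for final plant height
#'
#' `PH_trans_i = max_j(g_j) - |g_i|` on scaled GEBVs `g`: candidates near
#' the population mean (scaled value near 0) score highest, implementing
#' stabilizing selection. The additive constant (`max` of the scaled
#' values by default, or of their absolute values) shifts all scores
#' equally, so the ranking of the selection criterion does not depend on
#' the convention; reported values do.
#'
#' @param scaled_ph Scaled GEBVs for final height over the candidate set.
#' @param max_of_abs If `TRUE` use `max(|g|)` instead of `max(g)` as the
#'   additive constant.
#' @return Numeric vector of non-negative transformed values (under the
#'   `max_of_abs = TRUE` convention; the default convention can yield
#'   slightly negative values when `max(g) < max(|g|)`).
#' @export
ph_trans <- function(scaled_ph, max_of_abs = FALSE) {
  if (length(scaled_ph) == 0) stop("empty candidate set")
  cst <- if (max_of_abs) max(abs(scaled_ph)) else max(scaled_ph)
  cst - abs(scaled_ph)
}

#' Multi-trait selection criterion
#'
#' `SC_i = PH_V4_i + PH_V6_i + 2 * PH_trans_i` on scaled GEBVs: equal
#' weight on directional selection for the two early-height stages and
#' double weight on stabilizing selection for final height.
#'
#' @param scaled_v4,scaled_v6 Scaled GEBVs of the two early-height traits.
#' @param ph_trans_vals Transformed final-height values from [ph_trans()].
#' @param weights Length-3 weights (default `c(1, 1, 2)`).
#' @return Numeric vector of SC values.
#' @export
selection_criterion <- function(scaled_v4, scaled_v6, ph_trans_vals,
                                weights = c(1, 1, 2)) {
  stopifnot(length(scaled_v4) == length(scaled_v6),
            length(scaled_v6) == length(ph_trans_vals),
            length(weights) == 3)
  weights[1] * scaled_v4 + weights[2] * scaled_v6 +
    weights[3] * ph_trans_vals
}

#' Rank candidates by selection criterion
#'
#' Ties in SC are broken by candidate id (lexicographic), making the
#' ranking deterministic.
#'
#' @param sc Numeric SC values.
#' @param ids Candidate ids.
#' @return data.frame (id, sc, rank) ordered by rank (1 = best).
#' @export
rank_candidates <- function(sc, ids) {
  stopifnot(length(sc) == length(ids))
  ord <- order(-sc, ids)
  data.frame(id = ids[ord], sc = sc[ord], rank = seq_along(sc),
             stringsAsFactors = FALSE)
}

#' Truncation selection with per-founder contribution cap
#'
#' Walks the ranking from the top; a candidate is skipped when adding it
#' would push the selected count of any of its founder ancestors above
#' `cap`. Continues until `n_select` candidates are taken or the list is
#' exhausted (a shortfall is reported via attribute `"shortfall"`).
#'
#' @param ranked data.frame from [rank_candidates()] (columns id, rank).
#' @param n_select Number of candidates to select.
#' @param cap Maximum selected candidates per founder lineage; `Inf`
#'   disables the cap.
#' @param founder_sets Named list (by candidate id) of character vectors
#'   of founder-ancestor ids; required when `cap` is finite.
#' @return Character vector of selected ids, in rank order, with
#'   attributes `"shortfall"` and `"contributions"`.
#' @export
select_top <- function(ranked, n_select, cap = Inf, founder_sets = NULL) {
  stopifnot(n_select <= nrow(ranked))
  if (is.finite(cap)) {
    if (is.null(founder_sets)) stop("founder_sets required with finite cap")
    founders_all <- unique(unlist(founder_sets[ranked$id]))
    if (cap * length(founders_all) < n_select) {
      stop(sprintf(
        "infeasible: cap %d x %d founders < %d to select",
        cap, length(founders_all), n_select))
    }
    counts <- stats::setNames(rep(0L, length(founders_all)), founders_all)
  }
  sel <- character(0)
  for (i in seq_len(nrow(ranked))) {
    if (length(sel) >= n_select) break
    cand <- ranked$id[i]
    if (is.finite(cap)) {
      fs <- founder_sets[[cand]]
      if (any(counts[fs] + 1L > cap)) next
      counts[fs] <- counts[fs] + 1L
    }
    sel <- c(sel, cand)
  }
  shortfall <- n_select - length(sel)
  if (shortfall > 0) {
    warning(sprintf("selection shortfall: %d candidates missing", shortfall))
  }
  attr(sel, "shortfall") <- shortfall
  if (is.finite(cap)) attr(sel, "contributions") <- counts
  sel
}

#' Split a ranked selection into two founder sets by even and odd ranks
#'
#' Odd ranks (1st, 3rd, ...) seed replication 1, even ranks replication 2
#' (a fixed convention). For `k` selected, sizes are `ceiling(k/2)` and
#' `floor(k/2)`.
#'
#' @param ids Selected ids in rank order.
#' @return List with elements `R1` and `R2`.
#' @export
split_even_odd <- function(ids) {
  k <- length(ids)
  idx <- seq_len(k)
  list(R1 = ids[idx %% 2 == 1], R2 = ids[idx %% 2 == 0])
}

#' Pair selected individuals to maximize modified Rogers' distance
#'
#' Greedy matching: repeatedly take the unused pair with the largest MRD
#' (ties broken by ids), using each individual at most once, until
#' `n_pairs` pairs are formed. The paper-level objective (pairs with high
#' MRD between parents) is stated without an algorithm; greedy matching
#' is the implemented convention, with exhaustive matching available as a
#' test oracle for small sets.
#'
#' @param dmat Symmetric MRD matrix with dimnames = individual ids (e.g.
#'   from [mrd_matrix()] on `genotypes(pop)/2`).
#' @param n_pairs Number of pairs (2 * n_pairs <= individuals).
#' @return data.frame (parent_a, parent_b, mrd) with attribute
#'   `"total_mrd"`.
#' @export
pair_by_mrd <- function(dmat, n_pairs) {
  dmat <- as.matrix(dmat)
  ids <- rownames(dmat)
  n <- nrow(dmat)
  if (n < 2) stop("need at least 2 candidates to pair")
  stopifnot(2 * n_pairs <= n)
  used <- rep(FALSE, n)
  out <- vector("list", n_pairs)
  # enumerate pairs ordered by decreasing distance, id tie-break
  comb <- which(upper.tri(dmat), arr.ind = TRUE)
  ord <- order(-dmat[comb], ids[comb[, 1]], ids[comb[, 2]])
  comb <- comb[ord, , drop = FALSE]
  k <- 0L
  for (r in seq_len(nrow(comb))) {
    if (k >= n_pairs) break
    i <- comb[r, 1]; j <- comb[r, 2]
    if (used[i] || used[j]) next
    k <- k + 1L
    used[i] <- used[j] <- TRUE
    out[[k]] <- data.frame(parent_a = ids[i], parent_b = ids[j],
                           mrd = dmat[i, j], stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, out)
  attr(plan, "total_mrd") <- sum(plan$mrd)
  plan
}

# exhaustive perfect-matching oracle for small candidate sets (n <= 12)
best_matching_exhaustive <- function(dmat, n_pairs) {
  ids <- rownames(dmat)
  n <- nrow(dmat)
  stopifnot(n <= 12)
  best <- list(total = -Inf, pairs = NULL)
  rec <- function(avail, pairs, total) {
    if (length(pairs) == n_pairs) {
      if (total > best$total) best <<- list(total = total, pairs = pairs)
      return(invisible())
    }
    if (length(avail) < 2 * (n_pairs - length(pairs))) return(invisible())
    a <- avail[1]
    # either a is unused...
    rec(avail[-1], pairs, total)
    # ...or paired with any other available individual
    for (b in avail[-1]) {
      rec(setdiff(avail, c(a, b)), c(pairs, list(c(a, b))),
          total + dmat[a, b])
    }
  }
  rec(seq_len(n), list(), 0)
  data.frame(parent_a = ids[sapply(best$pairs, `[`, 1)],
             parent_b = ids[sapply(best$pairs, `[`, 2)],
             mrd = sapply(best$pairs, function(p) dmat[p[1], p[2]]),
             stringsAsFactors = FALSE)
}
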