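#' Default configuration for the rapid-cycling selection scheme
#'
#' The defaults encode the reference experiment's structure: a base
#' population of 402 DH lines derived from individual landrace S0
#' plants; 20 founder lines selected on the multi-trait criterion and
#' split by even/odd rank into two replications of 10; per replication a
#' diallel (45 families) selfed once to ~1000 S1 plants; ~40 S1 plants
#' selected (contribution cap 15 per founder line) and mated in 20
#' distance-maximizing pairs to ~1000 S0 plants; ~30 selected and mated
#' in 15 pairs; 100 DH lines extracted per cycle plus a random base-
#' cycle sample of 105. The genetic map (10 chromosomes x 500 markers)
#' and trait architecture (300 QTL, correlated early/final height plus
#' uncorrelated flowering) stand in for the experiment's 11 k SNP set
#' and are desk-scale choices, not estimates.
#'
#' @param scale Shrinks the large population sizes (`n_s1`, `n_s0`,
#'   `n_dh`) by this factor for fast smoke runs; 1 = full default.
#' @param ... Named overrides of any config entry.
#' @return Named list of configuration values.
#' @export
default_scheme_config <- function(scale = 1, ...) {
  cfg <- list(
    n_chrom = 10L, markers_per_chrom = 500L, chrom_length_cM = 160,
    n_landrace = 402L, maf_beta = c(1, 1),
    n_qtl = 300L,
    target_corr = default_traits()$target_corr,
    trait_sds = default_traits()$trait_sds,
    sel_traits = c("PH_V4", "PH_V6", "PH"),
    ff_trait = "FF",
    h2_train = 0.7,
    n_c0 = 402L, n_c0r = 105L, n_sel_c0 = 20L,
    n_s1 = max(2L, round(1000 / scale)),
    n_sel_s1 = 40L, cap_per_founder = 15L, n_pairs_c1 = 20L,
    n_s0 = max(2L, round(1000 / scale)),
    n_sel_s0 = 30L, n_pairs_c2 = 15L,
    n_dh = max(2L, round(100 / scale)),
    weights = c(1, 1, 2),
    criterion = "sc",            # "sc" or "early_only" (no stabilizing term)
    ph_trans_max_abs = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$n_sel_c0 %% 2 == 0, cfg$n_c0 <= cfg$n_landrace)
  cfg
}

# selection criterion over a candidate GEBV matrix
compute_sc <- function(gebv, cfg) {
  sv4 <- scale_gebvs(gebv[, cfg$sel_traits[1]])
  sv6 <- scale_gebvs(gebv[, cfg$sel_traits[2]])
  if (identical(cfg$criterion, "early_only")) {
    return(sv4 + sv6)
  }
  sph <- scale_gebvs(gebv[, cfg$sel_traits[3]])
  pt <- ph_trans(sph, max_of_abs = isTRUE(cfg$ph_trans_max_abs))
  selection_criterion(sv4, sv6, pt, cfg$weights)
}

# predict all traits (multi-trait selection traits + single-trait FF)
predict_gebvs <- function(fit_mt, fit_ff, geno_train, geno_new, ref_freqs) {
  Kx <- cross_grm(geno_train, geno_new, ref_freqs)
  out <- predict_unphenotyped(fit_mt, Kx)
  ff <- predict_unphenotyped(fit_ff, Kx)
  cbind(out, FF = ff)
}

founder_sets_of <- function(pop) {
  stats::setNames(strsplit(pop$info$founders, ";"), pop$info$id)
}

#' Run the rapid-cycling genomic selection scheme
#'
#' Executes the full scheme: simulate the landrace and its DH base
#' population, train the multi-trait GBLUP model once on base-population
#' phenotypes, select founder lines on the selection criterion, split
#' them even/odd into two replications, and per replication run diallel
#' + selfing to S1, genomic selection of S1 (contribution-capped),
#' distance-maximizing pair mating to S0, a second round of genomic
#' selection and pairing, and DH extraction from every cycle. The
#' prediction model is never refit between cycles; candidate GEBVs come
#' from the realized relationship between training set and candidates.
#' All randomness derives from the master seed through per-stage
#' sub-seeds.
#'
#' @param config Configuration list from [default_scheme_config()].
#' @param seed Master seed.
#' @return Object of class `scheme_result`: the map, architecture,
#'   populations (named list including the 14 reporting populations),
#'   per-population GEBV matrices (base-population allele-frequency
#'   anchoring), training fits, selections, mating plans, config, seed,
#'   and a stage log.
#' @export
run_scheme <- function(config = default_scheme_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 40L)
  log <- list()
  stage <- function(name, s) {
    log[[name]] <<- list(seed = s, time = format(Sys.time()))
    set.seed(s)
  }

  map <- make_genetic_map(cfg$n_chrom, cfg$markers_per_chrom,
                          cfg$chrom_length_cM, seed = ss[1])
  founders <- simulate_founders(map, cfg$n_landrace, cfg$maf_beta,
                                seed = ss[2])
  arch <- assign_architecture(map, cfg$n_qtl, cfg$target_corr,
                              cfg$trait_sds, allele_freqs(founders),
                              seed = ss[3])
  traits <- arch$trait_names

  stage("c0_dh", ss[4])
  c0 <- extract_dh(founders, cfg$n_c0, population = "C0", prefix = "C0")
  if (pop_size(c0) == 0) stop("stage C0: zero survivors")
  geno_c0 <- genotypes(c0)
  p_c0 <- colMeans(geno_c0) / 2
  K_c0 <- suppressWarnings(vanraden_grm(geno_c0, p_c0))
  tbv_c0 <- true_breeding_values(c0, arch)

  # training phenotypes: adjusted-mean analogues at entry-mean h2
  stage("train_pheno", ss[5])
  Y <- tbv_c0
  for (tt in traits) {
    noise_sd <- stats::sd(tbv_c0[, tt]) *
      sqrt((1 - cfg$h2_train) / cfg$h2_train)
    Y[, tt] <- tbv_c0[, tt] + stats::rnorm(nrow(Y), 0, noise_sd)
  }
  fit_mt <- fit_gblup_multitrait(Y[, cfg$sel_traits], K = K_c0)
  fit_ff <- fit_gblup(Y[, cfg$ff_trait], K = K_c0)
  gebv_c0 <- cbind(fit_mt$gebv, FF = fit_ff$gebv)
  colnames(gebv_c0) <- c(cfg$sel_traits, cfg$ff_trait)

  # base-cycle selection (no contribution cap: founders assumed unrelated)
  sc0 <- compute_sc(gebv_c0, cfg)
  ranked0 <- rank_candidates(sc0, c0$info$id)
  c0sel_ids <- select_top(ranked0, cfg$n_sel_c0)
  halves <- split_even_odd(c0sel_ids)

  stage("c0r", ss[6])
  c0r_ids <- sample(c0$info$id, cfg$n_c0r)

  pops <- list(C0 = c0, C0r = subset_population(c0, c0r_ids))
  gebvs <- list(C0 = gebv_c0, C0r = gebv_c0[c0r_ids, , drop = FALSE])
  selections <- list(C0sel = c0sel_ids)
  plans <- list()

  for (r in 1:2) {
    rl <- paste0("R", r)
    fnd <- subset_population(c0, halves[[rl]])
    # the selected DH lines become the lineage units for contribution caps
    fnd$info$founders <- fnd$info$id
    pops[[paste0("C0sel-", rl)]] <- fnd
    gebvs[[paste0("C0sel-", rl)]] <-
      gebv_c0[halves[[rl]], , drop = FALSE]

    # cycle 1: diallel + selfing -> S1, genomic selection with cap
    stage(paste0(rl, "_s1"), ss[10 + r])
    s1 <- diallel(fnd, cfg$n_s1, population = paste0("C1-S1-", rl))
    if (pop_size(s1) == 0) stop("stage C1-S1: zero survivors")
    g_s1 <- predict_gebvs(fit_mt, fit_ff, geno_c0, genotypes(s1), p_c0)
    colnames(g_s1) <- colnames(gebv_c0)
    pops[[paste0("C1-S1-", rl)]] <- s1
    gebvs[[paste0("C1-S1-", rl)]] <- g_s1
    sc1 <- compute_sc(g_s1, cfg)
    sel1 <- select_top(rank_candidates(sc1, s1$info$id), cfg$n_sel_s1,
                       cap = cfg$cap_per_founder,
                       founder_sets = founder_sets_of(s1))
    selections[[paste0("C1-S1sel-", rl)]] <- sel1
    sel1_pop <- subset_population(s1, sel1)

    stage(paste0(rl, "_pairs_c1"), ss[14 + r])
    plan1 <- pair_by_mrd(mrd_matrix(genotypes(sel1_pop) / 2),
                         cfg$n_pairs_c1)
    plans[[paste0("C1-", rl)]] <- plan1

    # cycle 2: pair crosses -> S0, second genomic selection (no cap)
    stage(paste0(rl, "_s0"), ss[18 + r])
    s0 <- cross_pairs(sel1_pop, plan1, cfg$n_s0,
                      population = paste0("C2-S0-", rl))
    if (pop_size(s0) == 0) stop("stage C2-S0: zero survivors")
    g_s0 <- predict_gebvs(fit_mt, fit_ff, geno_c0, genotypes(s0), p_c0)
    colnames(g_s0) <- colnames(gebv_c0)
    pops[[paste0("C2-S0-", rl)]] <- s0
    gebvs[[paste0("C2-S0-", rl)]] <- g_s0
    sc2 <- compute_sc(g_s0, cfg)
    sel2 <- select_top(rank_candidates(sc2, s0$info$id), cfg$n_sel_s0)
    selections[[paste0("C2-S0sel-", rl)]] <- sel2
    sel2_pop <- subset_population(s0, sel2)

    stage(paste0(rl, "_pairs_c2"), ss[22 + r])
    plan2 <- pair_by_mrd(mrd_matrix(genotypes(sel2_pop) / 2),
                         cfg$n_pairs_c2)
    plans[[paste0("C2-", rl)]] <- plan2

    stage(paste0(rl, "_c3"), ss[26 + r])
    c3 <- cross_pairs(sel2_pop, plan2, cfg$n_s0,
                      population = paste0("C3-S0-", rl))
    pops[[paste0("C3-S0-", rl)]] <- c3

    # DH extraction from every cycle
    stage(paste0(rl, "_dh"), ss[30 + r])
    for (cyc in 1:3) {
      src <- switch(cyc, s1, s0, c3)
      nm <- sprintf("C%d-DH-%s", cyc, rl)
      dh <- extract_dh(src, cfg$n_dh, population = nm, prefix = nm)
      g_dh <- predict_gebvs(fit_mt, fit_ff, geno_c0, genotypes(dh), p_c0)
      colnames(g_dh) <- colnames(gebv_c0)
      pops[[nm]] <- dh
      gebvs[[nm]] <- g_dh
    }
  }

  structure(list(map = map, arch = arch, founders = founders,
                 populations = pops, gebvs = gebvs,
                 selections = selections, plans = plans,
                 fit_mt = fit_mt, fit_ff = fit_ff,
                 train_pheno = Y, tbv_c0 = tbv_c0, c0_freqs = p_c0,
                 c0r_ids = c0r_ids, config = cfg, seed = seed,
                 log = log),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat("<scheme_result> populations:\n")
  for (nm in names(x$populations)) {
    cat(sprintf("  %-12s n = %d\n", nm, pop_size(x$populations[[nm]])))
  }
  invisible(x)
}

#' The 14 reporting populations of a scheme run
#'
#' @param scheme A `scheme_result`.
#' @return Character vector of the 14 population names (base population,
#'   its random sample, and per replication the founder set, the two
#'   heterozygous selection-unit populations and the three DH sets).
#' @export
reporting_populations <- function(scheme) {
  c("C0", "C0r",
    as.vector(outer(c("C0sel", "C1-S1", "C2-S0",
                      "C1-DH", "C2-DH", "C3-DH"),
                    c("R1", "R2"), paste, sep = "-")))
}

#' Summary tables of a scheme run
#'
#' Builds the reporting layer: mean GEBVs per population and trait
#' (anchored so the base population's mean GEBV is zero by the
#' allele-frequency convention), per-cycle selection-response slopes for
#' the heterozygous selection units (two cycles) and the DH sets (three
#' cycles) within each replication with one-sided significance, and the
#' DH slopes expressed in units of the base population's GEBV standard
#' deviation.
#'
#' @param scheme A `scheme_result`.
#' @param alpha Significance level for slope stars.
#' @param outdir Optional directory; if given, tables are written as CSV.
#' @return List with `mean_gebv`, `slopes`, `sd_units` data.frames.
#' @export
report_tables <- function(scheme, alpha = 0.05, outdir = NULL) {
  traits <- colnames(scheme$gebvs$C0)
  pops14 <- reporting_populations(scheme)
  rows <- lapply(pops14, function(nm) {
    g <- scheme$gebvs[[nm]]
    data.frame(population = nm, N = nrow(g),
               t(colMeans(g)), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  mean_gebv <- do.call(rbind, rows)

  slope_rows <- list()
  for (set in c("S", "DH")) {
    cyc_pops <- if (set == "S") {
      c("C1-S1" = 1, "C2-S0" = 2)
    } else {
      c("C1-DH" = 1, "C2-DH" = 2, "C3-DH" = 3)
    }
    for (tt in traits) {
      dat <- do.call(rbind, lapply(names(cyc_pops), function(pp) {
        do.call(rbind, lapply(c("R1", "R2"), function(rl) {
          g <- scheme$gebvs[[paste(pp, rl, sep = "-")]]
          data.frame(value = g[, tt], cycle = cyc_pops[[pp]],
                     replication = rl)
        }))
      }))
      fit <- response_regression(dat)
      for (k in seq_len(nrow(fit$slopes))) {
        slope_rows[[length(slope_rows) + 1]] <- data.frame(
          set = set, trait = tt,
          replication = fit$slopes$replication[k],
          slope = fit$slopes$slope[k], p = fit$slopes$p[k],
          significant = fit$slopes$p[k] < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  slopes <- do.call(rbind, slope_rows)

  sd_c0 <- apply(scheme$gebvs$C0, 2, stats::sd)
  dh <- slopes[slopes$set == "DH", ]
  sd_units <- data.frame(trait = dh$trait, replication = dh$replication,
                         slope_sd_units = dh$slope / sd_c0[dh$trait],
                         stringsAsFactors = FALSE)

  out <- list(mean_gebv = mean_gebv, slopes = slopes, sd_units = sd_units)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(mean_gebv, file.path(outdir, "mean_gebv.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes, file.path(outdir, "slopes.csv"),
                     row.names = FALSE)
    utils::write.csv(sd_units, file.path(outdir, "slopes_sd_units.csv"),
                     row.names = FALSE)
  }
  out
}
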