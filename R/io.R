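#' Write genotypes to disk
#'
#' Two plain-text formats: a phased diploid VCF 4.2 (haplotypes preserved
#' in the GT field) or a tab-separated 0/1/2 matrix (individuals x
#' markers, with ids).
#'
#' @param pop An `rg_pop` (for VCF; haplotypes required) or, for
#'   `format = "matrix"`, either an `rg_pop` or a 0/1/2 matrix with
#'   dimnames.
#' @param path Output file path.
#' @param format "vcf" or "matrix".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    g <- if (inherits(pop, "rg_pop")) genotypes(pop) else as.matrix(pop)
    df <- data.frame(id = rownames(g), g, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(pop, "rg_pop"))
  mk <- pop$map$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rapidgs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- pop$info$id
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", ids), collapse = "\t"),
             con)
  # genetic-map positions carried as integer 0.01 cM units
  pos <- as.integer(round(mk$pos_cM * 100)) + 1L
  for (j in seq_len(nrow(mk))) {
    gt <- paste0(pop$h1[, j], "|", pop$h2[, j])
    writeLines(paste(c(mk$chrom[j], pos[j], mk$marker[j], "A", "T", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from disk
#'
#' `format = "matrix"` reads the tab-separated 0/1/2 matrix written by
#' [write_genotypes()]. `format = "vcf"` reads a diploid VCF via
#' VariantAnnotation and returns 0/1/2 dosages plus, for phased records,
#' the two haplotype matrices.
#'
#' @param path Input file.
#' @param format "vcf" or "matrix".
#' @return List with `geno` (n x m matrix, 0/1/2), `ids`, `markers`, and
#'   for phased VCF input `h1`, `h2`.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    g <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(g) <- "integer"
    rownames(g) <- df$id
    if (any(!g %in% 0:2)) stop("matrix genotypes must be coded 0/1/2")
    return(list(geno = g, ids = df$id, markers = colnames(g)))
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  gt <- VariantAnnotation::readGT(path)
  ids <- colnames(gt)
  markers <- rownames(gt)
  parse_one <- function(x, line) {
    sp <- strsplit(x, "[|/]")
    lens <- lengths(sp)
    if (any(lens != 2)) {
      stop(sprintf("malformed or non-diploid GT at line %d",
                   line[which(lens != 2)[1]]))
    }
    al <- suppressWarnings(
      matrix(as.integer(unlist(sp)), nrow = 2))
    if (anyNA(al) || any(al > 1)) {
      stop(sprintf("unknown or multi-allelic allele code at line %d",
                   line[which(colSums(is.na(al) | al > 1) > 0)[1]]))
    }
    al
  }
  m <- nrow(gt); n <- ncol(gt)
  h1 <- matrix(0L, n, m, dimnames = list(ids, markers))
  h2 <- matrix(0L, n, m, dimnames = list(ids, markers))
  phased <- TRUE
  for (j in seq_len(m)) {
    al <- parse_one(gt[j, ], rep(j, n))
    h1[, j] <- al[1, ]
    h2[, j] <- al[2, ]
    if (any(!grepl("|", gt[j, ], fixed = TRUE))) phased <- FALSE
  }
  out <- list(geno = h1 + h2, ids = ids, markers = markers)
  if (phased) {
    out$h1 <- h1
    out$h2 <- h2
  }
  out
}

#' Write/read plot-level phenotypes as CSV
#'
#' Column layout: genotype, population, environment, replication, block,
#' plant_count, then one column per trait.
#'
#' @param records Plot-record data.frame.
#' @param path CSV path.
#' @return `path` (write) / the records with the `traits` attribute
#'   restored (read).
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("genotype", "population", "environment", "replication",
                 "block", "plant_count")
  missing <- setdiff(base_cols, names(rec))
  if (length(missing)) {
    stop("phenotype CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  attr(rec, "traits") <- setdiff(names(rec), base_cols)
  rec
}

#' Intersect two marker sets
#'
#' Returns the ordered common markers and the overlap fraction relative
#' to the smaller set (documented convention).
#'
#' @param set_a,set_b Character vectors of marker ids.
#' @return List with `common` (in `set_a` order) and `fraction`.
#' @export
intersect_markers <- function(set_a, set_b) {
  common <- set_a[set_a %in% set_b]
  frac <- length(common) / min(length(set_a), length(set_b))
  if (length(common) == 0) warning("marker sets are disjoint")
  list(common = common, fraction = frac)
}

#' Configuration serialization
#'
#' Round-trips a scheme configuration losslessly through JSON.
#'
#' @param config Configuration list.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  # named atomic vectors lose their names as JSON arrays; keep them as
  # objects by converting to named lists
  for (f in names(config)) {
    if (is.atomic(config[[f]]) && !is.null(names(config[[f]]))) {
      config[[f]] <- as.list(config[[f]])
    }
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("trait_sds", "maf_beta", "weights")) {
    if (!is.null(cfg[[f]]) && is.list(cfg[[f]])) {
      cfg[[f]] <- unlist(cfg[[f]])
    }
  }
  if (!is.null(cfg$target_corr)) {
    cfg$target_corr <- as.matrix(cfg$target_corr)
    dimnames(cfg$target_corr) <- list(names(cfg$trait_sds),
                                      names(cfg$trait_sds))
  }
  int_fields <- c("n_chrom", "markers_per_chrom", "n_landrace", "n_qtl",
                  "n_c0", "n_c0r", "n_sel_c0", "n_s1", "n_sel_s1",
                  "cap_per_founder", "n_pairs_c1", "n_s0", "n_sel_s0",
                  "n_pairs_c2", "n_dh")
  for (f in intersect(int_fields, names(cfg))) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  cfg
}

#' Structured run log
#'
#' Hashes the configuration (MD5 over its canonical JSON), derives
#' per-stage sub-seeds from the master seed, and records package version
#' and timestamps, so that reruns with the same (config, seed) reproduce
#' all outputs bit-identically.
#'
#' @param config Configuration list.
#' @param seed Master seed.
#' @param stages Stage names to pre-derive seeds for.
#' @return List with `config_hash`, `seed`, `stage_seeds`, `version`,
#'   `timestamp`.
#' @export
run_logger <- function(config, seed,
                       stages = c("map", "founders", "architecture",
                                  "training", "selection", "mating",
                                  "dh_extraction", "trial")) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  set.seed(seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(stages)), stages)
  list(config_hash = hash, seed = seed, stage_seeds = stage_seeds,
       version = as.character(utils::packageVersion("rapidgs")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
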