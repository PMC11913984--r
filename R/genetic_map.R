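#' Create a random genetic map
#'
#' Places `markers_per_chrom` markers uniformly at random on each of
#' `n_chrom` chromosomes of length `chrom_length_cM` centimorgans and sorts
#' them by position. Marker positions are in genetic-map units (cM); no
#' physical map is represented.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Number of markers per chromosome (>= 2).
#' @param chrom_length_cM Chromosome length in centimorgans (> 0). Either a
#'   single value recycled over chromosomes or a vector of length `n_chrom`.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return An object of class `genetic_map`: a list with elements
#'   `chromosomes` (data.frame: `chrom`, `length_cM`) and `markers`
#'   (data.frame: `marker`, `chrom`, `pos_cM`, ordered by chromosome then
#'   position).
#' @examples
#' gm <- make_genetic_map(2, 10, 100, seed = 1)
#' head(gm$markers)
#' @export
make_genetic_map <- function(n_chrom, markers_per_chrom, chrom_length_cM,
                             seed = 1L) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2)
  if (any(chrom_length_cM <= 0)) {
    stop("chromosome lengths must be positive")
  }
  len <- rep_len(chrom_length_cM, n_chrom)
  set.seed(seed)
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(cc) {
    pos <- sort(stats::runif(markers_per_chrom, 0, len[cc]))
    data.frame(
      marker = sprintf("chr%d_m%d", cc, seq_len(markers_per_chrom)),
      chrom  = cc,
      pos_cM = pos,
      stringsAsFactors = FALSE
    )
  }))
  rownames(markers) <- NULL
  out <- list(
    chromosomes = data.frame(chrom = seq_len(n_chrom), length_cM = len),
    markers = markers
  )
  class(out) <- "genetic_map"
  validate_genetic_map(out)
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d chromosomes, %d markers, total %.1f cM\n",
              nrow(x$chromosomes), nrow(x$markers),
              sum(x$chromosomes$length_cM)))
  invisible(x)
}

validate_genetic_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  mk <- map$markers
  if (anyDuplicated(mk$marker)) stop("marker ids must be unique")
  for (cc in map$chromosomes$chrom) {
    pos <- mk$pos_cM[mk$chrom == cc]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("marker positions must be non-decreasing within chromosome")
    }
    L <- map$chromosomes$length_cM[map$chromosomes$chrom == cc]
    if (any(pos < 0 | pos > L)) stop("marker position outside chromosome")
  }
  invisible(map)
}

n_markers <- function(map) nrow(map$markers)

# list of marker row indices per chromosome, in map order
map_chrom_index <- function(map) {
  split(seq_len(nrow(map$markers)), map$markers$chrom)
}
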