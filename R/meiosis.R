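#' Gamete formation under the Haldane model
#'
#' Crossover counts per chromosome are Poisson with mean `length_cM / 100`
#' (no interference), crossover positions are uniform, and the gamete is a
#' mosaic of the two parental haplotypes starting from a fair-coin choice
#' of strand. Markers at identical positions never recombine.
#'
#' @param h1,h2 Parental haplotype vectors (0/1, length = markers).
#' @param map The `genetic_map`.
#' @param chrom_index Optional precomputed `map_chrom_index(map)`.
#' @return Integer haplotype vector.
#' @export
gamete <- function(h1, h2, map, chrom_index = NULL) {
  if (is.null(chrom_index)) chrom_index <- map_chrom_index(map)
  out <- integer(length(h1))
  lens <- map$chromosomes$length_cM
  pos_all <- map$markers$pos_cM
  for (cc in seq_along(chrom_index)) {
    idx <- chrom_index[[cc]]
    start <- sample.int(2L, 1L)
    n_x <- stats::rpois(1L, lens[cc] / 100)
    if (n_x == 0L) {
      phase <- rep.int(start, length(idx))
    } else {
      xo <- sort(stats::runif(n_x, 0, lens[cc]))
      k <- findInterval(pos_all[idx], xo)
      phase <- 1L + (start - 1L + k) %% 2L
    }
    out[idx] <- ifelse(phase == 1L, h1[idx], h2[idx])
  }
  out
}

# internal: draw one gamete from individual i of pop
gamete_from <- function(pop, i, chrom_index) {
  gamete(pop$h1[i, ], pop$h2[i, ], pop$map, chrom_index)
}

join_founders <- function(a, b) {
  paste(sort(unique(c(strsplit(a, ";")[[1]], strsplit(b, ";")[[1]]))),
        collapse = ";")
}

#' Cross two individuals
#'
#' One gamete is drawn from each parent; the pedigree (mother, father) and
#' the union of the parents' founder-ancestor sets are recorded.
#'
#' @param mother,father `rg_pop` objects of size 1, or use `pop_a`/`i` via
#'   [subset_population()].
#' @param id Offspring id.
#' @param stage Stage label of the offspring (e.g. "F1", "S0").
#' @param population Population label.
#' @param family Family label (defaults to "mother x father").
#' @return An `rg_pop` with one individual.
#' @export
cross <- function(mother, father, id, stage = "S0",
                  population = NA_character_, family = NULL) {
  stopifnot(pop_size(mother) == 1, pop_size(father) == 1)
  ci <- map_chrom_index(mother$map)
  h1 <- gamete_from(mother, 1L, ci)
  h2 <- gamete_from(father, 1L, ci)
  if (is.null(family)) {
    family <- paste(mother$info$id, father$info$id, sep = "x")
  }
  info <- pop_info_frame(id, mother = mother$info$id,
                         father = father$info$id, stage = stage,
                         population = population, family = family,
                         founders = join_founders(mother$info$founders,
                                                  father$info$founders))
  new_population(matrix(h1, 1L), matrix(h2, 1L), info, mother$map)
}

#' Self-pollinate an individual
#'
#' Two independent gametes are drawn from the same parent.
#'
#' @inheritParams cross
#' @param parent `rg_pop` of size 1.
#' @export
self_cross <- function(parent, id, stage = "S1",
                       population = NA_character_, family = NULL) {
  stopifnot(pop_size(parent) == 1)
  ci <- map_chrom_index(parent$map)
  h1 <- gamete_from(parent, 1L, ci)
  h2 <- gamete_from(parent, 1L, ci)
  if (is.null(family)) family <- parent$info$family
  info <- pop_info_frame(id, mother = parent$info$id,
                         father = parent$info$id, stage = stage,
                         population = population, family = family,
                         founders = parent$info$founders)
  new_population(matrix(h1, 1L), matrix(h2, 1L), info, parent$map)
}

#' Doubled-haploid induction
#'
#' One gamete is drawn and its genome doubled; the offspring is fully
#' homozygous at every marker ("one meiosis away" from the parent).
#'
#' @inheritParams self_cross
#' @export
make_dh <- function(parent, id, population = NA_character_, family = NULL) {
  stopifnot(pop_size(parent) == 1)
  ci <- map_chrom_index(parent$map)
  h <- gamete_from(parent, 1L, ci)
  if (is.null(family)) family <- parent$info$family
  info <- pop_info_frame(id, mother = parent$info$id,
                         father = parent$info$id, stage = "DH",
                         population = population, family = family,
                         founders = parent$info$founders)
  new_population(matrix(h, 1L), matrix(h, 1L), info, parent$map)
}

# internal bulk versions (avoid per-offspring pop objects)

# n gametes from individual i: returns n x m integer matrix
gametes_bulk <- function(pop, i, n, chrom_index) {
  m <- ncol(pop$h1)
  out <- matrix(0L, n, m)
  for (k in seq_len(n)) out[k, ] <- gamete_from(pop, i, chrom_index)
  out
}

#' Diallel mating followed by one selfing to produce an S1 population
#'
#' All unordered founder pairs (no selfs, no reciprocals) are crossed to
#' one F1 plant per family; each F1 is then self-pollinated to produce S1
#' plants. `total_offspring` S1 plants are allocated as evenly as possible
#' across the `choose(n, 2)` families (sizes differ by at most one);
#' family ids record the founder pair.
#'
#' @param founders `rg_pop` with >= 2 individuals.
#' @param total_offspring Total number of S1 plants.
#' @param population Population label for the offspring.
#' @return An `rg_pop` of S1 plants.
#' @export
diallel <- function(founders, total_offspring, population = "S1") {
  n <- pop_size(founders)
  if (n < 2) stop("diallel requires at least 2 founders")
  pairs <- utils::combn(n, 2)
  n_fam <- ncol(pairs)
  sizes <- rep(total_offspring %/% n_fam, n_fam)
  extra <- total_offspring %% n_fam
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ci <- map_chrom_index(founders$map)
  m <- ncol(founders$h1)
  h1 <- matrix(0L, total_offspring, m)
  h2 <- matrix(0L, total_offspring, m)
  infos <- vector("list", n_fam)
  row <- 0L
  for (f in seq_len(n_fam)) {
    a <- pairs[1, f]; b <- pairs[2, f]
    # one F1 plant per family
    f1_h1 <- gamete_from(founders, a, ci)
    f1_h2 <- gamete_from(founders, b, ci)
    fam <- paste(founders$info$id[a], founders$info$id[b], sep = "x")
    f1_id <- paste0("F1_", fam)
    founders_set <- join_founders(founders$info$founders[a],
                                  founders$info$founders[b])
    k <- sizes[f]
    if (k > 0) {
      for (s in seq_len(k)) {
        row <- row + 1L
        # selfing the F1: two independent gametes from the F1 plant
        h1[row, ] <- gamete(f1_h1, f1_h2, founders$map, ci)
        h2[row, ] <- gamete(f1_h1, f1_h2, founders$map, ci)
      }
      ids <- sprintf("%s_%s_p%03d", population, fam, seq_len(k))
      infos[[f]] <- pop_info_frame(ids, mother = f1_id, father = f1_id,
                                   stage = "S1", population = population,
                                   family = fam, founders = founders_set)
    }
  }
  info <- do.call(rbind, infos)
  new_population(h1[seq_len(row), , drop = FALSE],
                 h2[seq_len(row), , drop = FALSE], info, founders$map)
}

#' Cross a set of mated pairs to an S0 population
#'
#' Executes a [pair_by_mrd()]-style mating plan: each pair contributes a
#' full-sib family; `total_offspring` plants are allocated as evenly as
#' possible across pairs.
#'
#' @param parents `rg_pop` containing all paired individuals.
#' @param plan data.frame with columns `parent_a`, `parent_b` (ids).
#' @param total_offspring Total number of S0 plants.
#' @param population Population label.
#' @return An `rg_pop` of S0 plants.
#' @export
cross_pairs <- function(parents, plan, total_offspring, population = "S0") {
  n_fam <- nrow(plan)
  stopifnot(n_fam >= 1)
  sizes <- rep(total_offspring %/% n_fam, n_fam)
  extra <- total_offspring %% n_fam
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ci <- map_chrom_index(parents$map)
  m <- ncol(parents$h1)
  h1 <- matrix(0L, total_offspring, m)
  h2 <- matrix(0L, total_offspring, m)
  infos <- vector("list", n_fam)
  row <- 0L
  for (f in seq_len(n_fam)) {
    a <- match(plan$parent_a[f], parents$info$id)
    b <- match(plan$parent_b[f], parents$info$id)
    if (is.na(a) || is.na(b)) stop("mating plan names unknown parent")
    fam <- paste(plan$parent_a[f], plan$parent_b[f], sep = "x")
    founders_set <- join_founders(parents$info$founders[a],
                                  parents$info$founders[b])
    k <- sizes[f]
    if (k > 0) {
      for (s in seq_len(k)) {
        row <- row + 1L
        h1[row, ] <- gamete_from(parents, a, ci)
        h2[row, ] <- gamete_from(parents, b, ci)
      }
      ids <- sprintf("%s_f%02d_p%03d", population, f, seq_len(k))
      infos[[f]] <- pop_info_frame(ids, mother = plan$parent_a[f],
                                   father = plan$parent_b[f], stage = "S0",
                                   population = population, family = fam,
                                   founders = founders_set)
    }
  }
  new_population(h1[seq_len(row), , drop = FALSE],
                 h2[seq_len(row), , drop = FALSE],
                 do.call(rbind, infos), parents$map)
}

#' Extract DH lines from a population
#'
#' Draws `n_dh` distinct parents at random (or uses all, cycling, if
#' `n_dh > pop_size`) and induces one doubled haploid per parent.
#'
#' @param pop Source `rg_pop`.
#' @param n_dh Number of DH lines.
#' @param population Population label of the DH set.
#' @param prefix Id prefix.
#' @return An `rg_pop` of homozygous DH lines.
#' @export
extract_dh <- function(pop, n_dh, population = "DH", prefix = population) {
  n <- pop_size(pop)
  parents <- if (n_dh <= n) sample.int(n, n_dh) else
    sample(rep(seq_len(n), length.out = n_dh))
  ci <- map_chrom_index(pop$map)
  m <- ncol(pop$h1)
  h <- matrix(0L, n_dh, m)
  for (k in seq_len(n_dh)) h[k, ] <- gamete_from(pop, parents[k], ci)
  ids <- sprintf("%s_%03d", prefix, seq_len(n_dh))
  info <- pop_info_frame(ids, mother = pop$info$id[parents],
                         father = pop$info$id[parents], stage = "DH",
                         population = population,
                         family = pop$info$family[parents],
                         founders = pop$info$founders[parents])
  new_population(h, h, info, pop$map)
}

#' Export a pedigree table
#' @param pop An `rg_pop` (or several bound together).
#' @param path Optional CSV path; if given the table is written.
#' @return data.frame with id, mother, father, stage, population, family.
#' @export
pedigree_table <- function(pop, path = NULL) {
  ped <- pop$info[, c("id", "mother", "father", "stage", "population",
                      "family")]
  if (!is.null(path)) utils::write.csv(ped, path, row.names = FALSE)
  ped
}
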