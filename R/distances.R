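#' Jukes-Cantor (JC69) distance between two aligned consensus sequences
#'
#' Computes the proportion of mismatching sites `p` over jointly resolved
#' sites (both residues in A/C/G/T; gaps and N are pairwise-deleted) and the
#' JC69 evolutionary distance `-(3/4) * log(1 - (4/3) * p)`. Saturated pairs
#' (`p >= 3/4`), for which the JC69 transform is undefined, are reported with
#' an `Inf` sentinel so they can never satisfy a finite match threshold.
#'
#' @param seq_a,seq_b Character scalars: aligned sequences of equal length
#'   over A/C/G/T/N/- (case-insensitive).
#' @return Named numeric vector with elements `p_mismatch` and `raw_jc69`.
#'   Both are `NA` (with a warning) when no site is resolved in both
#'   sequences.
#' @examples
#' jc69_distance("ACGT", "ACGA")
#' @export
jc69_distance <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1, length(seq_b) == 1)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must be aligned to equal length (got ",
         nchar(seq_a), " vs ", nchar(seq_b), ")")
  }
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  ok <- a > 0L & b > 0L
  n_ok <- sum(ok)
  if (n_ok == 0L) {
    warning("no jointly resolved sites; pair is not comparable")
    return(c(p_mismatch = NA_real_, raw_jc69 = NA_real_))
  }
  p <- sum(a[ok] != b[ok]) / n_ok
  c(p_mismatch = p, raw_jc69 = jc69_transform(p))
}

jc69_transform <- function(p) {
  out <- rep(Inf, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 / 3 * p[ok])
  out[!is.na(p) & p == 0] <- 0  # avoid -0
  out[is.na(p)] <- NA_real_
  out
}

# A/C/G/T -> 1..4, anything else (N, gap, ambiguity codes) -> 0.
encode_dna <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  out <- integer(length(x))
  out[x == 65L] <- 1L  # A
  out[x == 67L] <- 2L  # C
  out[x == 71L] <- 3L  # G
  out[x == 84L] <- 4L  # T
  out
}

# n x L integer matrix for one species' alignment (rows = samples).
alignment_matrix <- function(seqs, species = "?") {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    stop("alignment length mismatch in species '", species, "' (samples: ",
         paste(bad, collapse = ", "), ")")
  }
  m <- vapply(seqs, encode_dna, integer(lens[1]))
  # single-site alignments: vapply returns a bare vector
  if (!is.matrix(m)) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(seqs)))
  t(m)
}

#' Per-species pairwise JC69 distances for an alignment set
#'
#' For every species, computes `p` and the JC69 distance for all unordered
#' sample pairs with at least one jointly resolved site. Pairs with no
#' jointly resolved sites are omitted and logged. Species with fewer than
#' two samples yield no pairs (logged).
#'
#' @param alignments A strain alignment set: named list
#'   (species -> named character vector sample_id -> aligned sequence).
#' @return A tibble (the distance table, raw only) with columns `species`,
#'   `sample_a`, `sample_b`, `p_mismatch`, `raw_jc69`, stably sorted by
#'   (species, sample_a, sample_b); each unordered pair appears once with
#'   `sample_a < sample_b`.
#' @export
pairwise_species_distances <- function(alignments) {
  stopifnot(is.list(alignments))
  rows <- lapply(sort(names(alignments)), function(sp) {
    seqs <- alignments[[sp]]
    if (length(seqs) < 2) {
      eg_log("distances", paste0("species '", sp, "' has ", length(seqs),
                                 " sample(s); no pairs"), "WARN")
      return(NULL)
    }
    if (anyDuplicated(names(seqs))) {
      stop("duplicate sample ids in species '", sp, "'")
    }
    m <- alignment_matrix(seqs, sp)
    counts <- pair_counts(m)
    idx <- which(upper.tri(counts$valid), arr.ind = TRUE)
    valid <- counts$valid[idx]
    mism <- counts$mismatch[idx]
    keep <- valid > 0
    if (any(!keep)) {
      eg_log("distances", sprintf(
        "species '%s': %d pair(s) with no jointly resolved sites omitted",
        sp, sum(!keep)), "WARN")
    }
    idx <- idx[keep, , drop = FALSE]
    p <- mism[keep] / valid[keep]
    ids <- names(seqs)
    a <- ids[idx[, 1]]
    b <- ids[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    tibble::tibble(species = sp, sample_a = a, sample_b = b,
                   p_mismatch = p, raw_jc69 = jc69_transform(p))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(species = character(), sample_a = character(),
                          sample_b = character(), p_mismatch = double(),
                          raw_jc69 = double()))
  }
  dplyr::arrange(out, .data$species, .data$sample_a, .data$sample_b)
}

# Pairwise mismatch / valid-site counts via indicator cross-products.
pair_counts <- function(m) {
  valid_ind <- m > 0L
  storage.mode(valid_ind) <- "double"
  valid <- tcrossprod(valid_ind)
  match <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    ib <- m == b
    storage.mode(ib) <- "double"
    match <- match + tcrossprod(ib)
  }
  list(valid = valid, mismatch = valid - match)
}

#' Normalise JC69 distances by the per-species median
#'
#' Divides each species' raw JC69 distances by the median of that species'
#' finite raw pairwise distances, so species with different background
#' strain diversity become comparable. Saturated (`Inf`) pairs are excluded
#' from the median and stay `Inf` after normalisation. A species whose
#' median is zero (all retained strains identical) is flagged and its
#' zero-distance pairs are given normalised distance 0.
#'
#' @param table Distance table from [pairwise_species_distances()].
#' @return The table with columns `median_raw` and `normalised` added.
#'   Species flagged for a zero median are recorded in the
#'   `zero_median_species` attribute.
#' @export
normalise_by_species_median <- function(table) {
  stopifnot(all(c("species", "raw_jc69") %in% names(table)))
  out <- table |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(median_raw = stats::median(.data$raw_jc69[is.finite(.data$raw_jc69)])) |>
    dplyr::ungroup() |>
    dplyr::mutate(normalised = dplyr::case_when(
      .data$median_raw > 0 ~ .data$raw_jc69 / .data$median_raw,
      .data$raw_jc69 == 0 ~ 0,
      TRUE ~ Inf
    ))
  zero_sp <- unique(out$species[!is.na(out$median_raw) & out$median_raw == 0])
  if (length(zero_sp) > 0) {
    eg_log("normalise", paste0("zero-median species (all strains identical): ",
                               paste(zero_sp, collapse = ", ")), "WARN")
  }
  attr(out, "zero_median_species") <- zero_sp
  out
}

#' Split normalised distances into intra- and inter-subject classes
#'
#' Labels each pair `intra` when both samples belong to the same subject and
#' `inter` otherwise, for density plotting of the two strain-distance modes.
#' Donor batch samples (role `donor_batch`) are excluded from both classes
#' because they are ambiguous as intra- or inter-subject comparisons.
#'
#' @param table Distance table (raw or normalised).
#' @param roster Sample metadata with columns `sample_id`, `subject_id`,
#'   `role`.
#' @return The table restricted to non-batch pairs with a `pair_class`
#'   column (`"intra"`/`"inter"`); class counts are in the `class_counts`
#'   attribute.
#' @export
distance_density_split <- function(table, roster) {
  stopifnot(all(c("sample_id", "subject_id", "role") %in% names(roster)))
  missing <- setdiff(unique(c(table$sample_a, table$sample_b)),
                     roster$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from roster: ", paste(missing, collapse = ", "))
  }
  look <- stats::setNames(roster$subject_id, roster$sample_id)
  role <- stats::setNames(roster$role, roster$sample_id)
  batch <- role[table$sample_a] == "donor_batch" |
    role[table$sample_b] == "donor_batch"
  if (any(batch)) {
    eg_log("density", sprintf("%d donor-batch pair(s) excluded", sum(batch)))
  }
  out <- table[!batch, , drop = FALSE]
  out$pair_class <- unname(ifelse(look[out$sample_a] == look[out$sample_b],
                                  "intra", "inter"))
  attr(out, "class_counts") <- c(intra = sum(out$pair_class == "intra"),
                                 inter = sum(out$pair_class == "inter"))
  out
}
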