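# Shared fixtures built in code.

# brute-force per-site JC69 recount, kept deliberately naive: the oracle for
# the vectorised distance engine
brute_force_distances <- function(alignments) {
  rows <- list()
  for (sp in sort(names(alignments))) {
    seqs <- alignments[[sp]]
    if (length(seqs) < 2) next
    ids <- names(seqs)
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        a <- strsplit(toupper(seqs[[i]]), "")[[1]]
        b <- strsplit(toupper(seqs[[j]]), "")[[1]]
        nuc <- c("A", "C", "G", "T")
        mism <- 0L; valid <- 0L
        for (s in seq_along(a)) {
          if (a[s] %in% nuc && b[s] %in% nuc) {
            valid <- valid + 1L
            if (a[s] != b[s]) mism <- mism + 1L
          }
        }
        if (valid == 0L) next
        p <- mism / valid
        d <- if (p < 0.75) -0.75 * log(1 - 4 / 3 * p) else Inf
        pair <- sort(c(ids[i], ids[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, sample_a = pair[1], sample_b = pair[2],
          p_mismatch = p, raw_jc69 = d, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$species, out$sample_a, out$sample_b), , drop = FALSE]
}

random_toy_alignment <- function(n_samples, n_sites,
                                 alphabet = c("A", "C", "G", "T", "N", "-")) {
  prob <- if (length(alphabet) == 6) c(rep(0.22, 4), 0.06, 0.06) else NULL
  seqs <- vapply(seq_len(n_samples), function(i)
    paste(sample(alphabet, n_sites, replace = TRUE, prob = prob),
          collapse = ""),
    character(1))
  names(seqs) <- sprintf("S%02d", seq_len(n_samples))
  seqs
}

# small cohort used by several test files; memoised per options
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 1, ...) {
  key <- paste(seed, rlang::hash(list(...)))
  if (is.null(small_cohort_cache[[key]])) {
    cfg <- cohort_config(n_donors = 4, n_fmt_recipients = 6,
                         n_placebo_recipients = 3,
                         pool_size_range = c(2L, 2L), n_species = 12,
                         marker_length = 400, seed = seed, ...)
    small_cohort_cache[[key]] <- generate_cohort(cfg)
  }
  small_cohort_cache[[key]]
}

cohort_distances <- function(cohort) {
  normalise_by_species_median(pairwise_species_distances(cohort$alignments))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive confusion-matrix oracle: classify every (donor, recipient) pair by
# direct set membership
enumerate_confusion <- function(predicted, reference, donors, recipients) {
  tp <- fp <- tn <- fn <- 0L
  for (r in recipients) {
    for (d in donors) {
      in_ref <- any(reference$recipient == r & reference$donor == d)
      in_pred <- d %in% (predicted[[r]] %||% character(0))
      if (in_ref && in_pred) tp <- tp + 1L
      else if (!in_ref && in_pred) fp <- fp + 1L
      else if (in_ref && !in_pred) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# all permutations of 1..n as an (n! x n) matrix, for exhaustive
# permutation-test oracles
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# minimal roster for hand-built match fixtures
toy_roster <- function() {
  tibble::tibble(
    sample_id = c("D1-S1", "D2-S1", "R1-BL", "R1-WK", "P1-BL", "P1-WK"),
    subject_id = c("D1", "D2", "R1", "R1", "P1", "P1"),
    role = c("donor", "donor", "fmt_recipient", "fmt_recipient",
             "placebo_recipient", "placebo_recipient"),
    timepoint = c("donation", "donation", "baseline", "post",
                  "baseline", "post"),
    read_count = 1e6L)
}

# distance-table row builder for fixtures (already normalised)
toy_distance_rows <- function(...) {
  rows <- list(...)
  tibble::tibble(
    species = vapply(rows, `[[`, "", 1),
    sample_a = vapply(rows, function(r) sort(c(r[[2]], r[[3]]))[1], ""),
    sample_b = vapply(rows, function(r) sort(c(r[[2]], r[[3]]))[2], ""),
    p_mismatch = NA_real_, raw_jc69 = NA_real_, median_raw = 1,
    normalised = vapply(rows, function(r) as.numeric(r[[4]]), 0))
}
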