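# Roster helpers -------------------------------------------------------------

roster_check <- function(roster) {
  need <- c("sample_id", "subject_id", "role", "timepoint")
  stopifnot(all(need %in% names(roster)))
  if (anyDuplicated(roster$sample_id)) {
    stop("duplicate sample_id in roster: ",
         paste(unique(roster$sample_id[duplicated(roster$sample_id)]),
               collapse = ", "))
  }
  invisible(roster)
}

# subject -> baseline sample id, for recipients of the given role(s)
baseline_sample_map <- function(roster, roles = c("fmt_recipient",
                                                  "placebo_recipient")) {
  b <- roster[roster$role %in% roles & roster$timepoint == "baseline", ]
  if (anyDuplicated(b$subject_id)) {
    eg_log("roster", "multiple baseline samples for a subject; using the first",
           "WARN")
    b <- b[!duplicated(b$subject_id), ]
  }
  stats::setNames(b$sample_id, b$subject_id)
}

# canonical unordered pair key used to look distances up
pair_key <- function(species, s1, s2) {
  paste(species, pmin(s1, s2), pmax(s1, s2), sep = "\r")
}

# Candidate matching --------------------------------------------------------

#' Call candidate donor-recipient strain matches at a distance threshold
#'
#' A candidate match is a (species, donor sample, recipient post sample)
#' triple whose median-normalised JC69 distance is at or below `theta`
#' (inclusive). Subtraction flags are initialised to `FALSE`; every
#' candidate starts as surviving.
#'
#' @param distances Normalised distance table
#'   (from [normalise_by_species_median()]).
#' @param roster Sample metadata (`sample_id`, `subject_id`, `role`,
#'   `timepoint`).
#' @param theta Positive normalised-distance threshold.
#' @param recipient_role Which recipient cohort to match against
#'   (`"fmt_recipient"` or `"placebo_recipient"`).
#' @param strict If `TRUE`, use a strict `< theta` rule instead of the
#'   default inclusive `<= theta`.
#' @return A match table (tibble) with columns `species`, `donor_subject`,
#'   `donor_sample`, `recipient_subject`, `recipient_post_sample`,
#'   `normalised_distance`, `flag_baseline_origin`,
#'   `flag_placebo_background`, `surviving`, `class`.
#' @export
call_candidate_matches <- function(distances, roster, theta,
                                   recipient_role = "fmt_recipient",
                                   strict = FALSE) {
  stopifnot(theta > 0, "normalised" %in% names(distances))
  roster_check(roster)
  role <- stats::setNames(roster$role, roster$sample_id)
  tp <- stats::setNames(roster$timepoint, roster$sample_id)
  subj <- stats::setNames(roster$subject_id, roster$sample_id)

  d <- distances
  a_donor <- role[d$sample_a] == "donor"
  b_donor <- role[d$sample_b] == "donor"
  a_post <- role[d$sample_a] == recipient_role & tp[d$sample_a] == "post"
  b_post <- role[d$sample_b] == recipient_role & tp[d$sample_b] == "post"
  keep <- (a_donor & b_post) | (b_donor & a_post)
  hit <- if (strict) d$normalised < theta else d$normalised <= theta
  d <- d[keep & hit & is.finite(d$normalised), , drop = FALSE]
  donor_sample <- ifelse(role[d$sample_a] == "donor", d$sample_a, d$sample_b)
  post_sample <- ifelse(role[d$sample_a] == "donor", d$sample_b, d$sample_a)
  out <- tibble::tibble(
    species = d$species,
    donor_subject = unname(subj[donor_sample]),
    donor_sample = donor_sample,
    recipient_subject = unname(subj[post_sample]),
    recipient_post_sample = post_sample,
    normalised_distance = d$normalised,
    flag_baseline_origin = FALSE,
    flag_placebo_background = FALSE,
    surviving = TRUE,
    class = "unclassified")
  dplyr::arrange(out, .data$species, .data$donor_sample,
                 .data$recipient_post_sample)
}

#' Flag donor-matching strains already present at the recipient's baseline
#'
#' A surviving donor match is considered of recipient origin — and flagged —
#' when the same donor sample also matches (normalised distance at or below
#' `theta`) the recipient's own baseline sample for that species. Recipients
#' without a baseline sample cannot be evaluated: their matches are removed
#' entirely and logged.
#'
#' @inheritParams call_candidate_matches
#' @param matches Candidate match table.
#' @param mode `"donor_vs_baseline"` (default): flag when the donor strain
#'   matches the recipient baseline strain. `"baseline_vs_post"`: flag when
#'   the recipient's own baseline and post strains match (strain
#'   persistence), regardless of the donor.
#' @return The match table with `flag_baseline_origin` and `surviving`
#'   updated.
#' @export
apply_baseline_subtraction <- function(matches, distances, roster, theta,
                                       mode = c("donor_vs_baseline",
                                                "baseline_vs_post"),
                                       strict = FALSE) {
  mode <- match.arg(mode)
  roster_check(roster)
  base_map <- baseline_sample_map(roster)
  no_base <- !matches$recipient_subject %in% names(base_map)
  if (any(no_base)) {
    eg_log("baseline", paste0(
      "recipients without baseline sample excluded: ",
      paste(unique(matches$recipient_subject[no_base]), collapse = ", ")),
      "WARN")
    matches <- matches[!no_base, , drop = FALSE]
  }
  lut <- stats::setNames(distances$normalised,
                         pair_key(distances$species, distances$sample_a,
                                  distances$sample_b))
  other <- switch(mode,
                  donor_vs_baseline = matches$donor_sample,
                  baseline_vs_post = matches$recipient_post_sample)
  d_base <- unname(lut[pair_key(matches$species,
                                base_map[matches$recipient_subject], other)])
  hit <- !is.na(d_base) & (if (strict) d_base < theta else d_base <= theta)
  matches$flag_baseline_origin <- hit
  matches$surviving <- !matches$flag_baseline_origin &
    !matches$flag_placebo_background
  matches
}

#' Remove donor strains also matching the placebo cohort as background
#'
#' Any (donor subject, species) combination with a surviving match in a
#' placebo recipient is ambiguous background: every FMT match of that
#' combination is flagged. The placebo matches must have been produced by
#' the identical candidate-call + baseline-subtraction procedure on the
#' placebo recipients.
#'
#' @param matches FMT match table.
#' @param placebo_matches Placebo match table.
#' @return The FMT match table with `flag_placebo_background` and
#'   `surviving` updated. Idempotent.
#' @export
apply_placebo_subtraction <- function(matches, placebo_matches) {
  bg <- unique(paste(placebo_matches$donor_subject[placebo_matches$surviving],
                     placebo_matches$species[placebo_matches$surviving],
                     sep = "\r"))
  key <- paste(matches$donor_subject, matches$species, sep = "\r")
  matches$flag_placebo_background <- key %in% bg
  matches$surviving <- !matches$flag_baseline_origin &
    !matches$flag_placebo_background
  matches
}

#' Classify surviving engrafted strains as novel or replacement
#'
#' An engrafted species already present (relative abundance > 0) in the
#' recipient's baseline taxonomic profile replaced the existing conspecific
#' strain; a species absent at baseline is novel to the recipient. Species
#' missing from the abundance table stay `unclassified` (logged).
#'
#' @param matches Match table with subtractions applied.
#' @param abundances Wide abundance table: `sample_id` column plus one
#'   column per species (an `UNKNOWN` column is ignored).
#' @param roster Sample metadata.
#' @return The match table with `class` filled for surviving records.
#' @export
classify_novel_or_replacement <- function(matches, abundances, roster) {
  roster_check(roster)
  base_map <- baseline_sample_map(roster)
  ab <- as.data.frame(abundances)
  rownames(ab) <- ab$sample_id
  cls <- matches$class
  for (i in which(matches$surviving)) {
    sp <- matches$species[i]
    bs <- base_map[[matches$recipient_subject[i]]]
    if (is.null(bs) || !sp %in% names(ab)) {
      cls[i] <- "unclassified"
      eg_log("classify", paste0("species '", sp,
                                "' missing from abundance table"), "WARN")
      next
    }
    cls[i] <- if (ab[bs, sp] > 0) "replacement" else "novel"
  }
  matches$class <- cls
  matches
}

#' Distinct-species match-count matrix (recipients x donors)
#'
#' Heatmap-ready count of distinct species with surviving donor-matching
#' strains for each recipient-donor combination.
#'
#' @param matches Match table.
#' @param donors,recipients Optional row/column universes (default: those
#'   seen in the matches).
#' @return Integer matrix, rows = recipients, columns = donors.
#' @export
match_count_matrix <- function(matches, donors = NULL, recipients = NULL) {
  m <- matches[matches$surviving, , drop = FALSE]
  donors <- sort(donors %||% unique(m$donor_subject))
  recipients <- sort(recipients %||% unique(m$recipient_subject))
  out <- matrix(0L, length(recipients), length(donors),
                dimnames = list(recipients, donors))
  m <- m[m$donor_subject %in% donors & m$recipient_subject %in% recipients, ,
         drop = FALSE]
  if (nrow(m) > 0) {
    u <- unique(m[, c("recipient_subject", "donor_subject", "species")])
    tab <- table(u$recipient_subject, u$donor_subject)
    out[rownames(tab), colnames(tab)] <-
      out[rownames(tab), colnames(tab)] + unclass(tab)
  }
  out
}
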