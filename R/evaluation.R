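#' Predict donor pools from surviving strain matches
#'
#' For each FMT recipient, counts the distinct species with surviving
#' donor-matching strains per donor; the predicted donor set is every donor
#' with at least one such species.
#'
#' @param matches Match table with subtractions applied.
#' @return A `pairing_prediction`: list with `counts` (tibble `recipient`,
#'   `donor`, `n_species`) and `predicted` (named list recipient -> donor
#'   set; recipients with no matches are absent / empty).
#' @export
predict_pairings <- function(matches) {
  m <- matches[matches$surviving, , drop = FALSE]
  if (nrow(m) == 0) {
    counts <- tibble::tibble(recipient = character(), donor = character(),
                             n_species = integer())
  } else {
    counts <- m |>
      dplyr::distinct(.data$recipient_subject, .data$donor_subject,
                      .data$species) |>
      dplyr::count(recipient = .data$recipient_subject,
                   donor = .data$donor_subject, name = "n_species") |>
      dplyr::arrange(.data$recipient, .data$donor)
  }
  predicted <- split(counts$donor, counts$recipient)
  structure(list(counts = counts, predicted = predicted),
            class = "pairing_prediction")
}

#' Score predicted donor pools against reference pairings
#'
#' Classifies every (donor, evaluable recipient) pair as TP/FP/TN/FN and
#' summarises precision, recall and F1 (0/0 conventions: all three are 0
#' when undefined).
#'
#' @param prediction A [predict_pairings()] result (or its `counts` tibble).
#' @param reference Long reference pairing table: columns `recipient`,
#'   `donor`.
#' @param donors Donor roster (character vector).
#' @param recipients Evaluable recipients; defaults to those in `reference`.
#' @param theta Optional threshold annotation carried into the summary.
#' @return A `confusion_summary`: list with `theta`, `tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `f1` and the per-pair classification tibble
#'   `pairs`.
#' @export
score_against_reference <- function(prediction, reference, donors,
                                    recipients = NULL, theta = NA_real_) {
  counts <- if (inherits(prediction, "pairing_prediction"))
    prediction$counts else prediction
  recipients <- sort(recipients %||% unique(reference$recipient))
  extra <- setdiff(unique(counts$recipient), recipients)
  if (length(extra) > 0) {
    stop("predicted recipients absent from reference: ",
         paste(extra, collapse = ", "))
  }
  donors <- sort(donors)
  pairs <- tidyr::expand_grid(recipient = recipients, donor = donors)
  ref_key <- paste(reference$recipient, reference$donor, sep = "\r")
  pred_key <- paste(counts$recipient[counts$n_species >= 1],
                    counts$donor[counts$n_species >= 1], sep = "\r")
  key <- paste(pairs$recipient, pairs$donor, sep = "\r")
  pairs$truth <- key %in% ref_key
  pairs$predicted <- key %in% pred_key
  tp <- sum(pairs$truth & pairs$predicted)
  fp <- sum(!pairs$truth & pairs$predicted)
  fn <- sum(pairs$truth & !pairs$predicted)
  tn <- sum(!pairs$truth & !pairs$predicted)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(theta = theta, tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 pairs = pairs),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("theta = %s\n", format(x$theta)))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(ref = c("paired", "unpaired"),
                              pred = c("paired", "unpaired")))
  print(m)
  cat(sprintf("precision = %.3f, recall = %.3f, F1 = %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

# Cached candidate frame: one row per (species, donor sample, recipient)
# pair present in the distance table, with the donor-post and donor-baseline
# normalised distances. Thresholding this frame reproduces the full
# call + baseline-subtraction pipeline at any theta.
sweep_frame <- function(distances, roster,
                        recipient_role = "fmt_recipient") {
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
  d <- d[keep, , drop = FALSE]
  donor_sample <- ifelse(role[d$sample_a] == "donor", d$sample_a, d$sample_b)
  post_sample <- ifelse(role[d$sample_a] == "donor", d$sample_b, d$sample_a)
  fr <- tibble::tibble(
    species = d$species,
    donor_subject = unname(subj[donor_sample]),
    donor_sample = donor_sample,
    recipient_subject = unname(subj[post_sample]),
    recipient_post_sample = post_sample,
    d_post = d$normalised)
  base_map <- baseline_sample_map(roster)
  has_base <- fr$recipient_subject %in% names(base_map)
  if (any(!has_base)) {
    eg_log("sweep", paste0("recipients without baseline excluded: ",
                           paste(unique(fr$recipient_subject[!has_base]),
                                 collapse = ", ")), "WARN")
    fr <- fr[has_base, , drop = FALSE]
  }
  lut <- stats::setNames(distances$normalised,
                         pair_key(distances$species, distances$sample_a,
                                  distances$sample_b))
  fr$d_base <- unname(lut[pair_key(fr$species,
                                   base_map[fr$recipient_subject],
                                   fr$donor_sample)])
  fr
}

#' Sweep strain-match thresholds against reference pairings
#'
#' Re-runs the full matching + subtraction + prediction + scoring pipeline
#' at every threshold of `theta_grid` and selects the F1-optimal threshold
#' (ties broken by the smallest, i.e. most stringent, theta). Both
#' subtraction variants of the analysis are supported: baseline subtraction
#' only, or baseline + placebo subtraction.
#'
#' @inheritParams call_candidate_matches
#' @param abundances Wide abundance table (unused by scoring; accepted so
#'   the sweep signature mirrors the single-threshold pipeline).
#' @param reference Long reference pairing table (`recipient`, `donor`).
#' @param theta_grid Strictly positive, sorted thresholds. Default: 0.001
#'   to 3.000 in steps of 0.001.
#' @param use_placebo_subtraction Apply placebo subtraction at each theta.
#' @param placebo_background `"per_theta"` recomputes the placebo
#'   background at every theta; `"fixed"` freezes it at
#'   `fixed_background_theta`.
#' @param fixed_background_theta Theta used for the frozen background.
#' @param donors Donor subject ids (default: from the roster).
#' @return A `threshold_sweep`: list with `summaries` (tibble: theta, tp,
#'   fp, tn, fn, precision, recall, f1) and `optimum` (one-row tibble).
#' @export
threshold_sweep <- function(distances, roster, abundances = NULL, reference,
                            theta_grid = seq(0.001, 3, by = 0.001),
                            use_placebo_subtraction = FALSE,
                            placebo_background = c("per_theta", "fixed"),
                            fixed_background_theta = 0.2,
                            donors = NULL) {
  placebo_background <- match.arg(placebo_background)
  if (length(theta_grid) == 0) stop("empty theta grid")
  stopifnot(all(theta_grid > 0), !is.unsorted(theta_grid))
  donors <- donors %||% sort(unique(
    roster$subject_id[roster$role == "donor"]))
  recipients <- sort(unique(reference$recipient))

  fmt_fr <- sweep_frame(distances, roster, "fmt_recipient")
  fmt_fr <- fmt_fr[fmt_fr$recipient_subject %in% recipients, , drop = FALSE]
  plc_fr <- if (use_placebo_subtraction)
    sweep_frame(distances, roster, "placebo_recipient") else NULL

  pair_id <- paste(fmt_fr$recipient_subject, fmt_fr$donor_subject, sep = "\r")
  bg_key <- paste(fmt_fr$donor_subject, fmt_fr$species, sep = "\r")
  all_pairs <- tidyr::expand_grid(recipient = recipients, donor = donors)
  all_keys <- paste(all_pairs$recipient, all_pairs$donor, sep = "\r")
  truth <- all_keys %in% paste(reference$recipient, reference$donor,
                               sep = "\r")
  n_true <- sum(truth)

  surviving_bg <- function(fr, theta) {
    ok <- is.finite(fr$d_post) & fr$d_post <= theta &
      !(!is.na(fr$d_base) & fr$d_base <= theta)
    unique(paste(fr$donor_subject[ok], fr$species[ok], sep = "\r"))
  }
  fixed_bg <- if (use_placebo_subtraction && placebo_background == "fixed")
    surviving_bg(plc_fr, fixed_background_theta) else NULL

  rows <- lapply(theta_grid, function(theta) {
    ok <- is.finite(fmt_fr$d_post) & fmt_fr$d_post <= theta &
      !(!is.na(fmt_fr$d_base) & fmt_fr$d_base <= theta)
    if (use_placebo_subtraction) {
      bg <- fixed_bg %||% surviving_bg(plc_fr, theta)
      ok <- ok & !(bg_key %in% bg)
    }
    pred_keys <- unique(pair_id[ok])
    predicted <- all_keys %in% pred_keys
    tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
    fn <- n_true - tp; tn <- sum(!truth) - fp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(theta = theta, tp = tp, fp = fp, tn = tn, fn = fn,
      precision = precision, recall = recall, f1 = f1)
  })
  summaries <- tibble::as_tibble(do.call(rbind, rows))
  best <- which(summaries$f1 == max(summaries$f1))[1]  # smallest theta wins
  structure(list(summaries = summaries, optimum = summaries[best, ]),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold sweep over %d thresholds [%g, %g]\n",
              nrow(x$summaries), min(x$summaries$theta),
              max(x$summaries$theta)))
  cat(sprintf("optimum: theta = %g, F1 = %.3f (precision %.3f, recall %.3f)\n",
              x$optimum$theta, x$optimum$f1, x$optimum$precision,
              x$optimum$recall))
  invisible(x)
}

#' Per-donor recall of true recipient pairings
#'
#' For each donor, the proportion of its true recipients that were
#' correctly predicted (TP / (TP + FN)). Donors with no true recipients are
#' undefined and excluded (logged).
#'
#' @param confusion A [score_against_reference()] result.
#' @return Tibble with columns `donor`, `n_true`, `n_predicted`, `recall`.
#' @export
donor_recall <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_summary"))
  p <- confusion$pairs[confusion$pairs$truth, , drop = FALSE]
  skipped <- setdiff(unique(confusion$pairs$donor), unique(p$donor))
  if (length(skipped) > 0) {
    eg_log("recall", paste0("donors with no true recipients excluded: ",
                            paste(skipped, collapse = ", ")))
  }
  p |>
    dplyr::group_by(donor = .data$donor) |>
    dplyr::summarise(n_true = dplyr::n(),
                     n_predicted = sum(.data$predicted),
                     recall = mean(.data$predicted), .groups = "drop")
}

#' Engraftment efficiency per true donor-recipient pairing
#'
#' Efficiency is the percentage of the donor's distinct profiled species
#' strains (pooled across the donor's samples) that survive as matches in
#' the recipient. Donors with zero profiled strains have undefined
#' efficiency and are excluded (logged).
#'
#' @param matches Match table with subtractions applied.
#' @param alignments Strain alignment set (defines which species have a
#'   profiled strain in each donor sample).
#' @param roster Sample metadata.
#' @param reference Long reference pairing table (`recipient`, `donor`).
#' @return Tibble with columns `donor`, `recipient`, `n_donor_strains`,
#'   `n_engrafted`, `efficiency` (percent).
#' @export
engraftment_efficiency <- function(matches, alignments, roster, reference) {
  roster_check(roster)
  donor_samples <- roster$sample_id[roster$role == "donor"]
  donor_of <- stats::setNames(roster$subject_id, roster$sample_id)
  profiled <- lapply(alignments, function(recs)
    unique(donor_of[intersect(names(recs), donor_samples)]))
  n_strains <- table(unlist(profiled))
  m <- matches[matches$surviving, , drop = FALSE]
  ref <- dplyr::distinct(reference[, c("donor", "recipient")])
  no_strain <- setdiff(unique(ref$donor), names(n_strains))
  if (length(no_strain) > 0) {
    eg_log("efficiency", paste0(
      "donors with zero profiled strains excluded: ",
      paste(no_strain, collapse = ", ")), "WARN")
    ref <- ref[!ref$donor %in% no_strain, , drop = FALSE]
  }
  eng <- m |>
    dplyr::distinct(donor = .data$donor_subject,
                    recipient = .data$recipient_subject, .data$species) |>
    dplyr::count(.data$donor, .data$recipient, name = "n_engrafted")
  out <- ref |>
    dplyr::left_join(eng, by = c("donor", "recipient")) |>
    dplyr::mutate(n_engrafted = dplyr::coalesce(.data$n_engrafted, 0L),
                  n_donor_strains = as.integer(n_strains[.data$donor]),
                  efficiency = 100 * .data$n_engrafted / .data$n_donor_strains)
  dplyr::arrange(out[, c("donor", "recipient", "n_donor_strains",
                         "n_engrafted", "efficiency")],
                 .data$donor, .data$recipient)
}

#' Two-sample test for equality of novel-strain proportions
#'
#' Compares the proportion of novel (vs replacement) engrafted strains
#' between two cohorts with the standard two-sample equal-proportions
#' chi-square test with continuity correction (two-sided).
#'
#' @param novel Length-2 vector of novel-strain counts.
#' @param total Length-2 vector of classified engrafted-strain totals.
#' @return List with `novel`, `total`, `proportions`, `statistic`,
#'   `p_value` and the underlying `htest`.
#' @export
proportion_test <- function(novel, total) {
  stopifnot(length(novel) == 2, length(total) == 2)
  if (any(total == 0)) stop("zero totals: proportions undefined")
  ht <- stats::prop.test(novel, total)
  list(novel = novel, total = total, proportions = unname(ht$estimate),
       statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}

#' Compare novel-strain fractions of two cohorts' match tables
#'
#' Counts classified surviving matches (`novel` / `replacement`) per cohort
#' and applies [proportion_test()].
#'
#' @param matches_a,matches_b Match tables with `class` filled (e.g. from
#'   [classify_novel_or_replacement()]).
#' @return As [proportion_test()].
#' @export
novel_fraction_comparison <- function(matches_a, matches_b) {
  count1 <- function(m) {
    u <- m[m$surviving & m$class %in% c("novel", "replacement"), ] |>
      dplyr::distinct(.data$donor_subject, .data$recipient_subject,
                      .data$species, .data$class)
    c(novel = sum(u$class == "novel"), total = nrow(u))
  }
  a <- count1(matches_a); b <- count1(matches_b)
  proportion_test(c(a["novel"], b["novel"]), c(a["total"], b["total"]))
}
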