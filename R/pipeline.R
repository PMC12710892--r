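#' Default full and reduced mixed-model specifications
#'
#' The full model carries all covariates plus the interactions between
#' donor and recipient alpha-diversity and between donor and recipient
#' Prevotella/Bacteroides ratio; the reduced model drops the interactions.
#'
#' @param include_batch_size Include the FMT batch size covariate (useful
#'   only when pool sizes vary).
#' @param include_functional Include the functional Bray-Curtis covariate.
#' @return List with elements `full` and `reduced`.
#' @export
default_model_specs <- function(include_batch_size = FALSE,
                                include_functional = TRUE) {
  fixed <- c("donor_alpha_mean", "recipient_alpha_baseline",
             "bc_species_mean", "jaccard_species_mean",
             "donor_pb_mean", "recipient_pb")
  if (include_functional) fixed <- c(fixed, "bc_functional_mean")
  if (include_batch_size) fixed <- c(fixed, "batch_size")
  ints <- list(c("donor_alpha_mean", "recipient_alpha_baseline"),
               c("donor_pb_mean", "recipient_pb"))
  list(full = mixed_model_spec(fixed, ints),
       reduced = mixed_model_spec(fixed))
}

#' Run the full strain-engraftment analysis
#'
#' Orchestrates the pipeline end to end: pairwise JC69 distances and median
#' normalisation; candidate strain matching at `theta` with baseline
#' subtraction (placebo subtraction per the chosen variant); novel vs
#' replacement classification; donor-pool prediction; and — when reference
#' pairings are available and `blinded = FALSE` — threshold sweep, scoring,
#' donor recall, engraftment efficiency, the covariate table and the
#' full/reduced mixed models. In blinded mode (or without a reference) the
#' scoring stages are skipped with a logged notice, reproducing the
#' prediction-only phase of a blinded analysis.
#'
#' @param alignments Strain alignment set (named list), e.g. from
#'   [generate_cohort()] or [read_alignment_dir()].
#' @param roster Sample metadata table.
#' @param abundances Wide species abundance table.
#' @param cog Long COG annotation table, or `NULL` to skip functional
#'   covariates.
#' @param reference Long reference pairing table, or `NULL`.
#' @param theta Strain-match threshold on normalised distance.
#' @param theta_grid Optional sweep grid; when supplied the sweep runs and
#'   `theta_used` becomes the sweep optimum.
#' @param subtraction `"baseline"` or `"baseline+placebo"`.
#' @param blinded Skip all reference-dependent stages.
#' @param outdir Optional directory: write all stage outputs as TSV/JSON
#'   plus a run manifest.
#' @return List of stage results (`distances`, `matches`,
#'   `placebo_matches`, `prediction`, and when scored: `sweep`,
#'   `confusion`, `recall`, `efficiency`, `covariates`, `models`,
#'   `theta_used`, `manifest`).
#' @export
run_pipeline <- function(alignments, roster, abundances, cog = NULL,
                         reference = NULL, theta = 0.2, theta_grid = NULL,
                         subtraction = c("baseline", "baseline+placebo"),
                         blinded = FALSE, outdir = NULL) {
  subtraction <- match.arg(subtraction)
  roster_check(roster)
  eg_log("pipeline", "computing pairwise JC69 distances")
  distances <- normalise_by_species_median(
    pairwise_species_distances(alignments))

  scored <- !blinded && !is.null(reference)
  if (!scored) {
    eg_log("pipeline",
           "no reference pairings in use: sweep/recall/efficiency disabled (blinded mode)")
  }

  sweep <- NULL
  theta_used <- theta
  if (scored && !is.null(theta_grid)) {
    eg_log("pipeline", sprintf("threshold sweep over %d values",
                               length(theta_grid)))
    sweep <- threshold_sweep(distances, roster, abundances, reference,
                             theta_grid = theta_grid,
                             use_placebo_subtraction =
                               subtraction == "baseline+placebo")
    theta_used <- sweep$optimum$theta
  }

  match_at <- function(role) {
    m <- call_candidate_matches(distances, roster, theta_used, role)
    apply_baseline_subtraction(m, distances, roster, theta_used)
  }
  eg_log("pipeline", sprintf("matching at theta = %g", theta_used))
  placebo_matches <- match_at("placebo_recipient")
  matches <- match_at("fmt_recipient")
  if (subtraction == "baseline+placebo") {
    matches <- apply_placebo_subtraction(matches, placebo_matches)
  }
  matches <- classify_novel_or_replacement(matches, abundances, roster)
  prediction <- predict_pairings(matches)

  out <- list(distances = distances, matches = matches,
              placebo_matches = placebo_matches, prediction = prediction,
              theta_used = theta_used, sweep = sweep)

  if (scored) {
    donors <- sort(unique(roster$subject_id[roster$role == "donor"]))
    out$confusion <- score_against_reference(prediction, reference, donors,
                                             theta = theta_used)
    out$recall <- donor_recall(out$confusion)
    out$efficiency <- engraftment_efficiency(matches, alignments, roster,
                                             reference)
    fp <- if (!is.null(cog)) cog_renormalise(cog) else NULL
    out$functional_profiles <- fp
    out$covariates <- build_covariate_table(out$efficiency, abundances, fp,
                                            roster, reference)
    specs <- default_model_specs(
      include_batch_size = length(unique(table(reference$recipient))) > 1,
      include_functional = !is.null(fp))
    out$models <- tryCatch(
      fit_mixed_models(out$covariates, specs$full, specs$reduced),
      error = function(e) {
        eg_log("pipeline", paste("mixed models not fitted:",
                                 conditionMessage(e)), "WARN")
        NULL
      })
  }

  out$manifest <- run_manifest(out)
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

run_manifest <- function(out) {
  counts <- list(
    n_distance_pairs = nrow(out$distances),
    n_candidate_matches = nrow(out$matches),
    n_surviving_matches = sum(out$matches$surviving),
    n_predicted_recipients = length(out$prediction$predicted),
    theta_used = out$theta_used)
  list(tool = "engraftr",
       version = as.character(utils::packageVersion("engraftr")),
       result_hash = rlang::hash(counts),
       counts = counts,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_run <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_distances(out$distances, file.path(outdir, "distances.tsv"))
  readr::write_tsv(out$matches, file.path(outdir, "matches.tsv"))
  readr::write_tsv(out$prediction$counts,
                   file.path(outdir, "match_counts.tsv"))
  if (!is.null(out$sweep)) {
    readr::write_tsv(out$sweep$summaries, file.path(outdir, "sweep.tsv"))
    jsonlite::write_json(as.list(out$sweep$optimum),
                         file.path(outdir, "optimum.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$recall)) {
    readr::write_tsv(out$recall, file.path(outdir, "donor_recall.tsv"))
  }
  if (!is.null(out$efficiency)) {
    readr::write_tsv(out$efficiency, file.path(outdir, "efficiency.tsv"))
  }
  if (!is.null(out$covariates)) {
    readr::write_tsv(out$covariates, file.path(outdir, "covariates.tsv"))
  }
  if (!is.null(out$models)) {
    jsonlite::write_json(
      list(full = out$models$full$effects,
           reduced = out$models$reduced$effects,
           lrt_p = out$models$lrt_p, lrt_df = out$models$lrt_df,
           n = out$models$n,
           ci_method = out$models$full$ci_method,
           singular_full = out$models$full$singular,
           log_likelihood_full = out$models$full$log_likelihood,
           log_likelihood_reduced = out$models$reduced$log_likelihood),
      file.path(outdir, "models.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
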