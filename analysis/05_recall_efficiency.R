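#!/usr/bin/env Rscript

# Stage 5: donor recall and engraftment efficiency at each design's optimal
# threshold, the recall-vs-efficiency correlation, per-donor efficiency
# group test, and the between-design novel-strain proportion test.

suppressPackageStartupMessages({
  library(engraftr)
  library(dplyr)
})

match_tables <- list()
for (design in c("gutbugs", "focus")) {
  cohort <- read_cohort(file.path("results", paste0("cohort_", design)))
  distances <- read_distances(
    file.path("results", paste0(design, "_distances.tsv")))
  opt <- jsonlite::read_json(
    file.path("results", paste0(design, "_baseline_optimum.json")))
  theta <- opt$theta
  matches <- apply_baseline_subtraction(
    call_candidate_matches(distances, cohort$roster, theta),
    distances, cohort$roster, theta)
  matches <- classify_novel_or_replacement(matches, cohort$abundance,
                                           cohort$roster)
  match_tables[[design]] <- matches
  donors <- sort(unique(cohort$roster$subject_id[cohort$roster$role == "donor"]))
  confusion <- score_against_reference(predict_pairings(matches),
                                       cohort$reference, donors,
                                       theta = theta)
  recall <- donor_recall(confusion)
  readr::write_tsv(recall,
                   file.path("results", paste0(design, "_donor_recall.tsv")))
  eff <- engraftment_efficiency(matches, cohort$alignments, cohort$roster,
                                cohort$reference)
  readr::write_tsv(eff,
                   file.path("results", paste0(design, "_efficiency.tsv")))
  per_donor <- eff |> group_by(donor) |>
    summarise(mean_eff = mean(efficiency), .groups = "drop")
  cat(sprintf(
    "[%s] theta %.3f: donor recall %.2f-%.2f (mean %.2f); mean efficiency per donor %.1f-%.1f%%\n",
    design, theta, min(recall$recall), max(recall$recall),
    mean(recall$recall), min(per_donor$mean_eff), max(per_donor$mean_eff)))
  joined <- inner_join(recall, per_donor, by = "donor")
  ct <- correlation_with_fit(joined$mean_eff, joined$recall)
  cat(sprintf("[%s] recall vs efficiency: Pearson r %.2f (p %.3g)\n",
              design, ct$r, ct$p_value))
  kw <- group_tests(eff$efficiency, eff$donor, type = "kruskal")
  cat(sprintf("[%s] efficiency differs between donors: Kruskal-Wallis p %.3g\n",
              design, kw$omnibus$p_value))
}

pt <- novel_fraction_comparison(match_tables$focus, match_tables$gutbugs)
cat(sprintf(
  "novel-strain fraction focus %d/%d vs gutbugs %d/%d: proportion test p = %.3f\n",
  pt$novel[1], pt$total[1], pt$novel[2], pt$total[2], pt$p_value))
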