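#!/usr/bin/env Rscript

# Stage 6: determinants of engraftment efficiency on the variable-pool
# ("focus") design: covariate table, correlations, donor alpha-diversity
# threshold, community-composition PERMANOVA, and the full/reduced linear
# mixed models compared by likelihood-ratio test.

suppressPackageStartupMessages({
  library(engraftr)
  library(dplyr)
})

design <- "focus"
cohort <- read_cohort(file.path("results", paste0("cohort_", design)))
matches <- readr::read_tsv(
  file.path("results", paste0(design, "_matches.tsv")),
  show_col_types = FALSE)
eff <- readr::read_tsv(
  file.path("results", paste0(design, "_efficiency.tsv")),
  show_col_types = FALSE)

functional <- cog_renormalise(cohort$cog)
covariates <- build_covariate_table(eff, cohort$abundance, functional,
                                    cohort$roster, cohort$reference)
readr::write_tsv(covariates, file.path("results", "focus_covariates.tsv"))

for (v in c("donor_alpha_mean", "bc_species_mean", "bc_functional_mean")) {
  ok <- stats::complete.cases(covariates[[v]], covariates$efficiency)
  ct <- correlation_with_fit(covariates[[v]][ok], covariates$efficiency[ok])
  cat(sprintf("efficiency vs %s: r = %.2f, R2 = %.2f, p = %.3g (n = %d)\n",
              v, ct$r, ct$r_squared, ct$p_value, ct$n))
}

thr <- alpha_threshold_summary(covariates, cut = 2.5)
cat(sprintf(
  "zero-efficiency pairings: %.0f%% below alpha 2.5 vs %.0f%% at/above (n = %d/%d)\n",
  100 * thr$below$fraction_zero, 100 * thr$above$fraction_zero,
  thr$below$n, thr$above$n))

# community composition: donors vs recipient baselines
roster <- cohort$roster
keep <- roster$sample_id[roster$role == "donor" |
                           (roster$role == "fmt_recipient" &
                              roster$timepoint == "baseline")]
ab <- cohort$abundance[cohort$abundance$sample_id %in% keep, ]
grp <- ifelse(grepl("^D", ab$sample_id), "donor", "recipient_baseline")
pn <- permanova(dissimilarity_matrix(ab, "bray"), grp,
                n_permutations = 999, seed = 2026)
cat(sprintf("PERMANOVA donors vs recipient baselines: F = %.2f, R2 = %.3f, p = %.3g\n",
            pn$pseudo_F, pn$r_squared, pn$p_value))

specs <- default_model_specs(include_batch_size = TRUE)
models <- fit_mixed_models(covariates, specs$full, specs$reduced)
jsonlite::write_json(
  list(full = models$full$effects, reduced = models$reduced$effects,
       lrt_p = models$lrt_p, lrt_df = models$lrt_df, n = models$n,
       ci_method = models$full$ci_method),
  file.path("results", "focus_models.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("LRT full (with interactions) vs reduced: p = %.3f on %d df (n = %d pairings)\n",
            models$lrt_p, models$lrt_df, models$n))
best <- if (models$lrt_p < 0.05) models$full else models$reduced
effects <- best$effects[best$effects$term != "(Intercept)", ]
cat("fixed effects of the selected model (b [95% CI], p):\n")
for (i in seq_len(nrow(effects))) {
  cat(sprintf("  %-28s %6.2f [%6.2f, %6.2f]  p = %.3g\n",
              effects$term[i], effects$estimate[i], effects$ci_lower[i],
              effects$ci_upper[i], effects$p_value[i]))
}
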