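#!/usr/bin/env Rscript

# Stage 2: per-species pairwise JC69 distances, median-normalised, and the
# intra- vs inter-subject distance split that motivates the strain-match
# threshold. Writes results/<design>_distances.tsv and a density summary.

suppressPackageStartupMessages(library(engraftr))

for (design in c("gutbugs", "focus")) {
  cohort <- read_cohort(file.path("results", paste0("cohort_", design)))
  distances <- normalise_by_species_median(
    pairwise_species_distances(cohort$alignments))
  write_distances(distances,
                  file.path("results", paste0(design, "_distances.tsv")))
  split <- distance_density_split(distances, cohort$roster)
  fin <- is.finite(split$normalised)
  med <- tapply(split$normalised[fin], split$pair_class[fin], median)
  cnt <- attr(split, "class_counts")
  cat(sprintf(
    "[%s] %d pairs (%d intra, %d inter); median normalised distance intra %.3f vs inter %.3f\n",
    design, nrow(distances), cnt["intra"], cnt["inter"],
    med["intra"], med["inter"]))
  cat(sprintf(
    "[%s] %.1f%% of intra-subject pairs fall at or below the 0.2 match threshold, %.1f%% of inter\n",
    design,
    100 * mean(split$normalised[fin & split$pair_class == "intra"] <= 0.2),
    100 * mean(split$normalised[fin & split$pair_class == "inter"] <= 0.2)))
}
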