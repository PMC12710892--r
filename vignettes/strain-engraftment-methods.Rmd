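---
title: "Donor strain engraftment analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor strain engraftment analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftr)
```

## The problem

In multi-donor faecal microbiota transplantation (FMT) trials, each
recipient is treated with stool pooled from several donors. After
treatment, strain-resolved metagenomics can ask: *which donors' strains
actually engrafted in which recipients?* If the trial is blinded, the
donor–recipient assignment itself can be predicted from strain sharing and
later validated against the unblinded pairings. `engraftr` implements this
analysis end to end, together with the downstream question of *why* some
donors engraft better than others.

The package consumes the outputs of a dominant-strain profiler: for each
bacterial species, a multiple alignment of one consensus marker sequence
per sample. Everything downstream — distances, matching, threshold
selection, efficiency, mixed models — is computed here.

## Strain distances

For two aligned consensus sequences, the mismatch proportion $p$ is
computed over jointly resolved sites (both residues in A/C/G/T; gaps and
ambiguous bases are pairwise-deleted), and converted to the Jukes–Cantor
(JC69) evolutionary distance

$$d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}p\right),$$

which corrects for multiple substitutions at one site under the
equal-rates model. For $p \ge 3/4$ the transform is undefined
(saturation); such pairs carry an `Inf` sentinel, are excluded from
medians, and can never satisfy a finite match threshold — this preserves
the monotonicity of matching in the threshold.

Species differ widely in background strain diversity, so raw distances are
not comparable across species. Each species' distances are therefore
divided by the **median of all of that species' finite pairwise
distances**. After normalisation the median pair of every species sits at
1, and a common threshold can be applied across species. The median is
taken over all pairs without stratifying by sample role; donor-batch
samples, when present, are included in the median by default (a flag
excludes them) but always excluded from the intra/inter-subject density
split, because a pooled batch is ambiguous as an intra- or inter-subject
comparison.

Degenerate case: a species whose median distance is zero (all retained
strains identical). Zero-distance pairs are then assigned normalised
distance 0, so identical strains remain matchable, and the species is
flagged; nonzero distances in such species map to the `Inf` sentinel.

## Matching and subtraction

A **candidate strain match** is a (species, donor sample, recipient
post-treatment sample) triple with normalised distance at or below the
threshold $\theta$. The boundary is inclusive ($\le \theta$); a strictness
flag switches to $<$.

Two subtraction steps remove matches that do not evidence engraftment:

* **Baseline subtraction** — if the same donor strain also matches the
  recipient's *own baseline* sample for that species, the strain was
  present before treatment and is of recipient origin. The test compares
  donor sample vs recipient baseline; an alternative reading (baseline vs
  post persistence) is available via `mode = "baseline_vs_post"`.
  Recipients without a baseline sample cannot be evaluated and are
  excluded (logged), not counted as negatives.
* **Placebo subtraction** — a (donor, species) combination that also
  survives in a placebo recipient is ambiguous background (e.g. a widely
  shared strain) and is flagged in every FMT recipient. The granularity is
  (donor subject, species), pooling the donor's samples, matching how
  efficiency is defined. The operation is a contraction and idempotent.

The distinctness unit throughout is the species: several donor samples
matching the same species in the same recipient count once. Surviving
matches are classified **novel** (species absent from the recipient's
baseline taxonomic profile) or **replacement** (species present at
baseline, so the donor strain displaced the resident conspecific strain).

## Pairing prediction and the threshold sweep

Each recipient's predicted donor set is every donor with at least one
distinct-species surviving match. Predictions are scored against the
reference pairings over all (donor, evaluable recipient) pairs —
evaluable meaning baseline and post samples exist — giving precision,
recall and F1 with 0/0 defined as 0 throughout (an empty prediction scores
zero, consistently penalised).

The sweep re-runs matching, subtraction, prediction and scoring at every
threshold on a grid (default 0.001–3.000 in steps of 0.001) and selects
the F1-optimal threshold, breaking ties toward the smallest (most
stringent) value. Baseline-origin flags are recomputed at every
$\theta$ — they are themselves threshold-dependent — and the placebo
background can either be recomputed per $\theta$ (default) or frozen at a
reference threshold. A cached candidate frame holding, for every
(species, donor sample, recipient) pair, the donor–post and
donor–baseline distances makes each grid point a vectorised filter rather
than a recomputation.

One consequence worth knowing: candidate-level recall is provably
non-decreasing in $\theta$, but *after* baseline subtraction recall can
decrease once $\theta$ crosses the inter-subject distance mode, because
donor–baseline pairs then begin to match and flag previously surviving
matches. The package's tests assert monotonicity for the candidate
pipeline over the whole grid and for the subtracted pipeline below the
inter-subject mode.

**Donor recall** is, per donor, the proportion of its true recipients
correctly predicted. **Engraftment efficiency** is, per true
(donor, recipient) pairing, the percentage of the donor's distinct
profiled species strains (pooled across the donor's samples) that survive
as matches in that recipient.

## Community metrics and PERMANOVA

Shannon diversity (natural log; `vegan::diversity`) is computed on species
abundances renormalised to sum to one, excluding the unknown fraction by
default (a flag includes it) — the index then describes the observed
community. Bray–Curtis and binary Jaccard dissimilarities come from
`vegan::vegdist`. The *Prevotella*/*Bacteroides* ratio sums genus-level
abundances using the species-name prefix (an explicit genus map
overrides); 0 with positive numerator yields `Inf`, 0/0 is undefined and
logged. COG functional profiles count each (gene, category) annotation
once, send unannotated genes to `NA`, divide by the number of genes, and
renormalise so each sample sums to one. Principal coordinates analysis is
classical MDS (`stats::cmdscale`); negative eigenvalues are reported, not
corrected.

PERMANOVA is implemented directly in the package as the one-term
distance-based linear model: the squared dissimilarities are Gower
double-centred to $G$, the predictor (categorical or continuous) forms a
hat matrix $H$, and the pseudo-$F$ compares $\mathrm{tr}(HG)$ against the
residual trace on their degrees of freedom. Significance uses raw
permutation of the observations (no residualisation), with
$p = (1 + \#\{F^\pi \ge F\}) / (1 + n_\text{perm})$, so $p$ has resolution
$1/(n_\text{perm}+1)$ and 999 permutations give a floor of 0.001. The
implementation is cross-checked in the tests against `vegan::adonis2`
(exact agreement of $F$ and $R^2$) and against exhaustive label
enumeration at $n = 5$; `adonis2` is never the implementation.

## Determinants of efficiency

The covariate table holds one row per true pairing: efficiency; mean donor
Shannon diversity and recipient baseline Shannon diversity; mean
donor–recipient species Bray–Curtis and binary Jaccard dissimilarity; mean
functional (COG) Bray–Curtis dissimilarity; donor and recipient P/B
ratios; and the batch size. For donors with several samples,
*dissimilarities are averaged over the donor's samples* rather than
computed on averaged profiles.

Linear mixed models (`lme4`, p-values via `lmerTest`/Satterthwaite) treat
the covariates as fixed effects and donor and recipient identities as
random intercepts. The full model adds the donor×recipient interactions
for alpha-diversity and P/B ratio; the reduced model omits them. The two
are compared by a likelihood-ratio test on maximum-likelihood refits
(REML likelihoods are not comparable across fixed-effect structures);
identical specifications return $p = 1$ by the 0-df convention. Effect
CIs are Wald by default — profile intervals are supported via
`ci_method = "profile"` but are slower and can fail on singular fits, so
the default favours robustness; the method used is recorded in the
output. Rows with missing *or non-finite* covariates (an `Inf` P/B ratio
is possible) are dropped complete-case per model, with a log line.
Efficiency is modelled on the percent scale, untransformed.

Group comparisons use `kruskal.test` with Dunn's post-hoc test —
implemented in the package from the standard rank-sum $z$ formulation
with tie correction, since no Dunn implementation ships with the
environment's packages, and verified in the tests against the identity
$z^2 = H$ for two groups — or `aov` + Tukey HSD, or the Wilcoxon rank-sum
test. Dunn comparisons are Holm-adjusted by default (the adjustment is a
parameter; Tukey HSD carries its own family-wise correction).

## The synthetic cohort generator

Real trial data require external profiling pipelines, so validation runs
on a generator that emulates the statistical structure the analysis
depends on, with full ground truth:

* **Lineage model.** Per species, a random root sequence; each strain
  lineage mutates the root independently at `d_inter` per site; each
  sample's consensus adds `d_intra` noise to its lineage. With the
  defaults (`d_intra` = 5×10⁻⁴, `d_inter` = 0.02) the normalised distance
  density is bimodal: intra-lineage pairs near 0.03, inter-lineage pairs
  near 1 — the separation that justifies a threshold around 0.2.
* **Carriage.** Subjects carry each species independently; donors at 0.26,
  recipients at 0.10 (healthy donors carry a richer strain complement
  than dysbiotic recipients), and the four *Bacteroides* index species at
  0.60 for everyone, so the P/B ratio is defined for nearly all samples.
  These rates put the strain yield at ~8 profiled strains per sample on
  average (range ~1–17) for 36 species.
* **Background sharing.** With probability `p_shared_lineage` (default
  0.01) a subject reuses another carrier's lineage — the source of
  false-positive matches and of the placebo background.
* **Engraftment.** Each recipient receives a donor pool (fixed 4 of 9
  donors by default; a variable 4–7-of-14 design is one argument away).
  Per (recipient, species), a single categorical draw decides which pool
  donor's strain (if any) becomes the dominant post-treatment strain;
  each donor's marginal probability equals its `donor_efficiency`,
  renormalised only if the pool's combined probability exceeds one. This
  keeps the truth set's one-donor-per-engrafted-species semantics and
  makes the efficiency estimator unbiased for the configured parameter.
  The default efficiency of 0.30 was chosen by a design-time power
  analysis: it gives ≈2.4 expected *detected* engraftment events per true
  pairing, enough for the sweep to recover pairings at F1 ≥ 0.9
  reliably, while lower efficiencies (the 0–15% band reported for real
  cohorts) remain a single-argument change for studies of the
  underpowered regime.
* **Detection.** Strain profiling drops out per (sample, species) with a
  probability logistic in log read depth (~0.9 at typical depths),
  emulating depth-limited strain recovery; read depths are log-uniform on
  10⁶–10⁷.
* **Ancillary tables.** Species abundances are Dirichlet-distributed over
  carried species with an explicit unknown fraction; COG annotations are
  multinomial around a subject-level profile over the 23 categories plus
  `NA`, with occasional multi-category genes.

A single seed fans out to independent child seeds per random stream
(roster, pools, carriage, lineages, events, sequences, dropout,
abundances, annotations), so sub-components are reproducible in
isolation and outputs are byte-identical across reruns.

**What the generator does not emulate:** real taxonomies and marker
lengths, within-sample strain mixtures (dominant strains only),
recombination or site-rate heterogeneity (JC69's equal-rates world is the
generator's world), longitudinal persistence beyond one post timepoint,
and ecological covariance between species. Passing tests therefore show
the *pipeline* is correct and well-calibrated under the stated model, not
that any particular biological effect size in real trials will be
recovered.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default cohort (9 donors,
24 FMT + 12 placebo recipients, 36 species, 1 kb markers) across 20 seeds
for the end-to-end recovery checks, sweep grids at 0.01 steps (the
package default remains 0.001 — grid resolution only affects runtime, and
a finer grid can only raise the selected F1), 200 replicates for the
PERMANOVA size and LRT-calibration checks, and exhaustive enumeration
oracles at small n (all 5! label permutations; brute-force per-site JC69
recounts on alignments up to 6×50). Ties in the F1 sweep break toward the
smallest threshold; 0/0 ratios are defined as 0 in scoring; saturated
JC69 pairs are `Inf`, never dropped silently; all exclusions (missing
baselines, zero-gene samples, donors without strains) are logged with a
reason.

## Known limitations

* One post-treatment timepoint; persistence at later follow-ups is out of
  scope.
* One-term PERMANOVA only (no stratification or multi-term models).
* The per-COG-category difference model fits ~24 fixed effects and is
  honest only when pairings clearly outnumber categories.
* Efficiency is a ratio of detected counts; with shallow sequencing the
  denominator (donor strains) and numerator (recovered events) both
  shrink, and the estimator inherits that noise.
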