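#' Assemble the per-pairing covariate table for the efficiency models
#'
#' One row per true (donor, recipient) pairing, collating engraftment
#' efficiency with the candidate determinants: mean donor alpha-diversity
#' (Shannon, over the donor's samples), recipient baseline alpha-diversity,
#' mean donor-recipient species beta-diversity (Bray-Curtis and binary
#' Jaccard; dissimilarities are averaged over the donor's samples, not
#' computed on mean profiles), mean donor-recipient functional (COG)
#' Bray-Curtis beta-diversity, donor and recipient Prevotella/Bacteroides
#' ratios, and the FMT batch size. Pairings whose samples lack a functional
#' profile carry `NA` in `bc_functional_mean` (logged).
#'
#' @param efficiency [engraftment_efficiency()] output (`donor`,
#'   `recipient`, `efficiency`).
#' @param abundances Wide species abundance table.
#' @param functional_profiles [cog_renormalise()] output, or `NULL` to skip
#'   the functional covariate.
#' @param roster Sample metadata.
#' @param reference Long reference pairing table.
#' @return Tibble with one row per pairing: `donor_id`, `recipient_id`,
#'   `efficiency`, `donor_alpha_mean`, `recipient_alpha_baseline`,
#'   `bc_species_mean`, `jaccard_species_mean`, `bc_functional_mean`,
#'   `donor_pb_mean`, `recipient_pb`, `batch_size`.
#' @export
build_covariate_table <- function(efficiency, abundances,
                                  functional_profiles = NULL, roster,
                                  reference) {
  roster_check(roster)
  ref <- dplyr::distinct(reference[, c("donor", "recipient")])
  unknown <- setdiff(unique(c(ref$donor, ref$recipient)), roster$subject_id)
  if (length(unknown) > 0) {
    stop("pairing references unknown subjects: ",
         paste(unknown, collapse = ", "))
  }
  base_map <- baseline_sample_map(roster)
  donor_samples <- split(roster$sample_id[roster$role == "donor"],
                         roster$subject_id[roster$role == "donor"])

  alpha <- vapply(seq_len(nrow(abundances)), function(i)
    tryCatch(shannon_index(abundances[i, ]), error = function(e) NA_real_),
    numeric(1))
  names(alpha) <- abundances$sample_id
  if (anyNA(alpha)) {
    eg_log("covariates", paste0(
      "all-zero abundance profile(s); alpha-diversity set NA: ",
      paste(names(alpha)[is.na(alpha)], collapse = ", ")), "WARN")
  }
  pb <- vapply(seq_len(nrow(abundances)), function(i)
    suppressMessages(pb_ratio(abundances[i, ])), numeric(1))
  names(pb) <- abundances$sample_id

  bc <- suppressWarnings(as.matrix(dissimilarity_matrix(abundances, "bray")))
  jac <- suppressWarnings(as.matrix(dissimilarity_matrix(abundances,
                                                         "jaccard")))
  fmat <- if (!is.null(functional_profiles))
    functional_matrix(functional_profiles) else NULL
  fbc <- if (!is.null(fmat) && nrow(fmat) > 1)
    as.matrix(vegan::vegdist(fmat, "bray")) else NULL

  batch <- table(ref$recipient)
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    d <- ref$donor[i]; r <- ref$recipient[i]
    ds <- donor_samples[[d]]
    bs <- base_map[[r]]
    fb <- NA_real_
    if (!is.null(fbc)) {
      ok_d <- intersect(ds, rownames(fbc))
      if (length(ok_d) > 0 && !is.null(bs) && bs %in% rownames(fbc)) {
        fb <- mean(fbc[ok_d, bs])
      } else {
        eg_log("covariates", paste0("functional profile missing for pairing ",
                                    d, "-", r), "WARN")
      }
    }
    tibble::tibble(
      donor_id = d, recipient_id = r,
      donor_alpha_mean = mean(alpha[ds]),
      recipient_alpha_baseline = alpha[[bs]],
      bc_species_mean = mean(bc[ds, bs]),
      jaccard_species_mean = mean(jac[ds, bs]),
      bc_functional_mean = fb,
      donor_pb_mean = mean(pb[ds]),
      recipient_pb = pb[[bs]],
      batch_size = as.integer(batch[[r]]))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::inner_join(
    dplyr::rename(efficiency, donor_id = "donor", recipient_id = "recipient"),
    out, by = c("donor_id", "recipient_id"))
  dplyr::arrange(out, .data$donor_id, .data$recipient_id)
}

#' Specify a linear mixed model for engraftment efficiency
#'
#' @param fixed_effects Character vector of covariate names.
#' @param interactions List of character pairs (each must appear among the
#'   fixed effects).
#' @param random_effects Grouping variables given random intercepts.
#' @return A `mixed_model_spec`.
#' @export
mixed_model_spec <- function(fixed_effects,
                             interactions = list(),
                             random_effects = c("donor_id", "recipient_id")) {
  for (pair in interactions) {
    stopifnot(length(pair) == 2, all(pair %in% fixed_effects))
  }
  structure(list(fixed_effects = fixed_effects, interactions = interactions,
                 random_effects = random_effects),
            class = "mixed_model_spec")
}

spec_formula <- function(spec, response = "efficiency") {
  fixed <- spec$fixed_effects
  ints <- vapply(spec$interactions, function(p) paste(p, collapse = ":"),
                 character(1))
  rand <- paste0("(1 | ", spec$random_effects, ")")
  stats::as.formula(paste(response, "~",
                          paste(c(fixed, ints, rand), collapse = " + ")))
}

fit_one_lmm <- function(formula, data, ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    eg_log("lmm", "singular random-effect fit; retained and flagged", "WARN")
  }
  cf <- stats::coef(summary(fit))
  ci <- suppressMessages(stats::confint(
    fit, parm = "beta_", method = if (ci_method == "wald") "Wald" else "profile"))
  effects <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    ci_lower = ci[rownames(cf), 1],
    ci_upper = ci[rownames(cf), 2],
    p_value = cf[, "Pr(>|t|)"])
  list(effects = effects, fit = fit, singular = singular,
       ci_method = ci_method,
       log_likelihood = as.numeric(stats::logLik(fit)))
}

#' Fit full and reduced efficiency mixed models with a likelihood-ratio test
#'
#' Both models are fitted by REML for effect reporting (estimates, CIs,
#' Satterthwaite p-values) and refitted by maximum likelihood for the LRT,
#' since the fixed-effect structures differ. Complete cases for the full
#' model's covariates are used for both fits so the LRT compares the same
#' data.
#'
#' @param table Covariate table from [build_covariate_table()].
#' @param spec_full,spec_reduced [mixed_model_spec()]s; the reduced model
#'   must be nested in the full one.
#' @param standardise Z-score the fixed-effect covariates before fitting.
#' @param ci_method `"wald"` (default) or `"profile"` confidence intervals;
#'   the method used is recorded in the output.
#' @return List with `full`, `reduced` (each: `effects`, `fit`, `singular`,
#'   `ci_method`, `log_likelihood`), `lrt_p`, `lrt_df`, `n`.
#' @export
fit_mixed_models <- function(table, spec_full, spec_reduced,
                             standardise = FALSE, ci_method = "wald") {
  vars <- unique(c(spec_full$fixed_effects, spec_reduced$fixed_effects))
  need <- c("efficiency", vars, spec_full$random_effects)
  stopifnot(all(need %in% names(table)))
  num <- c("efficiency", vars)
  finite <- rowSums(!sapply(table[, num], is.finite)) == 0
  if (any(!finite)) {
    eg_log("lmm", sprintf(
      "%d pairing(s) with missing or non-finite covariates dropped (complete-case)",
      sum(!finite)), "WARN")
  }
  data <- table[finite, need]
  if (standardise) {
    for (v in vars) data[[v]] <- as.numeric(scale(data[[v]]))
  }
  f_full <- spec_formula(spec_full)
  f_red <- spec_formula(spec_reduced)
  full <- fit_one_lmm(f_full, data, ci_method)
  reduced <- fit_one_lmm(f_red, data, ci_method)
  same <- identical(deparse(f_full), deparse(f_red))
  if (same) {
    lrt_p <- 1; lrt_df <- 0L
  } else {
    full_ml <- suppressMessages(lme4::lmer(f_full, data = data,
                                           REML = FALSE))
    red_ml <- suppressMessages(lme4::lmer(f_red, data = data, REML = FALSE))
    an <- suppressMessages(stats::anova(red_ml, full_ml))
    lrt_p <- an$`Pr(>Chisq)`[2]
    lrt_df <- an$Df[2]
  }
  list(full = full, reduced = reduced, lrt_p = lrt_p, lrt_df = lrt_df,
       n = nrow(data))
}

#' Per-COG-category difference mixed model
#'
#' Builds, for each pairing, the mean difference in renormalised COG
#' category abundance between the donor's samples and the recipient's
#' baseline sample, and fits a mixed model of efficiency on these
#' differences with random intercepts for donor and recipient. Categories
#' absent from every sample are dropped with a warning.
#'
#' @param table Covariate table (supplies `efficiency`, `donor_id`,
#'   `recipient_id`).
#' @param functional_profiles [cog_renormalise()] output.
#' @param roster Sample metadata.
#' @param reference Long reference pairing table.
#' @param ci_method Confidence-interval method, as in [fit_mixed_models()].
#' @return List: `effects`-style model fit (as [fit_mixed_models()] single
#'   model) plus `differences`, the per-pairing covariate tibble.
#' @export
per_category_difference_model <- function(table, functional_profiles, roster,
                                          reference, ci_method = "wald") {
  fmat <- functional_matrix(functional_profiles)
  present <- colnames(fmat)[colSums(fmat) > 0]
  dropped <- setdiff(colnames(fmat), present)
  if (length(dropped) > 0) {
    warning("categories absent everywhere dropped: ",
            paste(dropped, collapse = ", "))
  }
  fmat <- fmat[, present, drop = FALSE]
  base_map <- baseline_sample_map(roster)
  donor_samples <- split(roster$sample_id[roster$role == "donor"],
                         roster$subject_id[roster$role == "donor"])
  ref <- dplyr::distinct(reference[, c("donor", "recipient")])
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    ds <- intersect(donor_samples[[ref$donor[i]]], rownames(fmat))
    bs <- base_map[[ref$recipient[i]]]
    if (length(ds) == 0 || is.null(bs) || !bs %in% rownames(fmat)) return(NULL)
    diffs <- colMeans(fmat[ds, , drop = FALSE]) - fmat[bs, ]
    tibble::as_tibble(c(list(donor_id = ref$donor[i],
                             recipient_id = ref$recipient[i]),
                        as.list(stats::setNames(diffs,
                                                paste0("cog_", present)))))
  })
  diffs <- dplyr::bind_rows(rows)
  data <- dplyr::inner_join(
    table[, c("donor_id", "recipient_id", "efficiency")], diffs,
    by = c("donor_id", "recipient_id"))
  covs <- paste0("cog_", present)
  f <- stats::as.formula(paste("efficiency ~",
                               paste(covs, collapse = " + "),
                               "+ (1 | donor_id) + (1 | recipient_id)"))
  fit <- fit_one_lmm(f, data, ci_method)
  c(fit, list(differences = diffs, n = nrow(data)))
}

#' Pearson correlation with a linear fit
#'
#' Standard Pearson correlation (two-sided t-test) together with the
#' ordinary least-squares slope and intercept, as used for the
#' efficiency-vs-covariate scatterplots.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return List: `r`, `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlation_with_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate) ^ 2,
       p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x))
}

#' Dunn's post-hoc test of multiple comparisons using rank sums
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the
#' standard tie correction, two-sided p-values, and multiple-testing
#' adjustment.
#'
#' @param values Numeric vector.
#' @param group Group labels aligned with `values`.
#' @param p_adjust Adjustment method for [stats::p.adjust()] (default Holm).
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "holm") {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) > 0))
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties ^ 3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, group, mean)
  sizes <- table(group)
  combs <- utils::combn(levels(group), 2)
  z <- apply(combs, 2, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[g[1]]] + 1 / sizes[[g[2]]]))
    (mean_rank[[g[1]]] - mean_rank[[g[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group1 = combs[1, ], group2 = combs[2, ], z = z,
                 p_value = p, p_adjusted = stats::p.adjust(p, p_adjust))
}

#' Omnibus group comparison with post-hoc tests
#'
#' `"kruskal"`: Kruskal-Wallis rank-sum omnibus with Dunn post-hoc
#' comparisons (Holm-adjusted by default). `"anova"`: one-way ANOVA with
#' Tukey Honest Significant Differences (family-wise correction inherent).
#' `"wilcoxon"`: two-group Wilcoxon rank-sum test (no post-hoc).
#'
#' @param values Numeric vector.
#' @param group Group labels aligned with `values`.
#' @param type Test family.
#' @param p_adjust Post-hoc adjustment for the Dunn test.
#' @return List: `omnibus` (`method`, `statistic`, `p_value`) and `posthoc`
#'   (tibble with adjusted p-values, or `NULL`).
#' @export
group_tests <- function(values, group,
                        type = c("kruskal", "anova", "wilcoxon"),
                        p_adjust = "holm") {
  type <- match.arg(type)
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) > 0))
  if (type == "kruskal") {
    kw <- stats::kruskal.test(values, group)
    posthoc <- dunn_test(values, group, p_adjust)
    omnibus <- list(method = "Kruskal-Wallis rank sum test",
                    statistic = unname(kw$statistic), p_value = kw$p.value)
  } else if (type == "anova") {
    fit <- stats::aov(values ~ group)
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    posthoc <- tibble::tibble(
      group1 = vapply(pairs, `[`, "", 1),
      group2 = vapply(pairs, `[`, "", 2),
      diff = unname(tk[, "diff"]), p_value = unname(tk[, "p adj"]),
      p_adjusted = unname(tk[, "p adj"]))
    omnibus <- list(method = "one-way ANOVA",
                    statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1])
  } else {
    stopifnot(nlevels(group) == 2)
    wt <- stats::wilcox.test(values[group == levels(group)[1]],
                             values[group == levels(group)[2]])
    posthoc <- NULL
    omnibus <- list(method = "Wilcoxon rank sum test",
                    statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Zero-efficiency fractions below and above a donor alpha-diversity cut
#'
#' Quantifies the apparent minimal-donor-diversity threshold: among
#' pairings with mean donor Shannon diversity below vs at/above `cut`, the
#' fraction with zero engraftment efficiency.
#'
#' @param table Covariate table.
#' @param cut Shannon-diversity cut in nats (default 2.5).
#' @return List: `below` and `above` (each `n`, `n_zero`, `fraction_zero`).
#' @export
alpha_threshold_summary <- function(table, cut = 2.5) {
  stopifnot(nrow(table) > 0)
  lo <- table$donor_alpha_mean < cut
  frac <- function(idx) {
    n <- sum(idx)
    nz <- sum(table$efficiency[idx] == 0)
    list(n = n, n_zero = nz, fraction_zero = if (n == 0) 0 else nz / n)
  }
  list(cut = cut, below = frac(lo), above = frac(!lo))
}
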