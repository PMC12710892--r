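make_covariate_fixture <- function() {
  roster <- tibble::tibble(
    sample_id = c("D1-S1", "D1-S2", "D2-S1", "R1-BL", "R1-WK"),
    subject_id = c("D1", "D1", "D2", "R1", "R1"),
    role = c("donor", "donor", "donor", "fmt_recipient", "fmt_recipient"),
    timepoint = c("donation", "donation", "donation", "baseline", "post"),
    read_count = 1L)
  ab <- tibble::tibble(
    sample_id = c("D1-S1", "D1-S2", "D2-S1", "R1-BL", "R1-WK"),
    Prevotella_sp01 = c(0.25, 0.10, 0.05, 0.10, 0.1),
    Bacteroides_sp01 = c(0.25, 0.40, 0.45, 0.10, 0.1),
    Clostridium_sp01 = c(0.25, 0.25, 0.25, 0.40, 0.4),
    Clostridium_sp02 = c(0.25, 0.25, 0.25, 0.40, 0.4))
  eff <- tibble::tibble(donor = c("D1", "D2"), recipient = "R1",
                        n_donor_strains = c(10L, 8L),
                        n_engrafted = c(2L, 0L), efficiency = c(20, 0))
  ref <- tibble::tibble(recipient = "R1", donor = c("D1", "D2"))
  list(roster = roster, ab = ab, eff = eff, ref = ref)
}

test_that("covariate table collates means as hand-computed", {
  f <- make_covariate_fixture()
  tab <- build_covariate_table(f$eff, f$ab, NULL, f$roster, f$ref)
  expect_equal(nrow(tab), 2)
  r1 <- tab[tab$donor_id == "D1", ]
  # donor alpha mean over the two donor samples
  a1 <- shannon_index(f$ab[1, ]); a2 <- shannon_index(f$ab[2, ])
  expect_equal(r1$donor_alpha_mean, mean(c(a1, a2)))
  expect_equal(r1$recipient_alpha_baseline, shannon_index(f$ab[4, ]))
  # dissimilarities averaged over donor samples, not on mean profiles
  bc1 <- bray_curtis(f$ab[1, ], f$ab[4, ])
  bc2 <- bray_curtis(f$ab[2, ], f$ab[4, ])
  expect_equal(r1$bc_species_mean, mean(c(bc1, bc2)))
  # P/B ratios
  expect_equal(r1$donor_pb_mean, mean(c(0.25 / 0.25, 0.10 / 0.40)))
  expect_equal(r1$recipient_pb, 1)
  expect_equal(r1$batch_size, 2L)
  expect_equal(r1$efficiency, 20)
  # deterministic and row-order invariant
  tab2 <- build_covariate_table(f$eff[2:1, ], f$ab, NULL, f$roster,
                                f$ref[2:1, ])
  expect_equal(tab, tab2)
  # unknown subject rejected
  bad_ref <- tibble::tibble(recipient = "R9", donor = "D1")
  expect_error(build_covariate_table(f$eff, f$ab, NULL, f$roster, bad_ref),
               "R9")
})

test_that("FOCUS-like pools give batch sizes in 4-7", {
  co <- generate_cohort(cohort_config(
    n_donors = 14, pool_size_range = c(4L, 7L), n_fmt_recipients = 8,
    n_placebo_recipients = 4, n_species = 12, marker_length = 200,
    seed = 44))
  ref <- true_pairings_table(co$truth)
  sizes <- table(ref$recipient)
  expect_true(all(sizes >= 4 & sizes <= 7))
})

test_that("correlation_with_fit reproduces closed-form Pearson arithmetic", {
  r <- correlation_with_fit(c(0, 1, 2), c(0, 1, 4))
  expect_equal(round(r$r, 4), 0.9608)
  expect_equal(r$r_squared, r$r ^ 2, tolerance = 1e-12)
  perfect <- correlation_with_fit(1:10, 2 * (1:10))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  set.seed(8)
  null <- correlation_with_fit(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_error(correlation_with_fit(rep(1, 5), 1:5), "zero variance")
})

test_that("group tests: exact Wilcoxon example, Dunn/KW identity, Tukey flags", {
  # exact two-sided rank-sum p for fully separated 3 vs 3
  w <- group_tests(c(1, 2, 3, 101, 102, 103),
                   rep(c("a", "b"), each = 3), type = "wilcoxon")
  expect_equal(w$omnibus$p_value, 0.1)
  # for two groups the Dunn z^2 equals the KW chi-square statistic
  set.seed(14)
  vals <- c(stats::rnorm(8), stats::rnorm(6, 1))
  grp <- rep(c("a", "b"), c(8, 6))
  kw <- group_tests(vals, grp, type = "kruskal")
  expect_equal(kw$posthoc$z ^ 2, kw$omnibus$statistic, tolerance = 1e-10)
  # ... including under ties
  vals_t <- c(1, 1, 2, 3, 3, 3, 4, 5, 5, 6)
  grp_t <- rep(c("a", "b"), each = 5)
  kw_t <- group_tests(vals_t, grp_t, type = "kruskal")
  expect_equal(kw_t$posthoc$z ^ 2, kw_t$omnibus$statistic, tolerance = 1e-10)
  # a strongly shifted group is flagged exactly in its pairwise contrasts
  set.seed(15)
  vals3 <- c(stats::rnorm(10), stats::rnorm(10), stats::rnorm(10, 10))
  grp3 <- rep(c("a", "b", "c"), each = 10)
  tk <- group_tests(vals3, grp3, type = "anova")
  expect_lt(tk$omnibus$p_value, 1e-6)
  hit <- tk$posthoc$p_adjusted < 0.01
  involved <- tk$posthoc$group1 == "c" | tk$posthoc$group2 == "c"
  expect_equal(hit, involved)
  dn <- group_tests(vals3, grp3, type = "kruskal")
  hit_d <- dn$posthoc$p_adjusted < 0.01
  involved_d <- dn$posthoc$group1 == "c" | dn$posthoc$group2 == "c"
  expect_equal(hit_d, involved_d)
})

test_that("mixed models recover a simulated donor P/B effect and the LRT conventions", {
  sim_table <- function(seed, beta = 5) {
    set.seed(seed)
    donors <- paste0("D", 1:15); recips <- paste0("R", 1:10)
    tab <- tidyr::expand_grid(donor_id = donors, recipient_id = recips)
    d_int <- stats::setNames(stats::rnorm(15, 0, 2), donors)
    tab$donor_pb_mean <- stats::runif(nrow(tab), 0, 3)
    tab$donor_alpha_mean <- stats::rnorm(nrow(tab), 2.5, 0.5)
    tab$efficiency <- 5 + beta * tab$donor_pb_mean +
      d_int[tab$donor_id] + stats::rnorm(nrow(tab), 0, 1)
    tab
  }
  spec1 <- mixed_model_spec(c("donor_pb_mean", "donor_alpha_mean"))
  tab <- sim_table(1)
  fit <- fit_mixed_models(tab, spec1, spec1)
  eff <- fit$full$effects
  row <- eff[eff$term == "donor_pb_mean", ]
  expect_gt(row$estimate, 4.5); expect_lt(row$estimate, 5.5)
  expect_true(row$ci_lower <= 5 && 5 <= row$ci_upper)
  expect_lt(row$p_value, 1e-6)
  # identical specs give the 0-df LRT convention p = 1
  expect_equal(fit$lrt_p, 1)
  expect_equal(fit$lrt_df, 0L)
  # nested comparison: adding a null interaction is not significant,
  # and the true effect's interval covers the simulated value repeatedly
  spec_full <- mixed_model_spec(c("donor_pb_mean", "donor_alpha_mean"),
                                list(c("donor_pb_mean", "donor_alpha_mean")))
  cover <- 0
  for (s in 1:5) {
    f <- fit_mixed_models(sim_table(s), spec_full, spec1)
    e <- f$reduced$effects
    r <- e[e$term == "donor_pb_mean", ]
    cover <- cover + (r$ci_lower <= 5 && 5 <= r$ci_upper)
    expect_gte(f$lrt_p, 0); expect_lte(f$lrt_p, 1)
  }
  expect_gte(cover, 4)
})

test_that("per-category difference model: zero differences and a recovered shift", {
  donor_ids <- paste0("D", 1:3)
  donor_smp <- paste0(donor_ids, "-S1")
  roster <- dplyr::bind_rows(
    tibble::tibble(sample_id = donor_smp, subject_id = donor_ids,
                   role = "donor", timepoint = "donation", read_count = 1L),
    tibble::tibble(sample_id = c("R1-BL", "R1-WK", "R2-BL", "R2-WK"),
                   subject_id = c("R1", "R1", "R2", "R2"),
                   role = "fmt_recipient",
                   timepoint = rep(c("baseline", "post"), 2),
                   read_count = 1L))
  ref <- tidyr::expand_grid(recipient = c("R1", "R2"), donor = donor_ids)
  # identical profiles -> all difference covariates zero
  fp_same <- tibble::tibble(
    sample_id = rep(c(donor_smp, "R1-BL", "R2-BL"), each = 2),
    category = rep(c("J", "K"), 5), abundance = rep(c(0.4, 0.6), 5))
  tab <- tibble::tibble(donor_id = ref$donor, recipient_id = ref$recipient,
                        efficiency = c(10, 20, 5, 8, 12, 3))
  diffs <- NULL
  fit <- tryCatch(per_category_difference_model(tab, fp_same, roster, ref),
                  warning = function(w) suppressWarnings(
                    per_category_difference_model(tab, fp_same, roster, ref)))
  expect_true(all(abs(as.matrix(fit$differences[, c("cog_J", "cog_K")])) < 1e-12))
  # a +0.1 shift in one category appears exactly there
  fp_shift <- fp_same
  fp_shift$abundance[fp_shift$sample_id %in% donor_smp] <-
    rep(c(0.5, 0.5), 3)
  fit2 <- tryCatch(per_category_difference_model(tab, fp_shift, roster, ref),
                   warning = function(w) suppressWarnings(
                     per_category_difference_model(tab, fp_shift, roster, ref)))
  expect_equal(unname(unlist(fit2$differences[, "cog_J"])), rep(0.1, 6))
  expect_equal(unname(unlist(fit2$differences[, "cog_K"])), rep(-0.1, 6))
})

test_that("alpha threshold summary computes zero-efficiency fractions", {
  tab <- tibble::tibble(donor_alpha_mean = c(1, 2, 3, 4),
                        efficiency = c(0, 0, 5, 10))
  s <- alpha_threshold_summary(tab, cut = 2.5)
  expect_equal(s$below$fraction_zero, 1)
  expect_equal(s$above$fraction_zero, 0)
  # all positive efficiencies -> both fractions zero
  tab2 <- tibble::tibble(donor_alpha_mean = c(1, 3), efficiency = c(2, 2))
  s2 <- alpha_threshold_summary(tab2)
  expect_equal(c(s2$below$fraction_zero, s2$above$fraction_zero), c(0, 0))
  # fixture: 2 zero-efficiency of 4 below the cut
  tab3 <- tibble::tibble(donor_alpha_mean = c(1, 1.5, 2, 2.2, 3),
                         efficiency = c(0, 0, 4, 6, 1))
  expect_equal(alpha_threshold_summary(tab3, 2.5)$below$fraction_zero, 0.5)
})
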