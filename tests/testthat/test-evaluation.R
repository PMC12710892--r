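test_that("pairing prediction counts distinct species per donor", {
  m <- tibble::tibble(
    species = c("s1", "s2", "s3", "s1", "s1"),
    donor_subject = c("D1", "D1", "D1", "D3", "D2"),
    donor_sample = c("D1-S1", "D1-S1", "D1-S2", "D3-S1", "D2-S1"),
    recipient_subject = c("R1", "R1", "R1", "R1", "R2"),
    recipient_post_sample = "wk",
    normalised_distance = 0.1, flag_baseline_origin = FALSE,
    flag_placebo_background = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    surviving = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    class = "unclassified")
  p <- predict_pairings(m)
  expect_equal(p$counts$n_species[p$counts$recipient == "R1" &
                                    p$counts$donor == "D1"], 3L)
  expect_setequal(p$predicted$R1, c("D1", "D3"))
  expect_null(p$predicted$R2)  # only a non-surviving match
  # empty matches give an empty prediction
  p0 <- predict_pairings(m[0, ])
  expect_equal(nrow(p0$counts), 0)
})

test_that("confusion scoring matches the derived toy example and conventions", {
  reference <- tibble::tibble(recipient = c("r1", "r1", "r2", "r2"),
                              donor = c("D1", "D2", "D2", "D3"))
  counts <- tibble::tibble(recipient = c("r1", "r2", "r2"),
                           donor = c("D1", "D2", "D1"),
                           n_species = c(2L, 1L, 4L))
  s <- score_against_reference(counts, reference, donors = c("D1", "D2", "D3"))
  expect_equal(c(s$tp, s$fp, s$fn, s$tn), c(2, 1, 2, 1))
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 1 / 2)
  expect_equal(s$f1, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2))
  # perfect prediction
  sp <- score_against_reference(
    tibble::tibble(recipient = reference$recipient,
                   donor = reference$donor, n_species = 1L),
    reference, donors = c("D1", "D2", "D3"))
  expect_equal(c(sp$fp, sp$fn), c(0, 0))
  expect_equal(sp$f1, 1)
  # empty prediction: all-zero conventions
  se <- score_against_reference(counts[0, ], reference,
                                donors = c("D1", "D2", "D3"))
  expect_equal(c(se$tp, se$recall, se$f1, se$precision), c(0, 0, 0, 0))
  # unknown recipient rejected
  expect_error(score_against_reference(
    tibble::tibble(recipient = "zz", donor = "D1", n_species = 1L),
    reference, donors = "D1"), "zz")
})

test_that("confusion scoring equals exhaustive enumeration on random cases", {
  set.seed(1234)
  donors <- paste0("D", 1:5)
  recipients <- paste0("r", 1:6)
  for (case in 1:200) {
    reference <- dplyr::bind_rows(lapply(recipients, function(r)
      tibble::tibble(recipient = r,
                     donor = sample(donors, sample(0:4, 1)))))
    pred_sets <- lapply(recipients, function(r)
      sample(donors, sample(0:5, 1)))
    names(pred_sets) <- recipients
    counts <- dplyr::bind_rows(lapply(recipients, function(r)
      if (length(pred_sets[[r]]) > 0)
        tibble::tibble(recipient = r, donor = pred_sets[[r]],
                       n_species = 1L)))
    if (nrow(reference) == 0) next
    s <- score_against_reference(
      counts %||% tibble::tibble(recipient = character(),
                                 donor = character(), n_species = integer()),
      reference, donors, recipients = recipients)
    want <- enumerate_confusion(pred_sets, reference, donors, recipients)
    expect_equal(c(tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn), want)
    expect_equal(s$tp + s$fp + s$tn + s$fn,
                 length(donors) * length(recipients))
  }
})

test_that("per-donor recall identities hold", {
  reference <- tibble::tibble(recipient = c("r1", "r1", "r2", "r3"),
                              donor = c("D1", "D2", "D1", "D1"))
  counts <- tibble::tibble(recipient = c("r1", "r2"),
                           donor = c("D1", "D1"), n_species = 1L)
  s <- score_against_reference(counts, reference, donors = c("D1", "D2", "D3"))
  rec <- suppressMessages(donor_recall(s))
  expect_equal(rec$recall[rec$donor == "D1"], 2 / 3)
  expect_equal(rec$recall[rec$donor == "D2"], 0)
  expect_false("D3" %in% rec$donor)  # no true recipients -> excluded
  # tp + fn per donor = number of true recipients
  expect_equal(rec$n_true, c(3L, 1L))
  # recipient-weighted mean of per-donor recalls = overall recall
  expect_equal(sum(rec$recall * rec$n_true) / sum(rec$n_true), s$recall)
})

test_that("threshold sweep reproduces the single-theta pipeline at each point", {
  co <- small_cohort(seed = 10)
  d <- suppressMessages(cohort_distances(co))
  ref <- true_pairings_table(co$truth)
  donors <- sort(unique(co$roster$subject_id[co$roster$role == "donor"]))
  sw <- threshold_sweep(d, co$roster, co$abundance, ref,
                        theta_grid = c(0.05, 0.2, 0.8),
                        use_placebo_subtraction = TRUE)
  for (i in seq_len(3)) {
    th <- sw$summaries$theta[i]
    plc <- apply_baseline_subtraction(
      call_candidate_matches(d, co$roster, th, "placebo_recipient"),
      d, co$roster, th)
    m <- apply_placebo_subtraction(
      apply_baseline_subtraction(
        call_candidate_matches(d, co$roster, th), d, co$roster, th),
      plc)
    s <- score_against_reference(predict_pairings(m), ref, donors)
    expect_equal(unlist(sw$summaries[i, c("tp", "fp", "tn", "fn")]),
                 c(tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn),
                 label = paste("theta", th))
  }
  # single-value grid returns that value
  one <- threshold_sweep(d, co$roster, co$abundance, ref, theta_grid = 0.2)
  expect_equal(one$optimum$theta, 0.2)
  expect_error(threshold_sweep(d, co$roster, co$abundance, ref,
                               theta_grid = numeric(0)), "empty")
})

test_that("recall is non-decreasing in theta where matching is monotone", {
  co <- small_cohort(seed = 13)
  d <- suppressMessages(cohort_distances(co))
  ref <- true_pairings_table(co$truth)
  donors <- sort(unique(co$roster$subject_id[co$roster$role == "donor"]))
  # candidate matching without subtraction is monotone over any grid
  rec <- vapply(c(0.02, 0.2, 0.6, 1.2, 2, 3), function(th) {
    m <- call_candidate_matches(d, co$roster, th)
    score_against_reference(predict_pairings(m), ref, donors)$recall
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  # with baseline subtraction the guarantee holds below the inter-subject
  # mode, where donor-baseline pairs cannot yet flag matches
  sw <- threshold_sweep(d, co$roster, co$abundance, ref,
                        theta_grid = seq(0.02, 0.8, by = 0.05))
  expect_true(all(diff(sw$summaries$recall) >= 0))
})

test_that("sweep optimum lands between the distance modes and F1 does not improve past the gap", {
  co <- small_cohort(seed = 21, detection_rate = 1, p_shared_lineage = 0,
                     d_intra = 0.002, donor_efficiency = 0.5)
  d <- suppressMessages(cohort_distances(co))
  ref <- true_pairings_table(co$truth)
  sw <- threshold_sweep(d, co$roster, co$abundance, ref,
                        theta_grid = seq(0.01, 3, by = 0.01))
  # the optimum sits below the inter-subject mode (normalised ~1) ...
  expect_lt(sw$optimum$theta, 0.8)
  # ... improves on the smallest threshold ...
  expect_gt(sw$optimum$f1, sw$summaries$f1[1])
  # ... and entering the inter mode only adds false positives
  f1_end <- sw$summaries$f1[nrow(sw$summaries)]
  expect_gte(sw$optimum$f1, f1_end)
})

test_that("engraftment efficiency counts distinct pooled donor species", {
  roster <- tibble::tibble(
    sample_id = c("D1-S1", "D1-S2", "D2-S1", "R1-BL", "R1-WK"),
    subject_id = c("D1", "D1", "D2", "R1", "R1"),
    role = c("donor", "donor", "donor", "fmt_recipient", "fmt_recipient"),
    timepoint = c("donation", "donation", "donation", "baseline", "post"),
    read_count = 1L)
  # D1 has strains for 10 species pooled over its two samples
  aln <- c(
    lapply(1:6, function(i) c("D1-S1" = "ACGT", "R1-WK" = "ACGT")),
    lapply(7:10, function(i) c("D1-S2" = "ACGT")),
    lapply(11:12, function(i) c("D2-S1" = "ACGT")))
  names(aln) <- paste0("sp", 1:12)
  m <- tibble::tibble(
    species = c("sp1", "sp2"), donor_subject = "D1",
    donor_sample = "D1-S1", recipient_subject = "R1",
    recipient_post_sample = "R1-WK", normalised_distance = 0,
    flag_baseline_origin = FALSE, flag_placebo_background = FALSE,
    surviving = TRUE, class = "novel")
  ref <- tibble::tibble(recipient = "R1", donor = c("D1", "D2"))
  eff <- suppressMessages(engraftment_efficiency(m, aln, roster, ref))
  expect_equal(eff$n_donor_strains[eff$donor == "D1"], 10L)
  expect_equal(eff$n_engrafted[eff$donor == "D1"], 2L)
  expect_equal(eff$efficiency[eff$donor == "D1"], 20)
  # donor with no surviving matches in its true recipient -> 0%
  expect_equal(eff$efficiency[eff$donor == "D2"], 0)
})

test_that("proportion test reproduces the two-cohort novel-strain comparison", {
  # printed worked example: 89/124 vs 235/381
  pt <- proportion_test(c(89, 235), c(124, 381))
  expect_equal(round(pt$p_value, 3), 0.054)
  # identical proportions -> p in the unit region
  expect_gt(proportion_test(c(50, 50), c(100, 100))$p_value, 0.99)
  # extreme split -> decisive
  expect_lt(proportion_test(c(0, 10), c(10, 10))$p_value, 0.001)
  expect_error(proportion_test(c(1, 2), c(0, 10)), "zero totals")
})

test_that("donor recall tracks donor efficiency across heterogeneous donors", {
  cfg <- cohort_config(
    n_donors = 6, n_fmt_recipients = 18, n_placebo_recipients = 4,
    pool_size_range = c(3, 3), detection_rate = 1,
    donor_efficiency = seq(0.02, 0.30, length.out = 6), seed = 31)
  co <- generate_cohort(cfg)
  d <- suppressMessages(cohort_distances(co))
  ref <- true_pairings_table(co$truth)
  donors <- sort(unique(co$roster$subject_id[co$roster$role == "donor"]))
  m <- apply_baseline_subtraction(
    call_candidate_matches(d, co$roster, 0.2), d, co$roster, 0.2)
  s <- score_against_reference(predict_pairings(m), ref, donors, theta = 0.2)
  rec <- donor_recall(s)
  eff_cfg <- cfg$donor_efficiency[match(rec$donor, donors)]
  expect_gt(cor(rec$recall, eff_cfg, method = "spearman"), 0.5)
})
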