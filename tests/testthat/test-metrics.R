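test_that("Shannon index: analytic values and the richness bound", {
  expect_equal(shannon_index(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)),
               log(4))
  expect_equal(shannon_index(c(a = 1)), 0)
  expect_equal(round(shannon_index(c(a = 0.5, b = 0.25, c = 0.25)), 4),
               1.0397)
  # zero-abundance species skipped; renormalisation applied
  expect_equal(shannon_index(c(a = 0.2, b = 0.2, c = 0)), log(2))
  # unknown fraction excluded by default, kept on request
  p <- c(a = 0.3, b = 0.3, UNKNOWN = 0.4)
  expect_equal(shannon_index(p), log(2))
  expect_gt(shannon_index(p, include_unknown = TRUE), log(2))
  expect_error(shannon_index(c(a = 0, b = 0)), "all-zero")
  # H <= ln(richness) with equality iff uniform
  set.seed(2)
  for (i in 1:20) {
    q <- stats::setNames(stats::rexp(6), letters[1:6])
    expect_lte(shannon_index(q), log(6))
  }
})

test_that("Bray-Curtis and Jaccard: worked values and boundary identities", {
  expect_equal(bray_curtis(c(a = 0.5, b = 0.5, c = 0),
                           c(a = 0, b = 0.5, c = 0.5)), 0.5)
  expect_equal(bray_curtis(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 0)
  expect_equal(bray_curtis(c(a = 1, b = 0), c(a = 0, b = 1)), 1)
  expect_equal(jaccard_binary(c(A = 1, B = 1, C = 0),
                              c(A = 0, B = 1, C = 1)), 2 / 3)
  expect_equal(jaccard_binary(c(A = 1, B = 1), c(A = 2, B = 5)), 0)
  expect_equal(jaccard_binary(c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  expect_error(bray_curtis(c(a = 0), c(a = 0)), "all-zero")
  # Bray-Curtis equals binary Jaccard when all abundances are 0 or c...
  set.seed(4)
  for (i in 1:10) {
    a <- stats::setNames(sample(c(0, 0.2), 8, replace = TRUE), letters[1:8])
    b <- stats::setNames(sample(c(0, 0.2), 8, replace = TRUE), letters[1:8])
    if (all(a == 0) || all(b == 0)) next
    # ... no: BC on equal-height profiles is Sorensen; assert the known
    # relation J = 2BC/(1+BC) instead
    bc <- bray_curtis(a, b)
    expect_equal(jaccard_binary(a, b), 2 * bc / (1 + bc), tolerance = 1e-12)
  }
})

test_that("P/B ratio handles dominance, zeros and genus prefixes", {
  p <- c(Prevotella_sp01 = 0.2, Bacteroides_sp01 = 0.1,
         Clostridium_sp01 = 0.3)
  expect_equal(pb_ratio(p), 2)
  expect_equal(pb_ratio(c(Prevotella_sp01 = 0, Bacteroides_sp01 = 0.1)), 0)
  expect_identical(pb_ratio(c(Prevotella_sp01 = 0.2,
                              Bacteroides_sp01 = 0)), Inf)
  expect_true(is.nan(suppressMessages(
    pb_ratio(c(Clostridium_sp01 = 1)))))
  # explicit taxa lists override the prefix heuristic
  expect_equal(pb_ratio(c(x = 0.4, y = 0.2), prevotella_taxa = "x",
                        bacteroides_taxa = "y"), 2)
})

test_that("COG renormalisation: worked example and sum-to-one invariant", {
  # 10 genes: 8 annotated once, 1 with two categories, 1 unannotated
  ann <- tibble::tibble(
    sample_id = "s1",
    gene_id = c(paste0("g", 1:8), "g9", "g9", "g10"),
    category = c(rep(c("J", "K"), 4), "L", "M", NA))
  out <- cog_renormalise(ann)
  expect_equal(sum(out$abundance), 1)
  # raw weights are elevenths after renormalising by 11/10
  expect_equal(out$abundance[out$category == "NA"], 1 / 11)
  expect_equal(out$abundance[out$category == "J"], 4 / 11)
  expect_equal(out$abundance[out$category == "L"], 1 / 11)
  # single-category genes: renormalisation is the identity
  ann1 <- tibble::tibble(sample_id = "s", gene_id = paste0("g", 1:4),
                         category = c("J", "J", "K", "L"))
  out1 <- cog_renormalise(ann1)
  expect_equal(out1$abundance[out1$category == "J"], 0.5)
  # all genes unannotated
  out2 <- cog_renormalise(tibble::tibble(sample_id = "s", gene_id = "g1",
                                         category = NA_character_))
  expect_equal(out2$category, "NA")
  expect_equal(out2$abundance, 1)
  # multi-annotation load never breaks the sum-to-one invariant
  set.seed(6)
  ann3 <- tibble::tibble(
    sample_id = rep(c("sA", "sB"), each = 30),
    gene_id = paste0("g", c(sample(1:12, 30, TRUE), sample(1:9, 30, TRUE))),
    category = sample(c(cog_categories(), NA), 60, TRUE))
  ann3 <- dplyr::distinct(ann3)
  sums <- cog_renormalise(ann3) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(abundance))
  expect_equal(sums$s, rep(1, 2), tolerance = 1e-9)
})

test_that("PCoA recovers collinear configurations and block structure", {
  # 3 collinear points: 1-D configuration reproduces the distances
  x <- c(0, 1, 3)
  d <- dist(x)
  expect_warning(fit <- pcoa(d, k = 2), "positive eigenvalues")
  expect_equal(as.numeric(dist(fit$coordinates[, 1])), as.numeric(d),
               tolerance = 1e-9)
  expect_lt(sum(abs(fit$eigenvalues[-1])), 1e-8)
  # identical samples are coincident
  d0 <- dist(c(0, 0, 5))
  f0 <- pcoa(d0, k = 1)
  expect_equal(f0$coordinates[1, 1], f0$coordinates[2, 1])
  # two tight clusters separate on PC1
  m <- matrix(0, 4, 4)
  m[1:2, 3:4] <- 1; m[3:4, 1:2] <- 1
  f2 <- suppressWarnings(pcoa(as.dist(m), k = 1))
  expect_equal(sign(f2$coordinates[1, 1]), sign(f2$coordinates[2, 1]))
  expect_false(sign(f2$coordinates[1, 1]) == sign(f2$coordinates[3, 1]))
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R-squared", {
  set.seed(11)
  m <- matrix(stats::rexp(20 * 8), nrow = 20)
  m <- m / rowSums(m)
  grp <- rep(c("a", "b"), each = 10)
  m[grp == "b", 1] <- m[grp == "b", 1] + 0.3
  m <- m / rowSums(m)
  d <- vegan::vegdist(m, "bray")
  got <- permanova(d, grp, n_permutations = 199, seed = 5)
  ref <- vegan::adonis2(d ~ grp, permutations = 199)
  expect_equal(got$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(got$r_squared, ref$R2[1], tolerance = 1e-10)
  # continuous predictor
  cov <- stats::rnorm(20)
  gotc <- permanova(d, cov, n_permutations = 99, seed = 6)
  refc <- vegan::adonis2(d ~ cov, permutations = 99)
  expect_equal(gotc$pseudo_F, refc$F[1], tolerance = 1e-10)
  expect_equal(gotc$r_squared, refc$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA p matches exhaustive label enumeration at n = 5", {
  set.seed(12)
  m <- matrix(stats::runif(5 * 4), nrow = 5)
  d <- dist(m)
  grp <- c("a", "a", "b", "b", "b")
  got <- permanova(d, grp, n_permutations = 999, seed = 2)
  # brute force over all 5! orderings of the labels
  dm <- as.matrix(d)
  a <- -0.5 * dm ^ 2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  f_of <- function(lab) {
    X <- stats::model.matrix(~lab)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    ssm <- sum(diag(H %*% G))
    (ssm / 1) / ((sum(diag(G)) - ssm) / 3)
  }
  all_perm <- all_permutations(5)
  perms <- apply(all_perm, 1, function(ix) f_of(factor(grp[ix])))
  F_obs <- f_of(factor(grp))
  exact_p <- mean(perms >= F_obs - 1e-12)
  expect_equal(got$pseudo_F, F_obs, tolerance = 1e-10)
  expect_lt(abs(got$p_value - exact_p), 0.06)
})

test_that("PERMANOVA resolution bound and degenerate predictors", {
  # strongly separated duplicated clusters reach the minimum p
  m <- rbind(matrix(stats::rnorm(40, 0), 10),
             matrix(stats::rnorm(40, 8), 10))
  d <- dist(m)
  res <- permanova(d, rep(c("x", "y"), each = 10), n_permutations = 999,
                   seed = 3)
  expect_equal(res$p_value, 0.001)
  expect_error(permanova(d, rep("x", 20), 99), "degenerate")
  expect_error(permanova(d, rep(1, 20), 99), "degenerate")
  # seed reproducibility
  r1 <- permanova(d, rep(c("x", "y"), each = 10), 99, seed = 7)
  r2 <- permanova(d, rep(c("x", "y"), each = 10), 99, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})
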