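# Accept either a bare named numeric vector of relative abundances or a row
# of the wide abundance table (sample_id + species columns + UNKNOWN).
as_profile <- function(x, drop_unknown = TRUE) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  }
  stopifnot(is.numeric(x))
  if (drop_unknown) x <- x[setdiff(names(x), "UNKNOWN")]
  if (any(x < 0)) stop("negative abundances")
  x
}

#' Shannon diversity index (nats)
#'
#' `H = -sum(q_i * log(q_i))` over species abundances renormalised to sum
#' one; zero-abundance species are skipped. By default the unknown
#' (unclassified) fraction is excluded before renormalising, so H describes
#' the observed community.
#'
#' @param profile Named numeric abundance vector, or one row of the wide
#'   abundance table.
#' @param include_unknown Keep the `UNKNOWN` column as a pseudo-taxon.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(profile, include_unknown = FALSE) {
  q <- as_profile(profile, drop_unknown = !include_unknown)
  q <- q[q > 0]
  if (length(q) == 0) stop("all-zero abundance profile")
  unname(vegan::diversity(q / sum(q), index = "shannon"))
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `1 - 2 * sum(min(a_i, b_i)) / sum(a_i + b_i)` over the union of species
#' (absent species count as zero).
#'
#' @param a,b Named numeric abundance vectors (or wide-table rows).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  m <- profile_pair_matrix(a, b)
  if (all(m == 0)) stop("both profiles all-zero")
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Binary Jaccard dissimilarity between two abundance profiles
#'
#' Abundances are converted to presence/absence (abundance > 0) and the
#' Jaccard dissimilarity `1 - |A intersect B| / |A union B|` is returned.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_binary <- function(a, b) {
  m <- profile_pair_matrix(a, b)
  if (all(m == 0)) stop("both profiles empty")
  as.numeric(vegan::vegdist(m, method = "jaccard", binary = TRUE))
}

profile_pair_matrix <- function(a, b) {
  a <- as_profile(a); b <- as_profile(b)
  if (is.null(names(a)) || is.null(names(b))) {
    stopifnot(length(a) == length(b))
    return(rbind(a, b))
  }
  sp <- union(names(a), names(b))
  av <- a[sp]; av[is.na(av)] <- 0
  bv <- b[sp]; bv[is.na(bv)] <- 0
  rbind(av, bv)
}

#' Pairwise dissimilarity matrix for a wide abundance table
#'
#' @param abundances Wide abundance table (`sample_id` + species columns;
#'   `UNKNOWN` dropped).
#' @param method `"bray"` or `"jaccard"` (binary).
#' @return A `dist` object over samples.
#' @export
dissimilarity_matrix <- function(abundances, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  m <- as.matrix(abundances[, setdiff(names(abundances),
                                      c("sample_id", "UNKNOWN"))])
  rownames(m) <- abundances$sample_id
  vegan::vegdist(m, method = method, binary = method == "jaccard")
}

#' Prevotella/Bacteroides ratio of an abundance profile
#'
#' Ratio of summed genus-level relative abundances. By default genus
#' membership is read from the species-name prefix before the first `_` or
#' `.`; explicit taxa vectors override.
#'
#' @param profile Named numeric abundance vector (or wide-table row).
#' @param prevotella_taxa,bacteroides_taxa Optional species-name vectors.
#' @return Ratio; `Inf` when the Bacteroides sum is 0 with a positive
#'   Prevotella sum; `NaN` (logged) for 0/0.
#' @export
pb_ratio <- function(profile, prevotella_taxa = NULL,
                     bacteroides_taxa = NULL) {
  q <- as_profile(profile)
  genus <- sub("[._].*$", "", names(q))
  prev <- prevotella_taxa %||% names(q)[genus == "Prevotella"]
  bact <- bacteroides_taxa %||% names(q)[genus == "Bacteroides"]
  num <- sum(q[intersect(prev, names(q))])
  den <- sum(q[intersect(bact, names(q))])
  if (den == 0 && num == 0) {
    eg_log("pb_ratio", "0/0: ratio undefined", "WARN")
    return(NaN)
  }
  if (den == 0) return(Inf)
  num / den
}

#' Renormalised COG functional-category profiles
#'
#' Each (gene, category) annotation contributes one count (genes with
#' multiple categories are counted separately); genes without an annotation
#' contribute to `NA`. Counts are taken as a proportion of the number of
#' genes per sample and then renormalised so each sample's profile sums to
#' one. Samples with zero genes are omitted (logged).
#'
#' @param annotations Long table: `sample_id`, `gene_id`, `category`
#'   (`NA` = unannotated).
#' @return Tibble: `sample_id`, `category` (`"NA"` for unannotated),
#'   `abundance`; per-sample abundances sum to 1.
#' @export
cog_renormalise <- function(annotations) {
  stopifnot(all(c("sample_id", "gene_id", "category") %in% names(annotations)))
  ann <- annotations
  ann$category <- ifelse(is.na(ann$category), "NA", ann$category)
  out <- ann |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      n_genes <- dplyr::n_distinct(d$gene_id)
      if (n_genes == 0) return(tibble::tibble(category = character(),
                                              abundance = double()))
      w <- table(d$category) / n_genes      # proportion of genes
      w <- w / sum(w)                       # renormalise to sum 1
      tibble::tibble(category = names(w), abundance = as.numeric(w))
    }) |>
    dplyr::ungroup()
  empty <- setdiff(unique(annotations$sample_id), unique(out$sample_id))
  if (length(empty) > 0) {
    eg_log("cog", paste0("samples with zero genes omitted: ",
                         paste(empty, collapse = ", ")), "WARN")
  }
  out
}

# wide matrix (samples x categories) of a cog_renormalise() result
functional_matrix <- function(profiles) {
  w <- tidyr::pivot_wider(profiles, names_from = "category",
                          values_from = "abundance", values_fill = 0)
  m <- as.matrix(w[, setdiff(names(w), "sample_id")])
  rownames(m) <- w$sample_id
  m
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centred Gower decomposition of a dissimilarity matrix via
#' [stats::cmdscale()]. Negative eigenvalues are reported, not corrected.
#'
#' @param d A `dist` or square symmetric matrix of dissimilarities.
#' @param k Number of coordinate dimensions (truncated with a warning when
#'   it exceeds the number of positive eigenvalues).
#' @return List with `coordinates` (samples x k) and `eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  stopifnot(k >= 1)
  n <- if (inherits(d, "dist")) attr(d, "Size") else nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  if (k > n_pos) {
    warning("k = ", k, " exceeds the number of positive eigenvalues (",
            n_pos, "); coordinates truncated")
  }
  coords <- fit$points[, seq_len(min(k, max(1, n_pos))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = fit$eig)
}

#' One-term PERMANOVA (categorical or continuous predictor)
#'
#' Distance-based linear model on the Gower-centred inner-product matrix:
#' the pseudo-F compares the sum of squares captured by the predictor's hat
#' matrix against the residual, and significance is assessed by permuting
#' the observation labels (raw permutation, no residualisation).
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param predictor Factor/character group labels, or a numeric covariate,
#'   aligned with the rows of `d`.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`, `df_model`, `df_residual`.
#' @export
permanova <- function(d, predictor, n_permutations = 999, seed = NULL) {
  stopifnot(n_permutations >= 1)
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(length(predictor) == n)
  if (is.character(predictor)) predictor <- factor(predictor)
  if (is.factor(predictor) && nlevels(droplevels(predictor)) < 2) {
    stop("degenerate predictor: fewer than 2 groups")
  }
  if (is.numeric(predictor) && stats::var(predictor) == 0) {
    stop("degenerate predictor: constant covariate")
  }
  a <- -0.5 * dm ^ 2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  X <- stats::model.matrix(~predictor)
  qr_x <- qr(X)
  df_model <- qr_x$rank - 1L
  df_res <- n - qr_x$rank
  ss_total <- sum(diag(G))
  # tr(H G[idx, idx]); G is double-centred so the intercept projection
  # contributes tr((11'/n) G) = 0 under every permutation.
  f_stat <- function(idx) {
    sum(diag(qr.fitted(qr_x, G[idx, idx])))
  }
  ss_model <- f_stat(seq_len(n))
  ss_res <- ss_total - ss_model
  F_obs <- (ss_model / df_model) / (ss_res / df_res)
  run_perms <- function() {
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      idx <- sample.int(n)
      ssm <- f_stat(idx)
      Fp <- (ssm / df_model) / ((ss_total - ssm) / df_res)
      if (Fp >= F_obs) exceed <- exceed + 1L
    }
    exceed
  }
  exceed <- if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  structure(list(pseudo_F = F_obs,
                 r_squared = ss_model / ss_total,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 df_model = df_model, df_residual = df_res),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_model, x$df_residual, x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}
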