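#' PCA of session synchrony vectors
#'
#' Centered principal component analysis on the matrix of 32-dimensional
#' synchrony vectors (rows = sessions).  Columns are not standardized: every
#' entry already lives on the common `[0, 1]` PLV scale.  Component signs are
#' fixed deterministically by making the largest-magnitude loading of each
#' component positive.
#'
#' @param x numeric matrix or data.frame of synchrony vectors (a `group`
#'   column, if present, is set aside as labels).
#' @return object of class `sync_embedding`: list with `loadings`
#'   (p x p rotation), `scores` (n x p), `var_fractions` (non-increasing, sums
#'   to 1), `center`, `labels`.
#' @export
fit_pca <- function(x) {
  labels <- NULL
  if (is.data.frame(x)) {
    if ("group" %in% names(x)) {
      labels <- x$group
      x <- x[, setdiff(names(x), "group"), drop = FALSE]
    }
    x <- as.matrix(x)
  }
  if (nrow(x) < 2) stop_data("PCA needs at least 2 rows")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sco <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = rot, scores = sco,
                 var_fractions = ev / sum(ev),
                 center = pc$center, labels = labels),
            class = "sync_embedding")
}

#' @export
print.sync_embedding <- function(x, ...) {
  k <- min(6, length(x$var_fractions))
  cat(sprintf("<sync_embedding> %d sessions x %d measures; first %d components explain %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores), k, 100 * sum(x$var_fractions[seq_len(k)])))
  invisible(x)
}

#' Project onto the leading principal components
#'
#' @param embedding a `sync_embedding` from [fit_pca()].
#' @param k number of components to keep (default 6, the number needed to
#'   explain over 90% of variance in typical synchrony data).
#' @return n x k score matrix.
#' @export
project_scores <- function(embedding, k = 6) {
  stopifnot(inherits(embedding, "sync_embedding"))
  if (k > ncol(embedding$scores)) stop_data("k = %d exceeds the %d available components",
                                            k, ncol(embedding$scores))
  embedding$scores[, seq_len(k), drop = FALSE]
}

#' Within- and between-group distance report
#'
#' Computes the mean pairwise Euclidean distance among the projected points of
#' each group (all unordered pairs), the mean cross distance of each group's
#' points against a reference group, and compares each group's cross-distance
#' set against (a) the reference group's within-distance set and (b) the
#' group's own within-distance set by two-sample Student's t-tests, with
#' Bonferroni adjustment over all emitted comparisons.  Pair distances are
#' treated as independent observations in the t-tests; pair counts are
#' reported so the dependence caveat can be judged.
#'
#' Because the pairwise distances within and across groups share underlying
#' points, they are strongly dependent and the naive t-test is anticonservative
#' (its effective sample size is the number of sessions, not the number of
#' pairs).  The significance flags are therefore based on group-label
#' permutation p-values, which are exact under exchangeability; the t
#' statistics and their naive p-values are reported alongside for reference.
#'
#' @param points numeric matrix of projected coordinates (rows = sessions).
#' @param labels group label per row.
#' @param reference_group the group against which cross distances are taken.
#' @param alpha familywise significance level before adjustment.
#' @param n_perm label permutations per contrast.
#' @param seed RNG seed for the permutations.
#' @return object of class `distance_report`: data.frame with one row per
#'   non-reference group (`group`, `reference`, `n_within`, `n_cross`,
#'   `within_mean`, `ref_within_mean`, `cross_mean`, `t_vs_ref`, `p_vs_ref`,
#'   `t_vs_own`, `p_vs_own`, permutation p-values, Bonferroni-adjusted
#'   p-values and significance flags), with the per-group within-distance
#'   means as attribute `within`.
#' @export
group_distances <- function(points, labels, reference_group, alpha = 0.05,
                            n_perm = 499, seed = 1L) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  groups <- unique(labels)
  if (!reference_group %in% groups) stop_config("reference group '%s' not present", reference_group)
  sizes <- table(labels)
  if (any(sizes < 2)) stop_data("singleton group(s): %s",
                                paste(names(sizes)[sizes < 2], collapse = ", "))

  dmat <- as.matrix(dist(points))
  within_sets <- lapply(groups, function(g) {
    idx <- which(labels == g)
    dmat[idx, idx][upper.tri(diag(length(idx)))]
  })
  names(within_sets) <- groups
  ref_idx <- which(labels == reference_group)
  ref_within <- within_sets[[reference_group]]

  # observed statistics for a pair of index sets: mean cross distance minus
  # mean within-distance of (a) the reference set and (b) the tested set
  contrast_stats <- function(idx_g, idx_r) {
    cross <- mean(dmat[idx_g, idx_r])
    c(ref = cross - mean(dmat[idx_r, idx_r][upper.tri(diag(length(idx_r)))]),
      own = cross - mean(dmat[idx_g, idx_g][upper.tri(diag(length(idx_g)))]))
  }

  others <- setdiff(groups, reference_group)
  rows <- lapply(others, function(g) {
    idx <- which(labels == g)
    cross <- as.vector(dmat[idx, ref_idx])
    safe_t <- function(a, b) {
      tryCatch(t.test(a, b, var.equal = TRUE),
               error = function(e) list(statistic = c(t = NA_real_), p.value = 1))
    }
    tt_ref <- safe_t(cross, ref_within)
    tt_own <- safe_t(cross, within_sets[[g]])
    obs <- contrast_stats(idx, ref_idx)
    pool <- c(idx, ref_idx)
    perm <- with_seed(derive_seed(seed, match(g, groups)), {
      vapply(seq_len(n_perm), function(b) {
        sh <- sample(pool)
        contrast_stats(sh[seq_along(idx)], sh[-seq_along(idx)])
      }, numeric(2))
    })
    p_perm_ref <- (1 + sum(abs(perm["ref", ]) >= abs(obs["ref"]))) / (1 + n_perm)
    p_perm_own <- (1 + sum(abs(perm["own", ]) >= abs(obs["own"]))) / (1 + n_perm)
    data.frame(group = g, reference = reference_group,
               n_within = length(within_sets[[g]]), n_cross = length(cross),
               within_mean = mean(within_sets[[g]]),
               ref_within_mean = mean(ref_within),
               cross_mean = mean(cross),
               t_vs_ref = unname(tt_ref$statistic), p_vs_ref = tt_ref$p.value,
               t_vs_own = unname(tt_own$statistic), p_vs_own = tt_own$p.value,
               p_perm_ref = p_perm_ref, p_perm_own = p_perm_own,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  n_comp <- 2 * nrow(rep_df)            # both contrasts enter the correction
  rep_df$p_vs_ref_adj <- pmin(1, rep_df$p_vs_ref * n_comp)
  rep_df$p_vs_own_adj <- pmin(1, rep_df$p_vs_own * n_comp)
  rep_df$p_perm_ref_adj <- pmin(1, rep_df$p_perm_ref * n_comp)
  rep_df$p_perm_own_adj <- pmin(1, rep_df$p_perm_own * n_comp)
  rep_df$sig_vs_ref <- rep_df$p_perm_ref_adj < alpha
  rep_df$sig_vs_own <- rep_df$p_perm_own_adj < alpha
  attr(rep_df, "within") <- vapply(within_sets, mean, numeric(1))
  attr(rep_df, "alpha") <- alpha
  class(rep_df) <- c("distance_report", "data.frame")
  rep_df
}

#' Export a distance report / embedding tables as CSV
#' @param report a `distance_report`.
#' @param path output file.
#' @export
write_distance_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @param embedding a `sync_embedding`.
#' @param prefix file prefix; writes `<prefix>_loadings.csv`,
#'   `<prefix>_scores.csv`, `<prefix>_variance.csv`.
#' @export
write_embedding_csv <- function(embedding, prefix) {
  write.csv(embedding$loadings, paste0(prefix, "_loadings.csv"))
  sc <- as.data.frame(embedding$scores)
  if (!is.null(embedding$labels)) sc <- cbind(group = embedding$labels, sc)
  write.csv(sc, paste0(prefix, "_scores.csv"), row.names = FALSE)
  write.csv(data.frame(component = seq_along(embedding$var_fractions),
                       var_fraction = embedding$var_fractions),
            paste0(prefix, "_variance.csv"), row.names = FALSE)
  invisible(prefix)
}
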