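#' Default pipeline configuration
#'
#' A fully serializable run configuration: band set, montage, detector and
#' feature parameters, PCA dimensionality, seeds, and the channel analysed
#' for spike-wave activity (an epidural screw by default, where these
#' waveforms are most prominent).
#'
#' @param seed master seed for any stochastic step.
#' @param pca_k components kept for pattern distances.
#' @param swd_channel channel analysed by the spike-wave detector.
#' @param rail saturation rail in microvolts, or `NULL` to skip screening.
#' @param detector a [detector_params()].
#' @param features a [feature_params()].
#' @export
default_run_config <- function(seed = 1L, pca_k = 6, swd_channel = "LFS",
                               rail = NULL, detector = detector_params(),
                               features = feature_params()) {
  cfg <- list(seed = as.integer(seed), pca_k = pca_k, swd_channel = swd_channel,
              rail = rail, detector = unclass(detector),
              features = unclass(features),
              bands = canonical_bands(),
              montage_pairs = canonical_montage()$pairs)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in intersect(names(raw), c("seed", "pca_k", "swd_channel", "rail"))) {
    cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$detector)) cfg$detector <- utils::modifyList(cfg$detector, raw$detector)
  if (!is.null(raw$features)) cfg$features <- utils::modifyList(cfg$features, raw$features)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg[setdiff(names(cfg), c("bands", "montage_pairs"))], path)
  invisible(path)
}

#' Analyse one session end to end
#'
#' Computes, for a complete 8-channel recording: per-channel normalized power
#' spectra (with 58-62 Hz line interpolation), the 32-entry synchrony vector,
#' spike-wave detection on the configured channel with prevalence, and
#' morphology features over the supplied (manually marked or ground-truth)
#' intervals.  Deterministic given the recording and configuration; the
#' configuration hash is attached to the report.
#'
#' @param rec a [recording()] with all montage channels.
#' @param cfg a [default_run_config()].
#' @param feature_intervals optional interval matrix / data.frame
#'   (`start_s`, `end_s`) on which features are extracted.  The detector's
#'   own output is deliberately not auto-fed to the feature extractor.
#' @return list of class `session_report`: `psd` (named list), `sync`
#'   (a `sync_vector`), `events`, `prevalence`, `features`, `config_hash`.
#' @export
run_session <- function(rec, cfg = default_run_config(), feature_intervals = NULL) {
  stopifnot(inherits(rec, "recording"))
  det <- do.call(detector_params, cfg$detector)
  fp <- do.call(feature_params, cfg$features)
  montage <- canonical_montage()
  missing_ch <- setdiff(montage$channels, names(rec$signals))
  if (length(missing_ch) > 0) {
    stop_data("incomplete-montage: missing channel(s) %s", paste(missing_ch, collapse = ", "))
  }
  psds <- lapply(rec$signals, function(s) {
    p <- compute_psd(rms_normalize(s))
    normalize_psd(interpolate_line_region(p))
  })
  sync <- session_sync_vector(rec, montage, rail = cfg$rail)
  events <- detect_swd(rec$signals[[cfg$swd_channel]], det, rail = cfg$rail)
  prev <- prevalence(events, attr(events, "analyzed"))
  feats <- NULL
  if (!is.null(feature_intervals) && nrow(feature_intervals) > 0) {
    feats <- features_for_intervals(rec$signals[[cfg$swd_channel]], feature_intervals, fp)
  }
  structure(list(psd = psds, sync = sync, events = events, prevalence = prev,
                 features = feats, config_hash = cfg$hash, meta = rec$meta),
            class = "session_report")
}

#' Group-level study analysis
#'
#' Aggregates per-session synchrony vectors into the multidimensional pattern
#' analysis (PCA, 6-D group distances with Bonferroni-adjusted t-tests),
#' optionally compares feature distributions between two groups with the
#' balanced-subsample Kolmogorov-Smirnov procedure, and optionally correlates
#' per-animal synchrony with entrance counts.
#'
#' @param sync_df data.frame with a `group` column and one column per
#'   synchrony-vector entry (e.g. from [gen_sync_vectors()] or stacked
#'   [sync_vector_values()] rows).
#' @param reference_group reference group for the distance report (default
#'   the first group).
#' @param pca_k projection dimensionality.
#' @param features_by_group optional named list (two groups) of per-animal
#'   feature-value lists, passed to [build_distribution()] / [ks_compare()].
#' @param subsample_n per-animal subsample size for the feature comparison.
#' @param behavior_df optional data.frame with `plv`, `entrances` per animal.
#' @param seed RNG seed for the balanced subsampling.
#' @return list of class `study_report`: `embedding`, `distances`,
#'   `ks` (or NULL), `behavior` (or NULL).
#' @export
run_study <- function(sync_df, reference_group = NULL, pca_k = 6,
                      features_by_group = NULL, subsample_n = NULL,
                      behavior_df = NULL, seed = 1L) {
  if (!"group" %in% names(sync_df)) stop_config("sync_df needs a 'group' column")
  groups <- unique(sync_df$group)
  if (length(groups) < 2) stop_data("need at least 2 groups")
  sizes <- table(sync_df$group)
  if (any(sizes < 2)) stop_data("group(s) with < 2 sessions: %s",
                                paste(names(sizes)[sizes < 2], collapse = ", "))
  if (is.null(reference_group)) reference_group <- groups[1]
  emb <- fit_pca(sync_df)
  pts <- project_scores(emb, k = min(pca_k, ncol(emb$scores)))
  dists <- group_distances(pts, emb$labels, reference_group)
  ks <- NULL
  if (!is.null(features_by_group)) {
    if (length(features_by_group) != 2) stop_config("features_by_group must name exactly 2 groups")
    if (is.null(subsample_n)) {
      subsample_n <- min(unlist(lapply(features_by_group, function(g) vapply(g, length, integer(1)))))
    }
    dists_ab <- lapply(seq_along(features_by_group), function(i) {
      build_distribution(features_by_group[[i]], subsample_n, seed = derive_seed(seed, i))
    })
    ks <- ks_compare(dists_ab[[1]]$pooled, dists_ab[[2]]$pooled)
    ks$distributions <- dists_ab
    ks$groups <- names(features_by_group)
  }
  beh <- NULL
  if (!is.null(behavior_df)) {
    beh <- correlate_sync_behavior(behavior_df$plv, behavior_df$entrances)
  }
  structure(list(embedding = emb, distances = dists, ks = ks, behavior = beh),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  print(x$embedding)
  cat("distance report:\n")
  print(as.data.frame(x$distances)[, c("group", "reference", "within_mean",
                                       "cross_mean", "p_vs_ref_adj", "sig_vs_ref")])
  if (!is.null(x$ks)) cat(sprintf("feature KS: D = %.3f, p = %.3g\n", x$ks$D, x$ks$p))
  if (!is.null(x$behavior)) cat(sprintf("sync-behavior correlation: r = %.2f, p = %.3g\n",
                                        x$behavior$r, x$behavior$p))
  invisible(x)
}
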