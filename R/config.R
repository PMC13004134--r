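#' Configuration constructors
#'
#' Validated configuration objects for the simulators and pipeline stages.
#' Each constructor checks its invariants and fails with a message naming the
#' violated constraint.
#'
#' @name configs
NULL

#' Bulk corpus simulation configuration
#'
#' @param n_cell_types number of primary cell types in the corpus.
#' @param triggers_min,triggers_max range of senescence triggers per cell type
#'   (drawn uniformly per type from CTIS/IRIS/OSIS/OIS).
#' @param replicates_per_arm samples per arm (senescent and control) of each
#'   senescence model.
#' @param n_features_rna,n_features_protein features per modality.
#' @param n_shared_up,n_shared_down planted pan-senescence features.
#' @param n_type_specific planted features per cell type (half up, half down).
#' @param effect_log2 planted effect size, log2 units.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion*mu^2).
#' @param protein_missing_frac overall fraction of missing protein values.
#' @param target_sum per-sample normalized total for RNA; defaults to
#'   `10000 * n_features_rna` so the conventional abundance floor of 1000
#'   normalized counts sits well below the mean feature abundance.
#' @param seed integer seed.
#' @return A validated list of class `BulkSimConfig`.
#' @export
bulkSimConfig <- function(n_cell_types = 14L, triggers_min = 2L, triggers_max = 4L,
                          replicates_per_arm = 3L,
                          n_features_rna = 5000L, n_features_protein = 3000L,
                          n_shared_up = 30L, n_shared_down = 30L,
                          n_type_specific = 50L, effect_log2 = 1.5,
                          dispersion = 0.3, protein_missing_frac = 0.1,
                          target_sum = NULL, seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              triggers_min = as.integer(triggers_min),
              triggers_max = as.integer(triggers_max),
              replicates_per_arm = as.integer(replicates_per_arm),
              n_features_rna = as.integer(n_features_rna),
              n_features_protein = as.integer(n_features_protein),
              n_shared_up = as.integer(n_shared_up),
              n_shared_down = as.integer(n_shared_down),
              n_type_specific = as.integer(n_type_specific),
              effect_log2 = effect_log2, dispersion = dispersion,
              protein_missing_frac = protein_missing_frac,
              target_sum = target_sum %||% 1e4 * as.integer(n_features_rna),
              seed = as.integer(seed))
  counts <- cfg[c("n_cell_types", "triggers_min", "triggers_max",
                  "replicates_per_arm", "n_features_rna", "n_features_protein",
                  "n_shared_up", "n_shared_down", "n_type_specific")]
  if (any(unlist(counts) <= 0))
    stopf("BulkSimConfig: all counts must be > 0 (violated: %s)",
          paste(names(counts)[unlist(counts) <= 0], collapse = ", "))
  if (cfg$triggers_min > cfg$triggers_max || cfg$triggers_max > 4L)
    stopf("BulkSimConfig: need triggers_min <= triggers_max <= 4")
  planted <- cfg$n_shared_up + cfg$n_shared_down +
    cfg$n_cell_types * cfg$n_type_specific
  if (planted > min(cfg$n_features_rna, cfg$n_features_protein))
    stopf("BulkSimConfig: planted features (%d) exceed n_features (violated: n_shared_up + n_shared_down + n_cell_types * n_type_specific <= n_features)",
          planted)
  if (cfg$protein_missing_frac < 0 || cfg$protein_missing_frac >= 1)
    stopf("BulkSimConfig: protein_missing_frac must be in [0, 1) (violated: 0 <= protein_missing_frac < 1)")
  if (cfg$dispersion <= 0) stopf("BulkSimConfig: dispersion must be > 0")
  structure(cfg, class = "BulkSimConfig")
}

#' Single-cell simulation configuration
#'
#' @param n_clusters number of cell clusters.
#' @param n_genes total genes, including a tagged mitochondrial 5%.
#' @param timepoints ordered condition labels; the first is the reference.
#' @param cells_per_timepoint cells simulated per timepoint.
#' @param senescent_frac_by_timepoint monotone nondecreasing true-senescent
#'   fractions, one per timepoint; the reference fraction must be <= 0.005.
#' @param signature_size number of planted up-regulated signature genes.
#' @param effect_log2 planted up-weighting of signature genes in true-senescent
#'   cells, log2 units.
#' @param depth_meanlog,depth_sdlog per-timepoint log-normal parameters of
#'   per-cell total counts (recycled); the default mean increases with
#'   timepoint, planting a depth-timepoint confound.
#' @param seed integer seed.
#' @return A validated list of class `SCSimConfig`.
#' @export
scSimConfig <- function(n_clusters = 6L, n_genes = 2000L,
                        timepoints = c("Day0", "Day1", "Day2", "Day4", "Day6"),
                        cells_per_timepoint = 1000L,
                        senescent_frac_by_timepoint = c(0.002, 0.03, 0.06, 0.10, 0.15),
                        signature_size = 100L, effect_log2 = 1.5,
                        depth_meanlog = NULL, depth_sdlog = 0.35,
                        seed = 1L) {
  nt <- length(timepoints)
  if (is.null(depth_meanlog))
    depth_meanlog <- log(3000) + 0.08 * (seq_len(nt) - 1L)
  cfg <- list(n_clusters = as.integer(n_clusters), n_genes = as.integer(n_genes),
              timepoints = as.character(timepoints),
              cells_per_timepoint = as.integer(cells_per_timepoint),
              senescent_frac_by_timepoint = senescent_frac_by_timepoint,
              signature_size = as.integer(signature_size),
              effect_log2 = effect_log2,
              depth_meanlog = rep_len(depth_meanlog, nt),
              depth_sdlog = rep_len(depth_sdlog, nt),
              seed = as.integer(seed))
  if (any(c(cfg$n_clusters, cfg$n_genes, cfg$cells_per_timepoint,
            cfg$signature_size) <= 0))
    stopf("SCSimConfig: all counts must be > 0")
  f <- cfg$senescent_frac_by_timepoint
  if (length(f) != nt)
    stopf("SCSimConfig: need one senescent fraction per timepoint (%d != %d)",
          length(f), nt)
  if (any(f < 0 | f > 1))
    stopf("SCSimConfig: fractions must lie in [0, 1]")
  if (is.unsorted(f))
    stopf("SCSimConfig: senescent fractions must be monotone nondecreasing")
  if (f[1] > 0.005)
    stopf("SCSimConfig: reference timepoint fraction must be <= 0.005 (got %g)", f[1])
  if (anyDuplicated(cfg$timepoints))
    stopf("SCSimConfig: timepoints must be distinct ordered labels")
  if (cfg$signature_size >= cfg$n_genes)
    stopf("SCSimConfig: signature_size must be < n_genes")
  structure(cfg, class = "SCSimConfig")
}

#' Rule-based marker-calling thresholds
#'
#' Defaults follow the conventional catalog rules: at least 1.5-fold change
#' (log2 0.585), p < 0.05, and for RNA an abundance floor of 1000 normalized
#' counts in the arm where the transcript is abundant.
#'
#' @param min_abs_log2fc minimum |log2 fold change|.
#' @param max_p significance cutoff on the (raw) p-value.
#' @param expression_floor RNA abundance floor (normalized counts).
#' @param floor_mode `"abundant-arm"` applies the floor to the senescent arm
#'   for up markers and the control arm for down markers; `"literal"` requires
#'   instead that down markers be *below* the floor in the control arm.
#' @export
markerThresholds <- function(min_abs_log2fc = 0.585, max_p = 0.05,
                             expression_floor = 1000,
                             floor_mode = c("abundant-arm", "literal")) {
  floor_mode <- match.arg(floor_mode)
  if (min_abs_log2fc <= 0) stopf("MarkerThresholds: min_abs_log2fc must be > 0")
  if (max_p <= 0 || max_p > 1) stopf("MarkerThresholds: need 0 < max_p <= 1")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_p = max_p,
                 expression_floor = expression_floor, floor_mode = floor_mode),
            class = "MarkerThresholds")
}

#' Consensus machine-learning configuration
#'
#' @param expression_percentile q in `[0, 1)`: features whose mean expression
#'   is at or below the q-quantile of all feature means are dropped
#'   (`percentile_mode = "per-feature-mean"`), or whose values are compared
#'   against the q-quantile of all values (`"per-value"`).
#' @param univariate_k features kept by the univariate one-way F screen.
#' @param l1_strength dimensionless multiplier of the universal-threshold
#'   penalty rate `0.5 * sqrt(log(p) / n)` for the L1 logistic fits: larger
#'   values, stronger penalty.
#' @param weight_threshold tau: per-fold absolute-weight cutoff for the
#'   consensus intersection.
#' @param include_intercept_in_score include the mean intercept in scores.
#' @param percentile_mode see `expression_percentile`.
#' @export
mlConfig <- function(expression_percentile = 0.80, univariate_k = 1000L,
                     l1_strength = 1.0, weight_threshold = 0.05,
                     include_intercept_in_score = FALSE,
                     percentile_mode = c("per-feature-mean", "per-value")) {
  percentile_mode <- match.arg(percentile_mode)
  if (expression_percentile < 0 || expression_percentile >= 1)
    stopf("MLConfig: need 0 <= expression_percentile < 1")
  if (univariate_k < 1) stopf("MLConfig: univariate_k must be >= 1")
  if (l1_strength <= 0) stopf("MLConfig: l1_strength must be > 0")
  if (weight_threshold < 0) stopf("MLConfig: weight_threshold must be >= 0")
  structure(list(expression_percentile = expression_percentile,
                 univariate_k = as.integer(univariate_k),
                 l1_strength = l1_strength,
                 weight_threshold = weight_threshold,
                 include_intercept_in_score = include_intercept_in_score,
                 percentile_mode = percentile_mode),
            class = "MLConfig")
}

#' Single-cell QC thresholds
#'
#' Cells are kept when `min_n_feature < n_feature < max_n_feature`,
#' `n_count < max_n_count` and `pct_mito < max_pct_mito`.
#'
#' @param min_n_feature,max_n_feature detected-gene bounds (exclusive).
#' @param max_n_count UMI ceiling (exclusive).
#' @param max_pct_mito mitochondrial-percentage ceiling (exclusive).
#' @export
qcThresholds <- function(min_n_feature = 200, max_n_feature = 10000,
                         max_n_count = 25000, max_pct_mito = 25) {
  if (min_n_feature >= max_n_feature)
    stopf("QCThresholds: min_n_feature must be < max_n_feature")
  structure(list(min_n_feature = min_n_feature, max_n_feature = max_n_feature,
                 max_n_count = max_n_count, max_pct_mito = max_pct_mito),
            class = "QCThresholds")
}

#' Read / write a run configuration (YAML)
#'
#' The run configuration nests the stage configurations under the keys
#' `bulk_sim`, `sc_sim`, `marker_thresholds`, `ml`, `qc` and `insitu`, plus a
#' global `seed`, `out_dir` and `log_level`.  Unspecified entries take the
#' constructor defaults; round-trips are lossless.
#'
#' @param path YAML file path.
#' @return `readRunConfig` returns a named list with fully-resolved stage
#'   configurations; `writeRunConfig` writes and returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  buildRunConfig(raw)
}

buildRunConfig <- function(raw = list()) {
  seed <- raw$seed %||% 1L
  list(seed = as.integer(seed),
       out_dir = raw$out_dir %||% ".",
       log_level = raw$log_level %||% "info",
       bulk_sim = do.call(bulkSimConfig,
                          modifyList(list(seed = seed), raw$bulk_sim %||% list())),
       sc_sim = do.call(scSimConfig,
                        modifyList(list(seed = seed), raw$sc_sim %||% list())),
       marker_thresholds = do.call(markerThresholds, raw$marker_thresholds %||% list()),
       ml = do.call(mlConfig, raw$ml %||% list()),
       qc = do.call(qcThresholds, raw$qc %||% list()),
       insitu = modifyList(list(reference_label = NULL, alpha = 0.05,
                                relabel_frac = 0.01, ref_weight = 0.5,
                                cv_folds = 10L, top_frac = 0.05,
                                spline_df = 4L, percentile = 99),
                           raw$insitu %||% list()))
}

#' @rdname readRunConfig
#' @param config a run-configuration list.
#' @export
writeRunConfig <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(config), path, precision = 15L)
  invisible(path)
}
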