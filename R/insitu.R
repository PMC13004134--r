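#' Quality-control filtering of cells
#'
#' Keeps cells with `min_n_feature < n_feature < max_n_feature`,
#' `n_count < max_n_count` and `pct_mito < max_pct_mito` (all strict), and
#' records per-criterion removal counts in `metadata(x)$qc_report`.
#'
#' @param x a [CellDataset-class].
#' @param thresholds a [qcThresholds()] object.
#' @return The filtered [CellDataset-class].
#' @export
qcFilter <- function(x, thresholds = qcThresholds()) {
  stopifnot(is(x, "CellDataset"))
  cd <- colData(x)
  ok_feat <- cd$n_feature > thresholds$min_n_feature &
    cd$n_feature < thresholds$max_n_feature
  ok_count <- cd$n_count < thresholds$max_n_count
  ok_mito <- cd$pct_mito < thresholds$max_pct_mito
  keep <- ok_feat & ok_count & ok_mito
  if (!any(keep)) stopf("qcFilter: all cells removed")
  out <- x[, keep]
  metadata(out)$qc_report <- c(removed_n_feature = sum(!ok_feat),
                               removed_n_count = sum(!ok_count),
                               removed_pct_mito = sum(!ok_mito),
                               removed_total = sum(!keep),
                               kept = sum(keep))
  out
}

#' Log-normalize single-cell counts
#'
#' Per cell: counts scaled to a total of `scale_factor` (default 10,000),
#' then log1p — the standard log-normalization.
#'
#' @param x a [CellDataset-class] (post-QC) or a gene-by-cell count matrix.
#' @param scale_factor per-cell target total.
#' @return A sparse gene-by-cell matrix of log-normalized values (for a
#'   [CellDataset-class] input, the dataset with a `lognorm` assay added).
#' @export
logNormalize <- function(x, scale_factor = 1e4) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
  tot <- Matrix::colSums(cnt)
  if (any(tot == 0)) stopf("logNormalize: zero-count cell present (run QC first)")
  ln <- log1p(cnt %*% Matrix::Diagonal(x = scale_factor / tot))
  dimnames(ln) <- dimnames(cnt)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "lognorm") <- ln
    x
  } else ln
}

lognormAssay <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"lognorm" %in% names(assays(x))) x <- logNormalize(x)
    assay(x, "lognorm")
  } else x
}

#' Drop candidate genes elevated in the reference condition
#'
#' For each cluster containing both reference and non-reference cells, runs a
#' two-sided Wilcoxon rank-sum test per candidate gene on log-normalized
#' values (reference vs non-reference within the cluster), BH-adjusted
#' across candidates within the cluster.  A gene is removed if in any
#' cluster it is significantly (adjusted p < `alpha`) *higher* in reference
#' cells.  Clusters lacking one side are skipped with a warning.
#'
#' @param candidates character vector of candidate genes.
#' @param x a [CellDataset-class].
#' @param reference_label the reference condition (e.g. `"Day0"`).
#' @param alpha significance level on the adjusted p-value.
#' @return The filtered candidate vector (attribute `"removed"` lists drops).
#' @export
referenceConditionFilter <- function(candidates, x, reference_label,
                                     alpha = 0.05) {
  if (!length(candidates)) stopf("referenceConditionFilter: empty candidate set")
  cd <- colData(x)
  if (!reference_label %in% cd$condition)
    stopf("referenceConditionFilter: reference label '%s' not present",
          reference_label)
  ln <- lognormAssay(x)
  candidates <- intersect(candidates, rownames(ln))
  removed <- character()
  for (cl in unique(cd$cluster)) {
    in_cl <- cd$cluster == cl
    ref <- in_cl & cd$condition == reference_label
    non <- in_cl & cd$condition != reference_label
    if (!any(ref) || !any(non)) {
      warnf("referenceConditionFilter: cluster '%s' lacks reference or non-reference cells; skipped", cl)
      next
    }
    p <- numeric(length(candidates)); up_ref <- logical(length(candidates))
    for (i in seq_along(candidates)) {
      a <- ln[candidates[i], ref]; b <- ln[candidates[i], non]
      p[i] <- tryCatch(
        wilcox.test(a, b, exact = FALSE)$p.value,
        error = function(e) 1)
      up_ref[i] <- mean(a) > mean(b)
    }
    p[is.na(p)] <- 1
    adj <- p.adjust(p, method = "BH")
    removed <- union(removed, candidates[adj < alpha & up_ref])
  }
  out <- setdiff(candidates, removed)
  attr(out, "removed") <- removed
  out
}

#' Refine a candidate gene set by label-noise LASSO
#'
#' Trains a LASSO-regularized logistic regression on log-normalized values of
#' the candidate genes across all cells.  Reference-condition cells are
#' labeled 0, all others 1; a small seeded fraction of reference cells is
#' relabeled 1 to avoid complete separation; reference cells are
#' down-weighted.  The regularization parameter is chosen by `cv_folds`-fold
#' cross-validated weighted deviance (minimum rule).  The refined signature
#' comprises the nonzero-coefficient genes, restricted to positive
#' coefficients for scoring.
#'
#' @param x a [CellDataset-class].
#' @param candidates candidate genes.
#' @param reference_label reference condition label.
#' @param relabel_frac fraction of reference cells relabeled senescent
#'   (must lie in `[0, 0.2]`).
#' @param ref_weight sample weight of reference cells (others weigh 1).
#' @param cv_folds cross-validation folds.
#' @param seed integer seed for relabeling and fold assignment.
#' @return A [RefinedSignature-class].
#' @export
refineLasso <- function(x, candidates, reference_label, relabel_frac = 0.01,
                        ref_weight = 0.5, cv_folds = 10L, seed = 1L) {
  if (!length(candidates)) stopf("refineLasso: empty candidate set")
  if (relabel_frac < 0 || relabel_frac > 0.2)
    stopf("refineLasso: relabel_frac must lie in [0, 0.2] (got %g)", relabel_frac)
  cd <- colData(x)
  if (!any(cd$condition == reference_label))
    stopf("refineLasso: no reference cells with label '%s'", reference_label)
  ln <- lognormAssay(x)
  candidates <- intersect(candidates, rownames(ln))
  xm <- Matrix::t(ln[candidates, , drop = FALSE])
  is_ref <- cd$condition == reference_label
  withSeed(substreamSeed(seed, "refine"), {
    y <- as.integer(!is_ref)
    flip <- sample(which(is_ref), round(relabel_frac * sum(is_ref)))
    y[flip] <- 1L
    w <- ifelse(is_ref, ref_weight, 1)
    foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
    cv <- glmnet::cv.glmnet(xm, y, family = "binomial", weights = w,
                            foldid = foldid, type.measure = "deviance",
                            alpha = 1, standardize = TRUE)
    cf <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
    nz <- cf[-1][cf[-1] != 0]
    pos <- names(nz)[nz > 0]
    if (!length(pos)) {
      warnf("refineLasso: refined set is empty; falling back to unfiltered candidates")
      pos <- candidates
      nz <- numeric()
    }
    new("RefinedSignature", genes = pos, coefficients = nz,
        lambda = cv$lambda.min, seed = as.integer(seed),
        provenance = list(relabel_frac = relabel_frac, ref_weight = ref_weight,
                          cv_folds = as.integer(cv_folds),
                          reference_label = reference_label,
                          n_candidates = length(candidates)))
  })
}

#' Per-cell rank-recovery (AUCell-style) gene-set scores
#'
#' Ranks all genes within each cell by descending expression (ties broken by
#' a seeded random permutation, or deterministic mid-ranks) and integrates
#' the recovery curve of the gene set over the top `top_frac` of the ranking:
#' with `T = floor(top_frac * n_genes)`, `m = min(|set|, T)` and `R(k)` the
#' number of set genes at rank `<= k`, the raw score is
#' `sum_{k=1..T} R(k) / sum_{k=1..T} min(k, m)`, which lies in `[0, 1]`.
#'
#' @param x a [CellDataset-class] or gene-by-cell expression matrix (counts
#'   or normalized values; only the within-cell ranking matters).
#' @param gene_set character vector (e.g. [signatureGenes()] of a
#'   [RefinedSignature-class]).
#' @param top_frac fraction of the ranking integrated (default 0.05).
#' @param seed seed for random tie-breaking.
#' @param ties `"random"` (seeded) or `"midrank"` (deterministic).
#' @return Named numeric vector of per-cell raw scores in `[0, 1]`.
#' @export
recoveryAUCScore <- function(x, gene_set, top_frac = 0.05, seed = 1L,
                             ties = c("random", "midrank")) {
  ties <- match.arg(ties)
  m0 <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
  if (top_frac <= 0 || top_frac > 1) stopf("recoveryAUCScore: top_frac must be in (0, 1]")
  genes <- rownames(m0)
  set <- intersect(unique(gene_set), genes)
  if (!length(set))
    stopf("recoveryAUCScore: gene set shares no genes with the dataset")
  n_genes <- length(genes)
  T_ <- max(1L, floor(top_frac * n_genes))
  m <- min(length(set), T_)
  denom <- sum(pmin(seq_len(T_), m))
  in_set <- genes %in% set
  m0 <- as.matrix(m0)
  withSeed(substreamSeed(seed, "aucell"), {
    scores <- vapply(seq_len(ncol(m0)), function(j) {
      r <- if (ties == "random") rank(-m0[, j], ties.method = "random")
           else rank(-m0[, j], ties.method = "average")
      rs <- r[in_set]
      rs <- rs[rs <= T_]
      if (!length(rs)) return(0)
      sum(T_ - rs + 1) / denom
    }, numeric(1))
    names(scores) <- colnames(m0)
    scores
  })
}

#' Correct per-cell scores for sequencing depth
#'
#' Fits `score ~ ns(log10(n_count), df = spline_df)` by least squares (a
#' fixed-df realization of a GAM spline term) and returns the residuals as
#' corrected scores; their mean is ~0.  Constant depth degrades to
#' mean-centering with a warning.
#'
#' @param scores numeric per-cell raw scores.
#' @param n_count per-cell total UMI counts (positive).
#' @param spline_df spline degrees of freedom (default 4).
#' @return Numeric vector of corrected scores (residuals).
#' @export
depthCorrect <- function(scores, n_count, spline_df = 4L) {
  stopifnot(length(scores) == length(n_count))
  if (any(n_count <= 0)) stopf("depthCorrect: n_count must be > 0")
  if (length(scores) < spline_df + 2L)
    stopf("depthCorrect: need at least spline_df + 2 cells")
  if (sd(n_count) == 0) {
    warnf("depthCorrect: constant n_count; degrading to mean-centering")
    return(scores - mean(scores))
  }
  basis <- splines::ns(log10(n_count), df = spline_df)
  fit <- lm(scores ~ basis)
  out <- resid(fit)
  names(out) <- names(scores)
  out
}

#' Flag senescent cells by a reference-percentile threshold
#'
#' The threshold is the linear-interpolation `percentile` of corrected
#' scores among reference-condition cells; cells strictly exceeding it are
#' flagged senescent.
#'
#' @param corrected numeric corrected scores, all cells.
#' @param is_reference logical, which cells belong to the reference condition.
#' @param percentile percentile of the reference distribution (default 99).
#' @return A list with `flags` (logical) and `threshold`.
#' @export
callSenescent <- function(corrected, is_reference, percentile = 99) {
  ref <- corrected[is_reference]
  if (!length(ref)) stopf("callSenescent: no reference cells")
  if (length(ref) < 100L)
    warnf("callSenescent: only %d reference cells; the %gth percentile may be unstable",
          length(ref), percentile)
  thr <- unname(quantile(ref, percentile / 100, type = 7))
  list(flags = corrected > thr, threshold = thr)
}

#' Senescent-cell fractions per cluster and condition
#'
#' @param flags logical senescent flags per cell.
#' @param clusters,conditions per-cell labels.
#' @return A `data.frame` with per-(cluster, condition) cell counts,
#'   senescent counts and fractions, plus per-condition marginal rows
#'   (`cluster = "ALL"`).
#' @export
senescentFractions <- function(flags, clusters, conditions) {
  d <- data.frame(flag = as.logical(flags), cluster = as.character(clusters),
                  condition = as.character(conditions))
  cell_rows <- do.call(rbind, lapply(
    split(d, list(d$cluster, d$condition), drop = TRUE), function(g)
      data.frame(cluster = g$cluster[1], condition = g$condition[1],
                 n_cells = nrow(g), n_senescent = sum(g$flag),
                 fraction = mean(g$flag))))
  marg <- do.call(rbind, lapply(split(d, d$condition), function(g)
    data.frame(cluster = "ALL", condition = g$condition[1],
               n_cells = nrow(g), n_senescent = sum(g$flag),
               fraction = mean(g$flag))))
  out <- rbind(cell_rows, marg)
  rownames(out) <- NULL
  out[order(out$condition, out$cluster), , drop = FALSE]
}

#' Module score (average expression minus bin-matched controls)
#'
#' For each set gene, `n_ctrl` control genes are sampled (seeded) from the
#' same average-expression bin (`n_bins` bins over all genes, set genes
#' excluded from the control pool); the per-cell score is the mean
#' log-normalized expression of the set genes minus the mean over the
#' sampled control genes.
#'
#' @param x a [CellDataset-class] or log-normalized gene-by-cell matrix.
#' @param gene_set character vector of set genes.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed.
#' @return Named numeric vector of per-cell module scores.
#' @export
moduleScore <- function(x, gene_set, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  ln <- lognormAssay(x)
  set <- intersect(unique(gene_set), rownames(ln))
  if (!length(set)) stopf("moduleScore: gene set not present in data")
  avg <- Matrix::rowMeans(ln)
  br <- quantile(avg, probs = seq(0, 1, length.out = n_bins + 1L))
  br <- unique(br)
  bin <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(ln)
  withSeed(substreamSeed(seed, "modulescore"), {
    ctrl <- unlist(lapply(set, function(g) {
      pool <- setdiff(names(bin)[bin == bin[g]], set)
      if (!length(pool)) pool <- setdiff(names(bin), set)
      if (length(pool) < n_ctrl) {
        warnf("moduleScore: control pool smaller than n_ctrl in bin %d; sampling with replacement", bin[g])
        sample(pool, n_ctrl, replace = TRUE)
      } else sample(pool, n_ctrl)
    }))
    set_mean <- Matrix::colMeans(ln[set, , drop = FALSE])
    ctrl_mean <- Matrix::colMeans(ln[ctrl, , drop = FALSE])
    out <- set_mean - ctrl_mean
    names(out) <- colnames(ln)
    out
  })
}

#' Run the full in-situ senescence scoring pipeline
#'
#' QC filtering, log-normalization, reference-condition candidate filtering,
#' label-noise LASSO refinement, rank-recovery scoring, spline depth
#' correction, reference-percentile thresholding and fraction tabulation.
#'
#' @param x a [CellDataset-class].
#' @param candidates candidate senescence genes (e.g. an expanded consensus
#'   signature list).
#' @param reference_label the reference (minimal-senescence) condition.
#' @param qc [qcThresholds()].
#' @param alpha reference-condition filter significance level.
#' @param relabel_frac,ref_weight,cv_folds see [refineLasso()].
#' @param top_frac see [recoveryAUCScore()].
#' @param spline_df see [depthCorrect()].
#' @param percentile see [callSenescent()].
#' @param seed root seed for the seeded stages.
#' @return A list: `scores` (DataFrame with `raw_auc`, `corrected`,
#'   `senescent` per kept cell), `fractions`, `refined`
#'   ([RefinedSignature-class]), `threshold`, `dataset` (the QC-filtered,
#'   normalized [CellDataset-class]) and `report`.
#' @export
runInsituPipeline <- function(x, candidates, reference_label,
                              qc = qcThresholds(), alpha = 0.05,
                              relabel_frac = 0.01, ref_weight = 0.5,
                              cv_folds = 10L, top_frac = 0.05,
                              spline_df = 4L, percentile = 99, seed = 1L) {
  filtered <- qcFilter(x, qc)
  filtered <- logNormalize(filtered)
  kept <- referenceConditionFilter(candidates, filtered, reference_label,
                                   alpha = alpha)
  refined <- refineLasso(filtered, kept, reference_label,
                         relabel_frac = relabel_frac, ref_weight = ref_weight,
                         cv_folds = cv_folds, seed = seed)
  raw <- recoveryAUCScore(filtered, signatureGenes(refined),
                          top_frac = top_frac, seed = seed)
  corrected <- depthCorrect(raw, colData(filtered)$n_count,
                            spline_df = spline_df)
  call <- callSenescent(corrected,
                        colData(filtered)$condition == reference_label,
                        percentile = percentile)
  scores <- DataFrame(raw_auc = raw, corrected = corrected,
                      senescent = call$flags,
                      row.names = colnames(filtered))
  fr <- senescentFractions(call$flags, colData(filtered)$cluster,
                           colData(filtered)$condition)
  list(scores = scores, fractions = fr, refined = refined,
       threshold = call$threshold, dataset = filtered,
       report = list(qc = metadata(filtered)$qc_report,
                     candidates_in = length(candidates),
                     candidates_after_reference_filter = length(kept),
                     refined_genes = length(signatureGenes(refined)),
                     threshold = call$threshold, seed = seed))
}
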