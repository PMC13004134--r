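#' Filter and transform the corpus for signature learning
#'
#' Keeps features with strictly positive, non-missing values in every sample;
#' drops features whose mean expression is at or below the
#' `expression_percentile` quantile of all feature means (or, in
#' `"per-value"` mode, whose values fall at or below the quantile of all
#' values in more than half the samples); log1p-transforms; then retains the
#' top `univariate_k` features by one-way F statistic between senescent and
#' control samples.
#'
#' @param x a [SenExperiment-class].
#' @param config an [mlConfig()] object.
#' @return A list: `prepared` (a [SenExperiment-class] whose assay holds the
#'   log1p values of the kept features), `features`, and `report` (feature
#'   counts after each filter).
#' @export
prepareFeatures <- function(x, config = mlConfig()) {
  stopifnot(is(x, "SenExperiment"))
  st <- colData(x)$state
  if (!all(c("senescent", "control") %in% st))
    stopf("prepareFeatures: matrix must contain both senescent and control samples")
  v <- assay(x)
  n0 <- nrow(v)
  complete <- rowSums(is.na(v) | v <= 0) == 0L
  v <- v[complete, , drop = FALSE]
  if (!nrow(v))
    stopf("prepareFeatures: the non-zero/complete-case filter removed every feature")
  if (config$percentile_mode == "per-feature-mean") {
    means <- rowMeans(v)
    keep <- means > quantile(means, config$expression_percentile)
  } else {
    thr <- quantile(as.vector(v), config$expression_percentile)
    keep <- rowMeans(v > thr) > 0.5
  }
  v <- v[keep, , drop = FALSE]
  if (!nrow(v))
    stopf("prepareFeatures: the expression-percentile filter removed every feature")
  lv <- log1p(v)
  fstat <- rowFStat(lv, st)
  k <- min(config$univariate_k, nrow(lv))
  sel <- rownames(lv)[order(-fstat)[seq_len(k)]]
  lv <- lv[sel, , drop = FALSE]
  prep <- SenExperiment(lv, cell_type = colData(x)$cell_type,
                        trigger = colData(x)$trigger, state = st,
                        modality = metadata(x)$modality)
  metadata(prep)$transform <- "log1p"
  list(prepared = prep, features = sel,
       report = c(input = n0, complete = sum(complete),
                  above_percentile = sum(keep), univariate = length(sel)))
}

#' Fit leave-one-cell-type-out L1-penalized logistic models
#'
#' One binary classifier per cell type, each trained on all samples except
#' those of the held-out type, minimizing the penalized logistic objective
#' `mean logistic loss + lambda * sum(|w|)` on features standardized within
#' the training split.  The penalty follows the universal-threshold rate for
#' sparse logistic regression,
#' `lambda = l1_strength * 0.5 * sqrt(log(p) / n_train)`, so that at the
#' default multiplier 1.0 null features are excluded with high probability
#' while strongly class-associated features survive, at any corpus size.
#'
#' @param prepared a prepared [SenExperiment-class] from [prepareFeatures()].
#' @param config an [mlConfig()] object.
#' @return List of fold models, each with `held_out`, `weights` (standardized
#'   scale), `intercept`, `center`, `scale`, and `heldout_auc`.
#' @export
fitFoldModels <- function(prepared, config = mlConfig()) {
  stopifnot(is(prepared, "SenExperiment"))
  cd <- colData(prepared)
  cts <- unique(cd$cell_type)
  if (length(cts) < 2L)
    stopf("fitFoldModels: need >= 2 cell types for leave-one-cell-type-out")
  lv <- assay(prepared)
  y_all <- as.integer(cd$state == "senescent")
  lapply(cts, function(ct) {
    tr <- cd$cell_type != ct
    y <- y_all[tr]
    if (length(unique(y)) < 2L)
      stopf("fitFoldModels: training split excluding '%s' has only one class", ct)
    xm <- t(lv[, tr, drop = FALSE])
    ctr <- colMeans(xm)
    scl <- apply(xm, 2, sd)
    scl[scl == 0] <- 1
    xs <- scale(xm, center = ctr, scale = scl)
    lam <- config$l1_strength * 0.5 * sqrt(log(ncol(xs)) / nrow(xs))
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                          lambda = lam, standardize = FALSE, thresh = 1e-10)
    w <- as.numeric(fit$beta)
    names(w) <- rownames(lv)
    b0 <- as.numeric(fit$a0)
    xh <- scale(t(lv[, !tr, drop = FALSE]), center = ctr, scale = scl)
    eta <- drop(xh %*% w) + b0
    list(held_out = ct, weights = w, intercept = b0,
         center = ctr, scale = scl,
         heldout_auc = rankAUC(eta, y_all[!tr] == 1L))
  })
}

#' Intersect per-fold informative features
#'
#' Retains features whose absolute standardized weight exceeds
#' `weight_threshold` in every fold; an empty intersection is valid.
#'
#' @param folds list of fold models from [fitFoldModels()].
#' @param weight_threshold tau (default from [mlConfig()]).
#' @return Character vector of consensus features.
#' @export
consensusSelect <- function(folds, weight_threshold = 0.05) {
  stopifnot(length(folds) >= 1L)
  Reduce(intersect, lapply(folds, function(f)
    names(f$weights)[abs(f$weights) > weight_threshold]))
}

#' Refit unpenalized per-fold models on the consensus set and average
#'
#' For each leave-one-cell-type-out split, fits an unpenalized logistic
#' regression on the consensus features using the log1p values directly (not
#' standardized), so the averaged coefficients live on the score's scale.
#' Splits with perfect separation (divergent maximum likelihood) fall back to
#' a tiny-ridge fit (`lambda = 1e-6`) to keep coefficients finite; affected
#' folds are flagged in the provenance.
#'
#' @param prepared a prepared [SenExperiment-class].
#' @param features consensus features from [consensusSelect()].
#' @param config an [mlConfig()] object.
#' @param provenance optional list merged into the signature's provenance.
#' @return A [ConsensusSignature-class].
#' @export
refitAndAverage <- function(prepared, features, config = mlConfig(),
                            provenance = list()) {
  if (!length(features)) stopf("refitAndAverage: empty consensus feature set")
  cd <- colData(prepared)
  cts <- unique(cd$cell_type)
  lv <- assay(prepared)[features, , drop = FALSE]
  y_all <- as.integer(cd$state == "senescent")
  coefs <- matrix(NA_real_, length(features), length(cts),
                  dimnames = list(features, cts))
  intercepts <- numeric(length(cts))
  ridge_folds <- character()
  for (i in seq_along(cts)) {
    tr <- cd$cell_type != cts[i]
    xm <- t(lv[, tr, drop = FALSE])
    y <- y_all[tr]
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(`(Intercept)` = 1, xm), y, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (separated || !fit$converged || any(!is.finite(fit$coefficients))) {
      rfit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                             lambda = 1e-6, standardize = FALSE, thresh = 1e-10)
      coefs[, i] <- as.numeric(rfit$beta)
      intercepts[i] <- as.numeric(rfit$a0)
      ridge_folds <- c(ridge_folds, cts[i])
    } else {
      cf <- fit$coefficients
      coefs[, i] <- cf[-1]
      intercepts[i] <- cf[1]
    }
  }
  ConsensusSignature(weights = rowMeans(coefs),
                     intercept = mean(intercepts),
                     modality = metadata(prepared)$modality %||% "RNA",
                     foldCount = length(cts),
                     provenance = c(provenance,
                                    list(config = unclass(config),
                                         ridge_fallback_folds = ridge_folds)))
}

#' Score samples with a consensus signature
#'
#' `score_j = sum_i w_i * log1p(x_ij)` (plus the intercept when the signature
#' was configured to include it).  Signature features absent from the matrix
#' contribute 0, with a warning, enabling cross-platform application.
#'
#' @param x a [SenExperiment-class], or a features-by-samples numeric matrix
#'   of normalized (untransformed) expression values.
#' @param signature a [ConsensusSignature-class].
#' @param probability also return the logistic probability
#'   `plogis(score + intercept)`.
#' @return A [S4Vectors::DataFrame] with a `score` column (and `probability`
#'   when requested), one row per sample.
#' @export
scoreSamples <- function(x, signature, probability = FALSE) {
  v <- if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
  w <- signature@weights
  present <- intersect(names(w), rownames(v))
  if (!length(present))
    stopf("scoreSamples: none of the %d signature features are present",
          length(w))
  miss <- setdiff(names(w), present)
  if (length(miss))
    warnf("scoreSamples: %d signature feature(s) absent, contributing 0 (e.g. %s)",
          length(miss), miss[1])
  lx <- log1p(v[present, , drop = FALSE])
  lx[is.na(lx)] <- 0
  sc <- drop(crossprod(lx, w[present]))
  include <- isTRUE(signature@provenance$config$include_intercept_in_score)
  out <- DataFrame(score = if (include) sc + signature@intercept else sc,
                   row.names = colnames(v))
  if (probability)
    out$probability <- stats::plogis(sc + signature@intercept)
  out
}

#' Derive a consensus senescence signature (orchestrator)
#'
#' Runs [prepareFeatures()], [fitFoldModels()], [consensusSelect()] and
#' [refitAndAverage()] and attaches a run report (feature counts at each
#' stage and per-fold held-out AUROC) to the signature's provenance.
#'
#' @param x a [SenExperiment-class].
#' @param config an [mlConfig()] object.
#' @param seed recorded in provenance (the fit itself is deterministic).
#' @return A [ConsensusSignature-class].
#' @export
deriveSignature <- function(x, config = mlConfig(), seed = NA_integer_) {
  prep <- prepareFeatures(x, config)
  folds <- fitFoldModels(prep$prepared, config)
  consensus <- consensusSelect(folds, config$weight_threshold)
  if (!length(consensus))
    stopf("deriveSignature: consensus feature set is empty")
  report <- list(stage_counts = c(prep$report, consensus = length(consensus)),
                 heldout_auc = vapply(folds, function(f) f$heldout_auc,
                                      numeric(1)),
                 held_out = vapply(folds, function(f) f$held_out, character(1)),
                 seed = seed)
  refitAndAverage(prep$prepared, consensus, config, provenance = report)
}
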