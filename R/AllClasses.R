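#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Labeled bulk expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one modality of the
#' senescence corpus: features in rows, samples in columns, with per-sample
#' `cell_type`, `trigger` (CTIS/IRIS/OSIS/OIS or a control analog) and `state`
#' (`"senescent"` or `"control"`) labels in `colData`, and the modality tag
#' (`"RNA"` or `"protein"`) in `metadata(x)$modality`.  RNA values are
#' library-size-normalized counts (finite, non-negative); protein values are
#' intensities and may contain `NA` (missing).
#'
#' @slot .placeholder see `SummarizedExperiment`
#' @export
setClass("SenExperiment", contains = "SummarizedExperiment")

validSenExperiment <- function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("cell_type", "trigger", "state")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (!all(cd$state %in% c("senescent", "control")))
      msg <- c(msg, "state must be 'senescent' or 'control'")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated sample identifiers")
    mod <- metadata(object)$modality
    if (is.null(mod) || !mod %in% c("RNA", "protein"))
      msg <- c(msg, "metadata(x)$modality must be 'RNA' or 'protein'")
    v <- assay(object)
    if (identical(mod, "RNA") && (anyNA(v) || any(!is.finite(v)) || any(v < 0)))
      msg <- c(msg, "RNA values must be finite and >= 0")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SenExperiment", validSenExperiment)

#' Construct a SenExperiment
#'
#' @param values numeric matrix, features x samples.
#' @param cell_type,trigger,state character vectors, one entry per sample.
#' @param modality `"RNA"` or `"protein"`.
#' @return A [SenExperiment-class] object.
#' @examples
#' v <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' se <- SenExperiment(v, cell_type = rep("WI38", 5), trigger = rep("CTIS", 5),
#'                     state = c("control", "control", rep("senescent", 3)))
#' @export
SenExperiment <- function(values, cell_type, trigger, state, modality = "RNA") {
  values <- as.matrix(values)
  cd <- DataFrame(cell_type = as.character(cell_type),
                  trigger = as.character(trigger),
                  state = as.character(state),
                  row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(values = values), colData = cd)
  metadata(se)$modality <- modality
  new("SenExperiment", se)
}

#' Single-cell/nucleus count dataset
#'
#' A [SingleCellExperiment::SingleCellExperiment] with a `counts` assay
#' (genes x cells, non-negative integers), per-cell `cluster`, `condition`
#' (timepoint), `n_count` (total UMIs), `n_feature` (genes detected) and
#' `pct_mito` (percent mitochondrial counts, 0-100) in `colData`, and a
#' logical `is_mito` column in `rowData` tagging the mitochondrial genes.
#'
#' @slot .placeholder see `SingleCellExperiment`
#' @export
setClass("CellDataset", contains = "SingleCellExperiment")

validCellDataset <- function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("cluster", "condition", "n_count", "n_feature", "pct_mito")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  if (!"is_mito" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain logical column is_mito")
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  if (!length(msg)) {
    cs <- Matrix::colSums(assay(object, "counts"))
    if (any(abs(cs - cd$n_count) > 1e-6))
      msg <- c(msg, "n_count must equal per-cell column sums")
    nf <- Matrix::colSums(assay(object, "counts") > 0)
    if (any(nf != cd$n_feature))
      msg <- c(msg, "n_feature must equal per-cell nonzero gene counts")
    if (any(cd$pct_mito < 0 | cd$pct_mito > 100))
      msg <- c(msg, "pct_mito must be in [0, 100]")
    if (any(!nzchar(as.character(cd$cluster))) ||
        any(!nzchar(as.character(cd$condition))))
      msg <- c(msg, "cluster and condition labels must be non-empty")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("CellDataset", validCellDataset)

#' Construct a CellDataset
#'
#' `n_count`, `n_feature` and `pct_mito` are computed from the counts if not
#' supplied.
#'
#' @param counts gene x cell count matrix (dense or sparse).
#' @param cluster,condition per-cell labels.
#' @param is_mito logical per-gene mitochondrial tag; defaults to gene names
#'   starting with `"mt-"` (case-insensitive).
#' @param ... additional per-cell columns (e.g. `true_senescent`).
#' @return A [CellDataset-class] object.
#' @export
CellDataset <- function(counts, cluster, condition, is_mito = NULL, ...) {
  counts <- as(counts, "CsparseMatrix")
  if (is.null(is_mito))
    is_mito <- grepl("^mt-", rownames(counts), ignore.case = TRUE)
  cd <- DataFrame(cluster = as.character(cluster),
                  condition = as.character(condition),
                  n_count = Matrix::colSums(counts),
                  n_feature = Matrix::colSums(counts > 0),
                  pct_mito = 100 * Matrix::colSums(counts[is_mito, , drop = FALSE]) /
                    pmax(Matrix::colSums(counts), 1),
                  ...,
                  row.names = colnames(counts))
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd,
                              rowData = DataFrame(is_mito = is_mito))
  new("CellDataset", sce)
}

#' Consensus machine-learning senescence signature
#'
#' Feature weights are the arithmetic mean, over leave-one-cell-type-out
#' splits, of unpenalized logistic-regression coefficients refit on the
#' consensus feature set; the intercept is the mean intercept.
#'
#' @slot weights named numeric vector of feature weights (log1p scale).
#' @slot intercept mean intercept across folds.
#' @slot modality `"RNA"` or `"protein"`.
#' @slot foldCount number of leave-one-cell-type-out folds averaged.
#' @slot provenance list (config, seed, stage feature counts, fold metrics).
#' @export
setClass("ConsensusSignature",
         representation(weights = "numeric", intercept = "numeric",
                        modality = "character", foldCount = "integer",
                        provenance = "list"))

setValidity("ConsensusSignature", function(object) {
  msg <- NULL
  if (is.null(names(object@weights)) || anyDuplicated(names(object@weights)))
    msg <- c(msg, "weights must be uniquely named")
  if (anyNA(object@weights) || any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (is.null(msg)) TRUE else msg
})

#' @export
ConsensusSignature <- function(weights, intercept, modality = "RNA",
                               foldCount = NA_integer_, provenance = list()) {
  new("ConsensusSignature", weights = weights, intercept = intercept,
      modality = modality, foldCount = as.integer(foldCount),
      provenance = provenance)
}

#' Refined in-situ senescence signature
#'
#' Product of the label-noise LASSO refinement on single-cell data: the
#' positive-coefficient genes feed rank-recovery scoring.
#'
#' @slot genes ordered character vector of positive-coefficient genes.
#' @slot coefficients named numeric, nonzero coefficients at the chosen lambda.
#' @slot lambda chosen regularization parameter.
#' @slot seed integer seed used for relabeling and fold assignment.
#' @slot provenance list of refinement parameters.
#' @export
setClass("RefinedSignature",
         representation(genes = "character", coefficients = "numeric",
                        lambda = "numeric", seed = "integer",
                        provenance = "list"))

#' A per-model (or per-cell-type) directional marker set
#'
#' @slot cellType cell type label.
#' @slot trigger trigger label (or `"ALL"` after trigger intersection).
#' @slot modality `"RNA"` or `"protein"`.
#' @slot direction `"up"` or `"down"`.
#' @slot features character vector of marker identifiers.
#' @export
setClass("MarkerSet",
         representation(cellType = "character", trigger = "character",
                        modality = "character", direction = "character",
                        features = "character"))

setValidity("MarkerSet", function(object) {
  msg <- NULL
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (anyDuplicated(object@features))
    msg <- c(msg, "duplicated features in marker set")
  if (is.null(msg)) TRUE else msg
})

#' @export
MarkerSet <- function(cellType, trigger, modality, direction, features) {
  new("MarkerSet", cellType = cellType, trigger = trigger,
      modality = modality, direction = direction,
      features = unique(as.character(features)))
}

setMethod("show", "SenExperiment", function(object) {
  callNextMethod()
  cat(sprintf("modality: %s | %d cell types | %d senescent / %d control samples\n",
              metadata(object)$modality,
              length(unique(colData(object)$cell_type)),
              sum(colData(object)$state == "senescent"),
              sum(colData(object)$state == "control")))
})

setMethod("show", "CellDataset", function(object) {
  callNextMethod()
  cat(sprintf("%d clusters | conditions: %s\n",
              length(unique(colData(object)$cluster)),
              paste(unique(colData(object)$condition), collapse = ", ")))
})

setMethod("show", "ConsensusSignature", function(object) {
  cat(sprintf("ConsensusSignature (%s): %d features, %d folds, intercept %.4g\n",
              object@modality, length(object@weights), object@foldCount,
              object@intercept))
  k <- head(order(-abs(object@weights)), 5L)
  for (i in k)
    cat(sprintf("  %-18s %+.4f\n", names(object@weights)[i], object@weights[i]))
  if (length(object@weights) > 5L) cat("  ...\n")
})

setMethod("show", "RefinedSignature", function(object) {
  cat(sprintf("RefinedSignature: %d positive genes (lambda = %.4g, seed = %d)\n",
              length(object@genes), object@lambda, object@seed))
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet %s/%s [%s, %s]: %d features\n", object@cellType,
              object@trigger, object@modality, object@direction,
              length(object@features)))
})

#' @describeIn ConsensusSignature-class feature weights
#' @param object,x a `ConsensusSignature`
#' @export
signatureWeights <- function(object) object@weights

#' @describeIn ConsensusSignature-class mean intercept
#' @export
signatureIntercept <- function(object) object@intercept

#' @describeIn RefinedSignature-class genes used for scoring
#' @export
signatureGenes <- function(object) {
  if (is(object, "RefinedSignature")) object@genes else names(object@weights)
}

#' @describeIn MarkerSet-class marker identifiers
#' @export
markerFeatures <- function(object) object@features
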