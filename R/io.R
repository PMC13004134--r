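#' Read / write a bulk expression matrix as TSV
#'
#' The values file is dense TSV with samples in rows and features in columns
#' (header row of feature identifiers, first column `sample`); the metadata
#' file is a TSV with columns `sample`, `cell_type`, `trigger`, `state`.
#'
#' @param x a [SenExperiment-class].
#' @param values_path,meta_path file paths.
#' @return `readLabeledMatrix` returns a [SenExperiment-class];
#'   `writeLabeledMatrix` returns the paths invisibly.
#' @export
writeLabeledMatrix <- function(x, values_path, meta_path) {
  stopifnot(is(x, "SenExperiment"))
  v <- t(assay(x))
  df <- data.frame(sample = rownames(v), v, check.names = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  md <- data.frame(sample = colnames(x), cd[, c("cell_type", "trigger", "state")],
                   modality = metadata(x)$modality)
  write.table(md, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(values_path, meta_path))
}

#' @rdname writeLabeledMatrix
#' @export
readLabeledMatrix <- function(values_path, meta_path) {
  for (p in c(values_path, meta_path))
    if (!file.exists(p)) stopf("readLabeledMatrix: file not found: %s", p)
  hdr <- strsplit(readLines(values_path, n = 1L), "\t", fixed = TRUE)[[1]]
  feats <- hdr[-1]
  dup <- feats[duplicated(feats)]
  if (length(dup))
    stopf("readLabeledMatrix: %s: duplicated feature column '%s'",
          values_path, dup[1])
  df <- read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  num <- df[, -1, drop = FALSE]
  bad <- which(!vapply(num, is.numeric, logical(1)))
  if (length(bad))
    stopf("readLabeledMatrix: %s: non-numeric values in column '%s'",
          values_path, colnames(num)[bad[1]])
  v <- t(as.matrix(num))
  colnames(v) <- df[[1]]
  md <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_type", "trigger", "state")
  if (!all(need %in% colnames(md)))
    stopf("readLabeledMatrix: %s: missing metadata columns (%s)", meta_path,
          paste(setdiff(need, colnames(md)), collapse = ", "))
  if (!setequal(md$sample, colnames(v)))
    stopf("readLabeledMatrix: sample identifiers differ between %s and %s",
          values_path, meta_path)
  md <- md[match(colnames(v), md$sample), ]
  SenExperiment(v, cell_type = md$cell_type, trigger = md$trigger,
                state = md$state,
                modality = if ("modality" %in% colnames(md)) md$modality[1] else "RNA")
}

#' Read / write a single-cell dataset as an MTX triplet
#'
#' Writes `matrix.mtx` (1-based coordinate MatrixMarket), `features.tsv`
#' (columns `gene`, `is_mito`), `barcodes.tsv` and `cell_metadata.tsv`
#' (columns `barcode`, `cluster`, `condition`, `n_count`, `n_feature`,
#' `pct_mito` plus any extra per-cell columns) into `dir`.
#'
#' @param x a [CellDataset-class].
#' @param dir directory for the triplet.
#' @return `readCellDataset` returns a [CellDataset-class];
#'   `writeCellDataset` returns `dir` invisibly.
#' @export
writeCellDataset <- function(x, dir) {
  stopifnot(is(x, "CellDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(assay(x, "counts"), file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene = rownames(x), is_mito = rowData(x)$is_mito),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(colData(x))
  write.table(data.frame(barcode = colnames(x), cd),
              file.path(dir, "cell_metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCellDataset
#' @export
readCellDataset <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cell_metadata.tsv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stopf("readCellDataset: incomplete MTX triplet; missing %s",
          paste(basename(miss), collapse = ", "))
  m <- as(Matrix::readMM(paths[1]), "CsparseMatrix")
  feats <- read.delim(paths[2], stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  if (length(barcodes) != ncol(m))
    stopf("readCellDataset: %d barcodes but %d matrix columns",
          length(barcodes), ncol(m))
  if (nrow(feats) != nrow(m))
    stopf("readCellDataset: %d features but %d matrix rows", nrow(feats), nrow(m))
  if (anyDuplicated(barcodes))
    stopf("readCellDataset: duplicated barcode '%s'",
          barcodes[duplicated(barcodes)][1])
  dimnames(m) <- list(feats$gene, barcodes)
  md <- read.delim(paths[4], stringsAsFactors = FALSE)
  md <- md[match(barcodes, md$barcode), ]
  extra <- setdiff(colnames(md), c("barcode", "cluster", "condition",
                                   "n_count", "n_feature", "pct_mito"))
  args <- c(list(counts = m, cluster = md$cluster, condition = md$condition,
                 is_mito = as.logical(feats$is_mito)),
            as.list(md[extra]))
  do.call(CellDataset, args)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then members.  Reading preserves set
#' order; duplicated members within a line are deduplicated with a warning;
#' an empty member list is an error naming the set.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (recycled).
#' @return `readGMT` returns a named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stopf("readGMT: file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stopf("readGMT: %s line %d: set '%s' has an empty member list", path, i,
            parts[1] %||% "?")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stopf("readGMT: %s line %d: set '%s' has an empty member list", path, i,
            parts[1])
    if (anyDuplicated(members)) {
      warnf("readGMT: set '%s' has duplicated members; deduplicated", parts[1])
      members <- unique(members)
    }
    out[[parts[1]]] <- members
  }
  out
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, descriptions = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a differential-expression table (TSV)
#'
#' Columns: `feature`, `log2_fc`, `p_value`, `adj_p`, `base_sen`, `base_ctrl`.
#'
#' @param de a DETable `data.frame`.
#' @param path TSV path.
#' @export
writeDETable <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature", "log2_fc", "p_value")
  if (!all(need %in% colnames(de)))
    stopf("readDETable: %s: missing columns (%s)", path,
          paste(setdiff(need, colnames(de)), collapse = ", "))
  if (anyDuplicated(de$feature))
    stopf("readDETable: %s: duplicated feature '%s'", path,
          de$feature[duplicated(de$feature)][1])
  de
}

#' Read / write an ortholog table (TSV, columns human / mouse)
#'
#' @param table `data.frame` with columns `human` and `mouse`.
#' @param path TSV path.
#' @export
writeOrthologTable <- function(table, path) {
  write.table(table[, c("human", "mouse")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeOrthologTable
#' @export
readOrthologTable <- function(path) {
  if (!file.exists(path)) stopf("readOrthologTable: file not found: %s", path)
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != 2L)
  if (length(bad))
    stopf("readOrthologTable: %s: malformed line %d (expected 2 tab-separated columns)",
          path, bad[1])
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("human", "mouse") %in% colnames(tbl)))
    stopf("readOrthologTable: %s: header must name columns 'human' and 'mouse'",
          path)
  tbl
}

#' Serialize / deserialize a consensus signature
#'
#' JSON form: `{modality, intercept, fold_count, weights: {feature: weight},
#' provenance}`; the optional TSV form has columns `feature`, `weight`.
#' Round-trips are lossless (full double precision).
#'
#' @param signature a [ConsensusSignature-class].
#' @param json_path JSON output path.
#' @param tsv_path optional two-column TSV output path.
#' @export
writeSignature <- function(signature, json_path, tsv_path = NULL) {
  obj <- list(modality = signature@modality,
              intercept = signature@intercept,
              fold_count = signature@foldCount,
              weights = as.list(signature@weights),
              provenance = signature@provenance)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  if (!is.null(tsv_path))
    write.table(data.frame(feature = names(signature@weights),
                           weight = unname(signature@weights)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ConsensusSignature(weights = unlist(obj$weights),
                     intercept = obj$intercept,
                     modality = obj$modality,
                     foldCount = obj$fold_count %||% NA_integer_,
                     provenance = as.list(obj$provenance))
}
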