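#' Surrogate differential expression for one senescence model
#'
#' A simple two-arm test intended for synthetic data and for exercising the
#' catalog rules: per feature, `log2_fc = log2((mean_sen + 1)/(mean_ctrl + 1))`,
#' a Welch two-sample t-test on `log2(x + 1)` values, and Benjamini-Hochberg
#' adjustment across features.  Catalogs built from real data should load the
#' dedicated differential-expression tables (e.g. DESeq2 output) via
#' [readDETable()] instead.  Protein features with more than 50% missing
#' values in either arm are dropped.
#'
#' @param x a [SenExperiment-class].
#' @param cell_type,trigger select the senescence model; `NULL` uses all
#'   samples (one pooled model).
#' @return A `data.frame` (DETable) with columns `feature`, `log2_fc`,
#'   `p_value`, `adj_p`, `base_sen`, `base_ctrl`.
#' @export
simpleDE <- function(x, cell_type = NULL, trigger = NULL) {
  stopifnot(is(x, "SenExperiment"))
  cd <- colData(x)
  keep <- rep(TRUE, ncol(x))
  if (!is.null(cell_type)) keep <- keep & cd$cell_type == cell_type
  if (!is.null(trigger)) keep <- keep & cd$trigger == trigger
  v <- assay(x)[, keep, drop = FALSE]
  st <- cd$state[keep]
  if (sum(st == "senescent") < 2L)
    stopf("simpleDE: senescent arm has fewer than 2 samples")
  if (sum(st == "control") < 2L)
    stopf("simpleDE: control arm has fewer than 2 samples")
  sen <- v[, st == "senescent", drop = FALSE]
  ctl <- v[, st == "control", drop = FALSE]

  if (identical(metadata(x)$modality, "protein")) {
    fr_sen <- rowMeans(is.na(sen))
    fr_ctl <- rowMeans(is.na(ctl))
    keepf <- fr_sen <= 0.5 & fr_ctl <= 0.5
    sen <- sen[keepf, , drop = FALSE]
    ctl <- ctl[keepf, , drop = FALSE]
  }
  m_sen <- rowMeans(sen, na.rm = TRUE)
  m_ctl <- rowMeans(ctl, na.rm = TRUE)
  lfc <- log2((m_sen + 1) / (m_ctl + 1))
  p <- rowWelchP(log2(sen + 1), log2(ctl + 1))
  data.frame(feature = rownames(sen), log2_fc = lfc, p_value = p,
             adj_p = p.adjust(p, method = "BH"),
             base_sen = m_sen, base_ctrl = m_ctl, row.names = NULL)
}

#' Call per-model marker sets from a differential-expression table
#'
#' Up markers satisfy `p < max_p` and `log2_fc >= min_abs_log2fc`; down
#' markers `p < max_p` and `log2_fc <= -min_abs_log2fc`.  For RNA an
#' abundance floor applies: up markers must exceed `expression_floor`
#' normalized counts in the senescent arm, down markers in the control arm
#' (the arm where the transcript is abundant; `floor_mode = "literal"`
#' instead requires down markers *below* the floor in the control arm).
#'
#' @param de a DETable as returned by [simpleDE()] or [readDETable()].
#' @param thresholds a [markerThresholds()] object.
#' @param modality `"RNA"` or `"protein"` (no floor for protein).
#' @param cell_type,trigger model key recorded on the returned sets.
#' @return A list with `up` and `down` [MarkerSet-class] objects.
#' @export
callModelMarkers <- function(de, thresholds = markerThresholds(),
                             modality = c("RNA", "protein"),
                             cell_type = "NA", trigger = "NA") {
  if (!is.character(modality) || !all(modality %in% c("RNA", "protein")))
    stopf("callModelMarkers: unknown modality '%s'", paste(modality, collapse = ","))
  modality <- match.arg(modality)
  stopifnot(all(c("feature", "log2_fc", "p_value") %in% colnames(de)))
  if (anyDuplicated(de$feature)) stopf("callModelMarkers: duplicated features")
  sig <- !is.na(de$p_value) & de$p_value < thresholds$max_p
  up <- sig & de$log2_fc >= thresholds$min_abs_log2fc
  down <- sig & de$log2_fc <= -thresholds$min_abs_log2fc
  if (modality == "RNA") {
    up <- up & de$base_sen > thresholds$expression_floor
    down <- if (thresholds$floor_mode == "literal")
      down & de$base_ctrl < thresholds$expression_floor
    else
      down & de$base_ctrl > thresholds$expression_floor
  }
  list(up = MarkerSet(cell_type, trigger, modality, "up", de$feature[up]),
       down = MarkerSet(cell_type, trigger, modality, "down", de$feature[down]))
}

#' Intersect per-trigger marker sets into a cell-type marker set
#'
#' A cell-type marker must be present in the marker list of every senescence
#' model (trigger) profiled for that cell type.
#'
#' @param sets list of [MarkerSet-class] with a common cell type and direction.
#' @return A [MarkerSet-class] with `trigger = "ALL"`.
#' @export
intersectTriggers <- function(sets) {
  stopifnot(length(sets) >= 1L)
  cts <- unique(vapply(sets, function(s) s@cellType, character(1)))
  dirs <- unique(vapply(sets, function(s) s@direction, character(1)))
  if (length(cts) != 1L)
    stopf("intersectTriggers: mixed cell types (%s)", paste(cts, collapse = ", "))
  if (length(dirs) != 1L)
    stopf("intersectTriggers: mixed directions (%s)", paste(dirs, collapse = ", "))
  feats <- Reduce(intersect, lapply(sets, function(s) s@features))
  MarkerSet(cts, "ALL", sets[[1]]@modality, dirs, feats)
}

#' Tabulate marker sharing across cell types
#'
#' @param celltype_sets list of cell-type [MarkerSet-class] objects (one per
#'   cell type, a common direction).
#' @return A `data.frame` with columns `feature`, `n_cell_types`,
#'   `cell_types` (comma-separated) and `direction`, sorted by sharing count.
#' @export
sharingTable <- function(celltype_sets) {
  cts <- vapply(celltype_sets, function(s) s@cellType, character(1))
  if (anyDuplicated(cts))
    stopf("sharingTable: duplicate cell-type keys (%s)",
          paste(cts[duplicated(cts)], collapse = ", "))
  dirs <- unique(vapply(celltype_sets, function(s) s@direction, character(1)))
  if (length(dirs) != 1L) stopf("sharingTable: mixed directions")
  long <- data.frame(
    feature = unlist(lapply(celltype_sets, function(s) s@features)),
    cell_type = rep(cts, vapply(celltype_sets, function(s) length(s@features),
                                integer(1))))
  if (!nrow(long))
    return(data.frame(feature = character(), n_cell_types = integer(),
                      cell_types = character(), direction = character()))
  agg <- lapply(split(long$cell_type, long$feature), sort)
  out <- data.frame(feature = names(agg),
                    n_cell_types = lengths(agg),
                    cell_types = vapply(agg, paste, character(1), collapse = ","),
                    direction = dirs, row.names = NULL)
  out[order(-out$n_cell_types, out$feature), , drop = FALSE]
}

#' Top shared markers, ranked by number of cell types
#'
#' Ties are broken by summed absolute log2 fold change across contributing
#' models (when supplied), then by identifier.
#'
#' @param table output of [sharingTable()].
#' @param k list length (default 20).
#' @param effect optional named numeric: per-feature summed |log2_fc| across
#'   contributing models, used as the tie-break.
#' @param min_cell_types optional minimum sharing count filter (e.g. 4).
#' @return Character vector of up to `k` features.
#' @export
topShared <- function(table, k = 20L, effect = NULL, min_cell_types = NULL) {
  if (k <= 0) stopf("topShared: k must be > 0")
  if (!nrow(table)) stopf("topShared: empty sharing table")
  if (!is.null(min_cell_types))
    table <- table[table$n_cell_types >= min_cell_types, , drop = FALSE]
  e <- if (is.null(effect)) rep(0, nrow(table)) else {
    v <- effect[table$feature]; v[is.na(v)] <- 0; abs(v)
  }
  ord <- order(-table$n_cell_types, -e, table$feature)
  head(table$feature[ord], k)
}

#' Top cell-type markers, ranked by summed log2 fold change
#'
#' Within one cell type, markers are ranked by the sum of their log2 fold
#' changes over that cell type's senescence models: descending for up
#' markers, ascending for down markers.
#'
#' @param de_tables list of DETables, one per senescence model of the cell type.
#' @param markers a cell-type [MarkerSet-class].
#' @param k list length (default 20).
#' @return A `data.frame` with columns `feature` and `sum_log2_fc`, ranked.
#' @export
topCellTypeMarkers <- function(de_tables, markers, k = 20L) {
  feats <- markers@features
  sums <- rep(0, length(feats)); names(sums) <- feats
  for (i in seq_along(de_tables)) {
    de <- de_tables[[i]]
    miss <- setdiff(feats, de$feature)
    if (length(miss))
      stopf("topCellTypeMarkers: feature '%s' missing from DE table %d",
            miss[1], i)
    sums <- sums + de$log2_fc[match(feats, de$feature)]
  }
  ord <- if (markers@direction == "down") order(sums, feats)
         else order(-sums, feats)
  head(data.frame(feature = feats[ord], sum_log2_fc = sums[ord],
                  row.names = NULL), k)
}

#' Overlap between transcriptomic and proteomic marker sets
#'
#' Reports both the Jaccard percentage (`|A \/\ B| / |A \\/ B| * 100`) and the
#' min-denominator percentage (`|A \/\ B| / min(|A|, |B|) * 100`); an empty
#' union yields 0 for both.
#'
#' @param rna_set,protein_set character vectors on a shared gene-symbol
#'   namespace (or [MarkerSet-class] objects).
#' @return A list with `intersection`, `jaccard_pct` and `min_pct`.
#' @export
modalityOverlap <- function(rna_set, protein_set) {
  a <- if (is(rna_set, "MarkerSet")) rna_set@features else unique(rna_set)
  b <- if (is(protein_set, "MarkerSet")) protein_set@features else unique(protein_set)
  i <- intersect(a, b); u <- union(a, b)
  list(intersection = i,
       jaccard_pct = if (length(u)) 100 * length(i) / length(u) else 0,
       min_pct = if (length(u)) 100 * length(i) / min(length(a), length(b)) else 0)
}

#' Expand a human gene set to mouse orthologs
#'
#' Includes all available mappings (1:1, 1:many and many:many).  Input
#' symbols without any mapping row are reported, not an error.
#'
#' @param features character vector of human symbols.
#' @param table ortholog table with columns `human` and `mouse` (see
#'   [makeOrthologTable()] / [readOrthologTable()]).
#' @return A list with `mouse` (deduplicated union of targets) and
#'   `unmapped` (input symbols with no mapping).
#' @export
expandOrthologs <- function(features, table) {
  if (!all(c("human", "mouse") %in% colnames(table)))
    stopf("expandOrthologs: table must have columns 'human' and 'mouse'")
  tbl <- table[!is.na(table$mouse) & nzchar(table$mouse), , drop = FALSE]
  hit <- tbl[tbl$human %in% features, , drop = FALSE]
  list(mouse = unique(hit$mouse),
       unmapped = setdiff(features, hit$human))
}

#' Build expanded marker lists for in-situ scoring
#'
#' Emits `Allsenshared` (features shared by at least `sharing_cutoff` cell
#' types, computed by intersecting each cell type's trigger lists) and, per
#' caller-supplied lineage grouping, the top `top_n` features ranked by the
#' number of senescence models containing them (ties by summed |log2_fc| when
#' `effect` is given, then identifier).
#'
#' @param model_sets list of per-model [MarkerSet-class] objects (one
#'   direction).
#' @param lineages named list: lineage -> character vector of cell types.
#' @param sharing_cutoff minimum cell types for `Allsenshared` (default 4).
#' @param top_n per-lineage list length (default 500).
#' @param effect optional named numeric tie-break (summed |log2_fc|).
#' @return Named list of character vectors, `Allsenshared` first.
#' @export
expandedLists <- function(model_sets, lineages = list(), sharing_cutoff = 4L,
                          top_n = 500L, effect = NULL) {
  keys <- vapply(model_sets, function(s) s@cellType, character(1))
  by_ct <- split(model_sets, keys)
  ct_sets <- lapply(by_ct, intersectTriggers)
  shar <- sharingTable(unname(ct_sets))
  all_shared <- if (nrow(shar))
    shar$feature[shar$n_cell_types >= sharing_cutoff] else character()
  out <- list(Allsenshared = all_shared)
  for (ln in names(lineages)) {
    cts <- lineages[[ln]]
    if (!all(cts %in% keys))
      stopf("expandedLists: unknown cell types in lineage '%s': %s", ln,
            paste(setdiff(cts, keys), collapse = ", "))
    sub <- model_sets[keys %in% cts]
    counts <- table(unlist(lapply(sub, function(s) s@features)))
    feats <- names(counts)
    e <- if (is.null(effect)) rep(0, length(feats)) else {
      v <- abs(effect[feats]); v[is.na(v)] <- 0; v
    }
    ord <- order(-as.integer(counts), -e, feats)
    out[[ln]] <- head(feats[ord], top_n)
  }
  out
}
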