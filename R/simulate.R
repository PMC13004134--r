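#' Simulate a bulk senescence corpus with planted markers
#'
#' Generates a multi-cell-type, multi-trigger bulk corpus: RNA counts are
#' negative-binomial around log-normal per-feature baselines, multiplied by
#' `2^effect_log2` (sign per direction) in senescent samples for planted
#' features, then library-size-normalized to a common target sum; protein
#' values are log-normal intensities carrying the same kind of planted
#' effects, with missing values concentrated in a sporadically-detected
#' subset of proteins so the overall missing fraction equals
#' `protein_missing_frac`.  Cell-type-specific planted features are perturbed
#' only in their own cell type (half up, half down).  Deterministic under
#' `config$seed`.
#'
#' Planted features are drawn from baselines above the 40th percentile:
#' catalog rules apply an abundance floor, and senescence markers in real
#' corpora are expressed genes.
#'
#' @param config a [bulkSimConfig()] object.
#' @return A list with elements `rna` and `protein` ([SenExperiment-class])
#'   and `truth`, a per-modality list of `planted_shared_up`,
#'   `planted_shared_down`, `planted_type_specific` (cell type -> features)
#'   and `effects` (feature -> signed log2 effect).
#' @examples
#' sim <- makeBulkDataset(bulkSimConfig(n_cell_types = 3, n_features_rna = 300,
#'                                      n_features_protein = 200,
#'                                      n_type_specific = 10, seed = 7))
#' sim$rna
#' @export
makeBulkDataset <- function(config = bulkSimConfig()) {
  stopifnot(inherits(config, "BulkSimConfig"))
  withSeed(substreamSeed(config$seed, "bulk"), {
    cts <- sprintf("CT%02d", seq_len(config$n_cell_types))
    trig_pool <- c("CTIS", "IRIS", "OSIS", "OIS")
    triggers <- lapply(cts, function(ct) {
      k <- sample(seq(config$triggers_min, config$triggers_max), 1L)
      sample(trig_pool, k)
    })
    names(triggers) <- cts

    arms <- do.call(rbind, lapply(cts, function(ct) {
      do.call(rbind, lapply(triggers[[ct]], function(tr) {
        expand.grid(cell_type = ct, trigger = tr,
                    state = c("control", "senescent"),
                    rep = seq_len(config$replicates_per_arm),
                    stringsAsFactors = FALSE)
      }))
    }))
    arms$sample <- sprintf("%s_%s_%s_%d", arms$cell_type, arms$trigger,
                           ifelse(arms$state == "senescent", "sen", "ctl"),
                           arms$rep)
    n_samp <- nrow(arms)

    plantModality <- function(feat, w_expressed) {
      eligible <- feat[w_expressed]
      picked <- sample(eligible,
                       config$n_shared_up + config$n_shared_down +
                         config$n_cell_types * config$n_type_specific)
      up <- picked[seq_len(config$n_shared_up)]
      down <- picked[config$n_shared_up + seq_len(config$n_shared_down)]
      rest <- picked[-seq_len(config$n_shared_up + config$n_shared_down)]
      ts <- split(rest, rep(cts, each = config$n_type_specific))
      n_up <- ceiling(config$n_type_specific / 2)
      eff <- c(rep(config$effect_log2, config$n_shared_up),
               rep(-config$effect_log2, config$n_shared_down))
      names(eff) <- c(up, down)
      for (ct in cts) {
        g <- ts[[ct]]
        e <- rep(c(config$effect_log2, -config$effect_log2),
                 c(n_up, length(g) - n_up))
        names(e) <- g
        eff <- c(eff, e)
      }
      list(planted_shared_up = up, planted_shared_down = down,
           planted_type_specific = ts[cts], effects = eff)
    }

    # per-sample signed log2 effect matrix for the planted features
    effectMatrix <- function(truth, feat) {
      E <- matrix(0, length(feat), n_samp, dimnames = list(feat, arms$sample))
      sen <- arms$state == "senescent"
      shared <- c(truth$planted_shared_up, truth$planted_shared_down)
      E[shared, sen] <- truth$effects[shared]
      for (ct in cts) {
        g <- truth$planted_type_specific[[ct]]
        idx <- sen & arms$cell_type == ct
        E[g, idx] <- truth$effects[g]
      }
      E
    }

    ## --- RNA: negative binomial counts, library-size normalized ---
    featR <- sprintf("G%05d", seq_len(config$n_features_rna))
    w <- rlnorm(config$n_features_rna, meanlog = 0, sdlog = 1)
    names(w) <- featR
    expressed <- w > quantile(w, 0.40)
    silent <- sample(which(!expressed), round(0.25 * sum(!expressed)))
    w[silent] <- w[silent] * 1e-3   # near-silent tail with frequent zeros
    truthR <- plantModality(featR, expressed)
    ER <- effectMatrix(truthR, featR)
    depth_factor <- rlnorm(n_samp, 0, 0.3)
    base_scale <- config$target_sum / sum(w)
    mu <- (w * base_scale) * 2^ER
    mu <- sweep(mu, 2, depth_factor, `*`)
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = 1 / config$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    norm <- sweep(counts, 2, config$target_sum / pmax(colSums(counts), 1), `*`)
    rna <- SenExperiment(norm, cell_type = arms$cell_type,
                         trigger = arms$trigger, state = arms$state,
                         modality = "RNA")

    ## --- protein: log-normal intensities with stratified missingness ---
    featP <- sprintf("G%05d", seq_len(config$n_features_protein))
    logint <- rnorm(config$n_features_protein, mean = log(1e6), sd = 1.5)
    names(logint) <- featP
    truthP <- plantModality(featP, rep(TRUE, length(featP)))
    EP <- effectMatrix(truthP, featP)
    noise <- matrix(rnorm(length(EP), 0, 0.25), nrow = nrow(EP))
    intens <- exp(logint + EP * log(2) + noise)
    dimnames(intens) <- dimnames(EP)
    if (config$protein_missing_frac > 0) {
      sporadic_frac <- 0.25
      rate <- config$protein_missing_frac / sporadic_frac
      if (rate > 0.9) { rate <- 0.9; sporadic_frac <- config$protein_missing_frac / 0.9 }
      sporadic <- sample(featP, round(sporadic_frac * length(featP)))
      drop <- matrix(runif(length(sporadic) * n_samp) < rate,
                     nrow = length(sporadic))
      intens[sporadic, ][drop] <- NA_real_
    }
    protein <- SenExperiment(intens, cell_type = arms$cell_type,
                             trigger = arms$trigger, state = arms$state,
                             modality = "protein")
    metadata(rna)$triggers <- metadata(protein)$triggers <- triggers
    list(rna = rna, protein = protein,
         truth = list(rna = truthR, protein = truthP, triggers = triggers,
                      config = config))
  })
}

#' Simulate a single-cell dataset with a planted senescent subpopulation
#'
#' Cells are assigned a cluster, a timepoint and a Bernoulli true-senescent
#' flag with the configured per-timepoint fraction.  Counts are multinomial
#' over log-normal gene weights (cluster-perturbed for cluster structure);
#' planted signature genes are up-weighted by `2^effect_log2` in true
#' senescent cells.  Per-cell totals follow the per-timepoint log-normal
#' depth distribution, whose mean increases with timepoint, planting a
#' depth-timepoint confound.  A tagged 5% mitochondrial gene subset carries
#' slightly elevated baseline weight.  Deterministic under `config$seed`.
#'
#' @param config an [scSimConfig()] object.
#' @return A [CellDataset-class] with a logical `true_senescent` colData
#'   column; `metadata(x)$truth` holds the planted signature genes and config.
#' @export
makeSCDataset <- function(config = scSimConfig()) {
  stopifnot(inherits(config, "SCSimConfig"))
  withSeed(substreamSeed(config$seed, "sc"), {
    n_mito <- max(1L, round(0.05 * config$n_genes))
    genes <- c(sprintf("mt-G%04d", seq_len(n_mito)),
               sprintf("G%04d", seq_len(config$n_genes - n_mito)))
    is_mito <- startsWith(genes, "mt-")
    w <- rlnorm(config$n_genes, 0, 1)
    w[is_mito] <- w[is_mito] * 2          # mito genes slightly elevated
    names(w) <- genes
    signature <- sample(genes[!is_mito], config$signature_size)

    cl_mult <- matrix(1, config$n_genes, config$n_clusters,
                      dimnames = list(genes, NULL))
    for (k in seq_len(config$n_clusters)) {
      idx <- sample(config$n_genes, round(0.1 * config$n_genes))
      cl_mult[idx, k] <- 1.5
    }

    nt <- length(config$timepoints)
    cols <- vector("list", nt)
    meta <- vector("list", nt)
    for (i in seq_len(nt)) {
      n <- config$cells_per_timepoint
      cl <- sample(config$n_clusters, n, replace = TRUE)
      sen <- runif(n) < config$senescent_frac_by_timepoint[i]
      depth <- pmax(300L, as.integer(round(
        rlnorm(n, config$depth_meanlog[i], config$depth_sdlog[i]))))
      cnt <- matrix(0L, config$n_genes, n)
      for (j in seq_len(n)) {
        wj <- w * cl_mult[, cl[j]]
        if (sen[j]) wj[signature] <- wj[signature] * 2^config$effect_log2
        cnt[, j] <- rmultinom(1, depth[j], wj)
      }
      cols[[i]] <- cnt
      meta[[i]] <- data.frame(cluster = paste0("cluster", cl),
                              condition = config$timepoints[i],
                              true_senescent = sen)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    meta <- do.call(rbind, meta)
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
    cds <- CellDataset(counts, cluster = meta$cluster,
                       condition = meta$condition, is_mito = is_mito,
                       true_senescent = meta$true_senescent)
    metadata(cds)$truth <- list(signature = signature, config = config)
    cds
  })
}

#' Generate a synthetic human-to-mouse ortholog table
#'
#' Two-column mapping with 1:1, 1:many and many:many blocks.  Some human
#' symbols in the accompanying universe (`attr(x, "human_universe")`) have no
#' mapping row at all.  Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @return A `data.frame` with columns `human` and `mouse`.
#' @export
makeOrthologTable <- function(seed = 1L) {
  withSeed(substreamSeed(seed, "ortho"), {
    human <- sprintf("HGENE%03d", seq_len(40L))
    rows <- list()
    # 1:1 block
    for (h in human[1:20]) rows[[h]] <- data.frame(human = h, mouse = tolower(h))
    # 1:many block
    for (h in human[21:28]) {
      k <- sample(2:3, 1L)
      rows[[h]] <- data.frame(human = h,
                              mouse = paste0(tolower(h), letters[seq_len(k)]))
    }
    # many:many block: shared mouse targets across human paralogs
    mm_mouse <- c("mfam001a", "mfam001b", "mfam001c")
    for (h in human[29:32]) {
      rows[[h]] <- data.frame(human = h, mouse = sample(mm_mouse, 2L))
    }
    # human[33:35] map 1:1 onto a shared family member too
    for (h in human[33:35]) rows[[h]] <- data.frame(human = h, mouse = "mfam001a")
    # human[36:40] deliberately have no mapping rows (unmapped)
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    attr(tbl, "human_universe") <- human
    tbl
  })
}
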