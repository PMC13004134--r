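suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
  library(Matrix)
})

# Shared fixtures, built in code.  Expensive default-scale objects are cached
# for the session so several test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small hand-sized bulk experiment: 2 cell types x 2 triggers, 3+3 samples
tinyBulk <- function(seed = 1) {
  withr::with_seed(seed, {
    n_feat <- 60
    feats <- sprintf("G%03d", seq_len(n_feat))
    arms <- expand.grid(rep = 1:3, state = c("control", "senescent"),
                        trigger = c("CTIS", "IRIS"),
                        cell_type = c("CTA", "CTB"),
                        stringsAsFactors = FALSE)
    mu <- rlnorm(n_feat, log(2000), 0.7)
    v <- sapply(seq_len(nrow(arms)), function(j) {
      m <- mu
      if (arms$state[j] == "senescent") m[1:10] <- m[1:10] * 4
      rnbinom(n_feat, mu = m, size = 20)
    })
    dimnames(v) <- list(feats, sprintf("s%02d", seq_len(ncol(v))))
    SenExperiment(v, arms$cell_type, arms$trigger, arms$state, "RNA")
  })
}

# small single-cell dataset for fast unit tests
smallSC <- function(seed = 1, ...) {
  makeSCDataset(scSimConfig(n_genes = 400, cells_per_timepoint = 150,
                            signature_size = 40, seed = seed, ...))
}

defaultBulkSim <- function() cached("bulk_default", makeBulkDataset(bulkSimConfig(seed = 101)))

defaultSCRun <- function() cached("sc_run_default", {
  cds <- makeSCDataset(scSimConfig(seed = 202))
  truth <- S4Vectors::metadata(cds)$truth
  noise <- withr::with_seed(9000, sample(setdiff(rownames(cds), truth$signature), 50))
  res <- runInsituPipeline(cds, c(truth$signature, noise), "Day0", seed = 202)
  list(cds = cds, truth = truth, res = res)
})

# brute-force recovery-curve oracle: explicit R(k) construction per cell
bruteRecoveryAUC <- function(expr_vec, set, top_frac) {
  n <- length(expr_vec)
  ord <- order(-expr_vec)            # distinct values assumed: no ties
  T_ <- max(1L, floor(top_frac * n))
  m <- min(length(intersect(set, names(expr_vec))), T_)
  Rk <- numeric(T_)
  hits <- 0
  for (k in seq_len(T_)) {
    if (names(expr_vec)[ord[k]] %in% set) hits <- hits + 1
    Rk[k] <- hits
  }
  denom <- sum(pmin(seq_len(T_), m))
  sum(Rk) / denom
}

# construct a CellDataset with prescribed per-cell n_feature / n_count /
# pct_mito: ten mito genes carry the mito counts, a block of non-mito genes
# carries the rest
qcExampleDataset <- function() {
  n_genes <- 12000
  genes <- c(sprintf("mt-G%03d", 1:100), sprintf("G%05d", 1:(n_genes - 100)))
  cellCounts <- function(n_feature, total, mito_frac) {
    x <- rep(0, n_genes)
    mt <- round(total * mito_frac)
    x[1:10] <- c(rep(floor(mt / 10), 9), mt - 9 * floor(mt / 10))
    k <- n_feature - 10
    rest <- total - mt
    x[100 + seq_len(k)] <- floor(rest / k)
    x[101] <- x[101] + rest - k * floor(rest / k)
    x
  }
  m <- cbind(low_features = cellCounts(150, 3000, 0.05),
             good = cellCounts(5000, 20000, 0.10),
             high_umi = cellCounts(5000, 30000, 0.05),
             high_mito = cellCounts(1000, 5000, 0.30))
  rownames(m) <- genes
  CellDataset(Matrix::Matrix(m, sparse = TRUE),
              cluster = rep("c1", 4), condition = rep("Day0", 4))
}

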