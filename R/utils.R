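#' @importFrom stats quantile rnbinom rlnorm rbinom rmultinom runif rnorm
#'   t.test wilcox.test p.adjust lm resid predict glm binomial coef sd
#'   complete.cases cor median
#' @importFrom utils head read.delim write.table modifyList
NULL

# Deterministic per-stage seed derived from one root seed, so pipeline stages
# can be rerun in isolation without sharing an RNG stream.  Kept < 2^31.
substreamSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2003L + h) %% .Machine$integer.max
}

# run code under a local RNG state (does not disturb the caller's stream)
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mann-Whitney AUROC of scores for a binary label (TRUE = positive class);
# used for per-fold run reports only.
rankAUC <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# vectorised one-way F statistic (two groups) per row of a matrix
rowFStat <- function(x, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  n <- ncol(x)
  idx <- split(seq_len(n), group)
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]])
  m1 <- rowMeans(x[, idx[[1]], drop = FALSE])
  m2 <- rowMeans(x[, idx[[2]], drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x[, idx[[1]], drop = FALSE] - m1)^2) +
    rowSums((x[, idx[[2]], drop = FALSE] - m2)^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- msb / msw
  f[msw == 0 & msb == 0] <- 0
  f[msw == 0 & msb > 0] <- Inf
  f
}

# Row-wise Welch two-sample t-test p-values (vectorized t.test equivalent;
# NA entries excluded per row).  Degenerate rows with zero variance in both
# arms get p = 1 when the means agree, p = 0 otherwise.
rowWelchP <- function(a, b) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(abs(m1[zero] - m2[zero]) < 1e-12, 1, 0)
  p[n1 < 2L | n2 < 2L] <- NA_real_
  unname(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
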