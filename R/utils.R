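# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a global seed. Kept below 2^31
# so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

# Run code under a temporary RNG state restored afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# cells x genes sparse matrix coercion with dimension name checks.
as_umi_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  m <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

stopifnot_counts <- function(counts) {
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    abort("UMI matrix must contain non-negative integer counts.")
  }
  invisible(counts)
}

# Vectorised two-sided Wilcoxon rank-sum over the columns of a dense matrix
# (cells in rows). Normal approximation with mid-ranks and tie correction,
# no continuity correction; used for per-gene DE where exactness is not
# required. Returns list(stat = W for side A, p).
rank_sum_matrix <- function(mat, idx_a, idx_b) {
  n1 <- length(idx_a)
  n2 <- length(idx_b)
  n <- n1 + n2
  sub <- mat[c(idx_a, idx_b), , drop = FALSE]
  stats_w <- numeric(ncol(sub))
  pvals <- numeric(ncol(sub))
  mu <- n1 * n2 / 2
  for (j in seq_len(ncol(sub))) {
    r <- rank(sub[, j])
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(sub[, j])
    tie_adj <- sum(nt^3 - nt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_adj)
    z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
    stats_w[j] <- w
    pvals[j] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(stat = stats_w, p = pvals)
}
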