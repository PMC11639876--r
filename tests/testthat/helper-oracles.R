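# Independent oracles used to verify the statistical primitives. These are
# deliberately naive (enumeration, O(m^2) scans, direct transcription of the
# trim-and-weight formula) and share no code with the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all C(m+n, m)
# assignments of the pooled values to group A (assumes no ties).
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  idx <- utils::combn(length(pooled), m)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(idx, 2, u_of)
  mu <- m * length(b) / 2
  # two-sided: arrangements at least as extreme in |U - mn/2|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Naive O(m^2) Benjamini-Hochberg step-up.
bh_naive_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  fdr <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in seq_len(m)) {
      # min over positions j >= i in the sorted order
      if (j >= i) vals <- c(vals, p[ord[j]] * m / j)
    }
    fdr[ord[i]] <- min(1, min(vals))
  }
  fdr
}

# Brute-force TMM: direct transcription of the trim-and-weight definition.
# Reference = unit whose upper-quartile count fraction is nearest the mean;
# 30% two-sided trim on M, 5% on A (rank-based), inverse binomial-variance
# weights, geometric-mean recentering.
tmm_oracle <- function(x, ref_unit = NULL) {
  lib <- colSums(x)
  if (is.null(ref_unit)) {
    uq <- apply(x, 2, function(col) stats::quantile(col / sum(col), 0.75))
    ref_unit <- colnames(x)[which.min(abs(uq - mean(uq)))]
  }
  ref <- x[, ref_unit]
  nR <- lib[ref_unit]
  f <- sapply(colnames(x), function(u) {
    obs <- x[, u]; nO <- lib[u]
    M <- log2((obs / nO) / (ref / nR))
    A <- (log2(obs / nO) + log2(ref / nR)) / 2
    w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
    ok <- is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    keepM <- rank(M) >= floor(0.3 * n) + 1 & rank(M) <= n - floor(0.3 * n)
    keepA <- rank(A) >= floor(0.05 * n) + 1 & rank(A) <= n - floor(0.05 * n)
    keep <- keepM & keepA
    if (!any(keep)) return(1)
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  })
  f / exp(mean(log(f)))
}

# Random small count matrix for oracle comparisons.
random_count_matrix <- function(n_genes = 50, n_units = 4) {
  x <- matrix(rnbinom(n_genes * n_units, mu = exp(runif(n_genes, 1, 6)),
                      size = 5),
              n_genes, n_units,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("u%02d", seq_len(n_units))))
  # ensure positive library sizes
  x[1, ] <- x[1, ] + 1
  x
}

# A scaled-down module layout (same seven patterns, ~8x fewer genes) for
# small-cohort unit tests where the full 357-gene layout would not fit.
small_modules <- function() {
  data.frame(pattern = module_patterns(),
             up = c(0L, 4L, 2L, 1L, 4L, 10L, 3L),
             down = c(2L, 3L, 1L, 4L, 1L, 0L, 12L),
             stringsAsFactors = FALSE)
}
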