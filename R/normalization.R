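# Between-sample and within-sample normalization:
#   raw counts -> TMM factors -> log2 CPM (effective library sizes, scaled
#   pseudo-count) -> control-gene subtraction -> per-feature z-scaling.
# The control-gene step is what makes the classifier's features robust to
# platform/batch shifts: any per-sample global shift of log2 CPM cancels in
# the subtraction.

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes one scaling factor per unit as the weighted mean of gene-wise
#' log2 expression ratios (M-values) against a reference unit, after trimming
#' the top and bottom 30% of M-values and 5% of average log expression
#' (A-values); weights are the inverse asymptotic binomial variances.
#' Factors are recentered so their geometric mean is 1. When no reference is
#' given, the unit whose upper-quartile count fraction is closest to the mean
#' upper quartile is used.
#'
#' @param counts Count matrix (at least two units, positive library sizes).
#' @param ref_unit Optional reference unit id.
#' @param trim_m,trim_a Trim fractions for M- and A-values (defaults 0.30, 0.05).
#' @return Data.frame of class `ov_normfactors` with columns `unit_id`,
#'   `library_size`, `tmm_factor` (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_unit = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as_count_input(counts)
  x <- unclass(counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 units")
  lib <- colSums(x)
  if (is.null(ref_unit)) {
    uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_unit <- colnames(x)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_unit %in% colnames(x)) stop("ref_unit '", ref_unit, "' not found")
  ref <- x[, ref_unit]
  nR <- lib[ref_unit]
  f <- vapply(colnames(x), function(u) {
    tmm_pair_factor(x[, u], ref, lib[u], nR, trim_m = trim_m, trim_a = trim_a,
                    unit = u)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(data.frame(unit_id = colnames(x), library_size = lib,
                       tmm_factor = as.numeric(f), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("ov_normfactors", "data.frame"))
}

# One column's TMM factor against the reference (not recentered).
tmm_pair_factor <- function(obs, ref, nO, nR, trim_m = 0.30, trim_a = 0.05,
                            unit = "?") {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  keep <- is.finite(logR) & is.finite(absE)
  logR <- logR[keep]; absE <- absE[keep]; v <- v[keep]
  if (length(logR) == 0) {
    warning("unit '", unit, "' shares no co-expressed gene with the reference; ",
            "TMM factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(logR); rA <- rank(absE)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) {
    warning("unit '", unit, "' has no genes left after trimming; ",
            "TMM factor set to 1")
    return(1)
  }
  2^(sum(logR[sel] / v[sel]) / sum(1 / v[sel]))
}

#' Log2 counts per million with effective library sizes
#'
#' `log2((count + p) / (eff_lib + 2 p) * 1e6)` where the effective library
#' size is `library_size * tmm_factor` and the pseudo-count `p` is the prior
#' scaled proportionally to each unit's effective library size (so the
#' zero-count floor is the same for every unit).
#'
#' @param counts Count matrix.
#' @param factors Optional [tmm_factors()] result aligned to `counts`; `NULL`
#'   means all factors 1 (plain CPM — the per-cell/per-spot convention).
#' @param prior_count Pseudo-count before library-size scaling (default 2).
#' @return Numeric genes-by-units matrix of log2 CPM values (finite everywhere).
#' @export
log2cpm <- function(counts, factors = NULL, prior_count = 2) {
  counts <- as_count_input(counts)
  x <- unclass(counts)
  lib <- colSums(x)
  if (is.null(factors)) {
    eff <- lib
  } else {
    idx <- match(colnames(x), factors$unit_id)
    if (anyNA(idx)) stop("factors not aligned to counts")
    eff <- lib * factors$tmm_factor[idx]
  }
  prior <- prior_count * eff / mean(eff)
  y <- sweep(x, 2, prior, "+")
  y <- sweep(y, 2, eff + 2 * prior, "/")
  log2(y * 1e6)
}

#' Control-gene per-sample normalization
#'
#' Subtracts the control gene's log2 CPM from every signature gene's log2 CPM
#' within each unit, yielding features that are invariant to per-unit global
#' expression shifts. One such feature matrix per control gene feeds one
#' classifier channel.
#'
#' @param expr Log2 CPM matrix (genes by units).
#' @param panel Signature panel (see [build_panel()]) or a character vector of
#'   signature gene ids.
#' @param control_gene Control gene id, present in `expr`.
#' @return Numeric matrix (signature genes by units).
#' @export
control_normalize <- function(expr, panel, control_gene) {
  genes <- if (is.character(panel)) panel else panel$genes$gene
  missing <- setdiff(c(genes, control_gene), rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ", paste(missing, collapse = ", "))
  sweep(expr[genes, , drop = FALSE], 2, expr[control_gene, ], "-")
}

#' Fit and apply per-feature z-scaling
#'
#' Means and (sample) standard deviations are estimated on the training units
#' only and applied identically to any future unit.
#'
#' @param features Numeric features-by-units matrix.
#' @param train_ids Unit ids (columns of `features`) to estimate on.
#' @return `fit_scaling`: list of class `ov_scaling` with `mean` and `sd`
#'   vectors; `apply_scaling`: the z-scored feature matrix.
#' @export
fit_scaling <- function(features, train_ids = colnames(features)) {
  if (length(train_ids) < 2) stop("need at least 2 training units to fit scaling")
  missing <- setdiff(train_ids, colnames(features))
  if (length(missing)) stop("unknown training unit(s): ", paste(missing, collapse = ", "))
  tr <- features[, train_ids, drop = FALSE]
  m <- rowMeans(tr)
  s <- apply(tr, 1, stats::sd)
  const <- rownames(tr)[s == 0 | !is.finite(s)]
  if (length(const))
    stop("constant feature(s) among training units: ",
         paste(const, collapse = ", "))
  structure(list(mean = m, sd = s), class = "ov_scaling")
}

#' @rdname fit_scaling
#' @param stats An `ov_scaling` object from [fit_scaling()].
#' @export
apply_scaling <- function(features, stats) {
  stopifnot(inherits(stats, "ov_scaling"))
  if (!identical(rownames(features), names(stats$mean)))
    features <- features[names(stats$mean), , drop = FALSE]
  (features - stats$mean) / stats$sd
}
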