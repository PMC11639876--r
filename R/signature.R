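# Signature construction: union of DE genes over the ten designs, a
# multi-dataset expression filter, assignment of each candidate gene to one of
# the four subtype bipartitions (D vs Other, DI vs MP, DM vs IP, DP vs IM)
# with an up/down direction, and selection of stable high-expression control
# genes for the per-sample normalization.

new_panel <- function(genes, controls, provenance = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "module", "direction") %in% colnames(genes)))
  if (length(intersect(genes$gene, controls)))
    stop("control genes overlap signature genes: ",
         paste(intersect(genes$gene, controls), collapse = ", "))
  if (anyDuplicated(genes$gene)) stop("duplicate signature gene(s)")
  bad <- setdiff(unique(genes$module), bipartition_names())
  if (length(bad)) stop("unknown module(s): ", paste(bad, collapse = ", "))
  structure(list(genes = genes, controls = as.character(controls),
                 provenance = provenance),
            class = "ov_panel")
}

#' @export
print.ov_panel <- function(x, ...) {
  cat(sprintf("ov_panel: %d signature genes, %d control genes (%s)\n",
              nrow(x$genes), length(x$controls),
              paste(x$controls, collapse = ", ")))
  print(table(module = x$genes$module, direction = x$genes$direction))
  invisible(x)
}

#' The four subtype bipartitions, in table order
#'
#' @return Character vector of module names.
#' @export
bipartition_names <- function() c("DvsOther", "DIvsMP", "DMvsIP", "DPvsIM")

bipartition_sides <- function() {
  list(DvsOther = list(a = "D", b = c("I", "M", "P")),
       DIvsMP   = list(a = c("D", "I"), b = c("M", "P")),
       DMvsIP   = list(a = c("D", "M"), b = c("I", "P")),
       DPvsIM   = list(a = c("D", "P"), b = c("I", "M")))
}

#' Union of DE genes across designs
#'
#' @param results List of `ov_de` results (normally all 10 designs).
#' @return Character vector of genes flagged DE in at least one design, in
#'   gene-universe order of the first result.
#' @export
union_de_genes <- function(results) {
  stopifnot(length(results) >= 1)
  flagged <- unique(unlist(lapply(results, function(r) r$gene[r$is_de])))
  intersect(results[[1]]$gene, flagged)
}

#' Detection-based expression mask
#'
#' Genes with a nonzero count in at least `min_detect_fraction` of units.
#' Used to keep only signature candidates that are also expressed in the
#' auxiliary (bulk, single-cell, spatial) datasets.
#'
#' @param counts Count matrix of the dataset.
#' @param min_detect_fraction Fraction in (0, 1].
#' @return Character vector of gene ids passing the mask.
#' @export
expression_mask <- function(counts, min_detect_fraction) {
  stopifnot(min_detect_fraction > 0, min_detect_fraction <= 1)
  counts <- as_count_input(counts)
  x <- unclass(counts)
  rownames(x)[rowMeans(x > 0) >= min_detect_fraction]
}

#' Assign candidate genes to bipartition modules
#'
#' For each gene, the four bipartition contrasts are computed on the log2 CPM
#' matrix (group mean difference and Mann-Whitney p on the bipartition split);
#' the gene is assigned to the bipartition with the smallest p (ties broken by
#' largest absolute fold change, then by table order), with direction `up`
#' when the first-listed side is higher. Genes with no bipartition significant
#' at `alpha` are dropped.
#'
#' @param genes Candidate gene ids.
#' @param expr Log2 CPM matrix.
#' @param labels Label table for the units of `expr`.
#' @param alpha Significance threshold for keeping a gene (default 0.05).
#' @return Data.frame `gene`, `module`, `direction`, `p`, `log2fc` for the
#'   retained genes, plus attribute `dropped` with the dropped gene ids.
#' @export
assign_modules <- function(genes, expr, labels, alpha = 0.05) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("candidate gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- labels_for_units(labels, colnames(expr))
  sides <- bipartition_sides()
  nb <- length(sides)
  pmat <- matrix(NA_real_, length(genes), nb,
                 dimnames = list(genes, names(sides)))
  fmat <- pmat
  for (k in seq_along(sides)) {
    ia <- which(sub %in% sides[[k]]$a)
    ib <- which(sub %in% sides[[k]]$b)
    ea <- expr[genes, ia, drop = FALSE]
    eb <- expr[genes, ib, drop = FALSE]
    fmat[, k] <- rowMeans(ea) - rowMeans(eb)
    pmat[, k] <- vapply(seq_along(genes), function(g)
      mann_whitney(ea[g, ], eb[g, ])$p, numeric(1))
  }
  pick <- vapply(seq_along(genes), function(g) {
    p <- pmat[g, ]
    best <- which(p == min(p))
    if (length(best) > 1) {
      f <- abs(fmat[g, best])
      best <- best[f == max(f)]
    }
    best[1]  # remaining ties: table order
  }, integer(1))
  best_p <- pmat[cbind(seq_along(genes), pick)]
  best_f <- fmat[cbind(seq_along(genes), pick)]
  keep <- best_p <= alpha
  out <- data.frame(gene = genes[keep],
                    module = names(sides)[pick[keep]],
                    direction = ifelse(best_f[keep] > 0, "up", "down"),
                    p = best_p[keep], log2fc = best_f[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- genes[!keep]
  out
}

#' Select stable, highly expressed control genes
#'
#' Candidates must, in every one of the supplied designs, have
#' `|log2fc| < lfc_max` and both test p-values `>= p_min`; their mean log2 CPM
#' must be at least `min_log2cpm` in every subtype. Candidates are ranked by
#' ascending coefficient of variation of log2 CPM across all units and the
#' top `k` are returned.
#'
#' @param results List of `ov_de` results over the full design set.
#' @param expr Log2 CPM matrix.
#' @param labels Label table.
#' @param k Number of control genes (default 4).
#' @param lfc_max,p_min,min_log2cpm Selection thresholds (defaults 0.2, 0.05, 7).
#' @return Character vector of `k` control gene ids.
#' @export
select_control_genes <- function(results, expr, labels, k = 4,
                                 lfc_max = 0.2, p_min = 0.05, min_log2cpm = 7) {
  genes <- results[[1]]$gene
  stopifnot(all(genes %in% rownames(expr)))
  not_de <- rep(TRUE, length(genes))
  for (r in results) {
    stopifnot(identical(r$gene, genes))
    not_de <- not_de & abs(r$log2fc) < lfc_max & r$p_mw >= p_min & r$p_qlf >= p_min
  }
  sub <- labels_for_units(labels, colnames(expr))
  grp_means <- vapply(subtype_levels(), function(s)
    rowMeans(expr[genes, sub == s, drop = FALSE]), numeric(length(genes)))
  high <- apply(grp_means >= min_log2cpm, 1, all)
  ok <- not_de & high
  if (sum(ok) < k)
    stop(sprintf(paste0("only %d control candidates (need %d): %d pass the ",
                        "non-DE criterion, %d the expression floor"),
                 sum(ok), k, sum(not_de), sum(high)))
  e <- expr[genes[ok], , drop = FALSE]
  cv <- apply(e, 1, stats::sd) / rowMeans(e)
  names(sort(cv))[seq_len(k)]
}

#' Build the full signature panel
#'
#' Chains the selection pipeline: union of DE genes across the designs,
#' intersection with the expression masks of the auxiliary datasets, module
#' assignment, and control-gene selection; packages the result with
#' provenance.
#'
#' @param results Named list of the 10 `ov_de` design results.
#' @param expr Log2 CPM matrix of the training cohort.
#' @param labels Label table of the training cohort.
#' @param masks Optional list of gene-id vectors from [expression_mask()];
#'   candidates must appear in every mask.
#' @param alpha Module-assignment significance threshold.
#' @param k_controls Number of control genes.
#' @param control_lfc_max,control_p_min,control_min_log2cpm Control-gene
#'   thresholds (see [select_control_genes()]).
#' @return An `ov_panel`.
#' @export
build_panel <- function(results, expr, labels, masks = NULL, alpha = 0.05,
                        k_controls = 4, control_lfc_max = 0.2,
                        control_p_min = 0.05, control_min_log2cpm = 7) {
  candidates <- union_de_genes(results)
  n_union <- length(candidates)
  if (!is.null(masks))
    for (m in masks) candidates <- intersect(candidates, m)
  assigned <- assign_modules(candidates, expr, labels, alpha = alpha)
  controls <- select_control_genes(results, expr, labels, k = k_controls,
                                   lfc_max = control_lfc_max,
                                   p_min = control_p_min,
                                   min_log2cpm = control_min_log2cpm)
  assigned <- assigned[!assigned$gene %in% controls, , drop = FALSE]
  prov <- list(n_union_de = n_union,
               n_after_masks = length(candidates),
               n_assigned = nrow(assigned),
               n_dropped = length(attr(assigned, "dropped")),
               designs = names(results),
               alpha = alpha,
               assignment = assigned)
  new_panel(genes = assigned[, c("gene", "module", "direction")],
            controls = controls, provenance = prov)
}
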