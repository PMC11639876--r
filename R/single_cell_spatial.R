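# Applying the trained model to sparse units (single cells, Visium spots):
# log2 CPM with unit factors fixed at 1, a control-gene dropout fallback
# (mean log2 CPM of the detected control genes), explicit rejection of units
# with too few detected panel genes, and aggregation of unit calls into
# sample-level subtype proportions and spatial area fractions.

#' Predict subtypes for single cells or spatial spots
#'
#' Sparse-tolerant path. Counts are converted to log2 CPM with normalization
#' factors fixed at 1 (TMM's mostly-non-DE assumption does not hold across
#' cells). Per channel, the control value is the control gene's log2 CPM when
#' that gene is detected in the unit, otherwise the mean log2 CPM of the
#' detected control genes; units with no detected control gene, or with fewer
#' than `min_panel_detect` detected signature genes, are rejected with a
#' reason code rather than silently dropped.
#'
#' @param model `ov_model`.
#' @param counts Count matrix with unit kind `cell` or `spot` (signature and
#'   control genes must be present as rows; zero counts are fine).
#' @param min_panel_detect Minimum number of signature genes with nonzero
#'   count for a unit to be scored (default 25).
#' @return List of class `ov_cell_predictions`: `predictions`
#'   (`ov_predictions` for accepted units, including
#'   `n_panel_genes_detected`) and `rejected` (data.frame `unit_id`,
#'   `reason`, `n_panel_genes_detected`).
#' @export
predict_cells <- function(model, counts, min_panel_detect = 25) {
  counts <- as_count_input(counts)
  x <- unclass(counts)
  panel_genes <- model$panel$genes$gene
  controls <- model$panel$controls
  missing <- setdiff(c(panel_genes, controls), rownames(x))
  if (length(missing))
    stop("panel gene(s) absent from count matrix: ",
         paste(missing, collapse = ", "))
  n_detect <- colSums(x[panel_genes, , drop = FALSE] > 0)
  ctl_detect <- x[controls, , drop = FALSE] > 0
  no_control <- colSums(ctl_detect) == 0
  too_few <- n_detect < min_panel_detect
  reject <- too_few | no_control
  rejected <- data.frame(
    unit_id = colnames(x)[reject],
    reason = ifelse(no_control[reject], "no_control_gene_detected",
                    "too_few_panel_genes"),
    n_panel_genes_detected = as.integer(n_detect[reject]),
    stringsAsFactors = FALSE)
  keep <- !reject
  if (!any(keep))
    return(structure(list(predictions = probs_to_predictions(
      matrix(numeric(0), 4, 0, dimnames = list(subtype_levels(), NULL)),
      model$mixed_threshold, integer(0)),
      rejected = rejected), class = "ov_cell_predictions"))
  expr <- log2cpm(x[, keep, drop = FALSE], factors = NULL)
  ctl_expr <- expr[controls, , drop = FALSE]
  ctl_det <- ctl_detect[, keep, drop = FALSE]
  # fallback control value: mean log2 CPM over the unit's detected controls
  fallback <- colSums(ctl_expr * ctl_det) / colSums(ctl_det)
  P <- 0
  for (ch in model$channels) {
    cg <- ch$control_gene
    ctl_val <- ifelse(ctl_det[cg, ], ctl_expr[cg, ], fallback)
    feats <- sweep(expr[panel_genes, , drop = FALSE], 2, ctl_val, "-")
    z <- apply_scaling(feats, ch$scaling)
    P <- P + nn_forward(ch$par, z)
  }
  P <- P / length(model$channels)
  rownames(P) <- subtype_levels(); colnames(P) <- colnames(expr)
  structure(list(predictions = probs_to_predictions(
    P, model$mixed_threshold, as.integer(n_detect[keep])),
    rejected = rejected),
    class = "ov_cell_predictions")
}

#' @export
print.ov_cell_predictions <- function(x, ...) {
  cat(sprintf("ov_cell_predictions: %d accepted, %d rejected units\n",
              nrow(x$predictions), nrow(x$rejected)))
  if (nrow(x$predictions))
    print(table(x$predictions$label))
  invisible(x)
}

as_unit_predictions <- function(preds) {
  if (inherits(preds, "ov_cell_predictions")) preds$predictions else preds
}

#' Aggregate unit predictions into a sample summary
#'
#' Per-subtype proportions over accepted units, by hard-label voting
#' (default) or mean probability. The dominant subtype is the one with the
#' largest proportion (ties toward canonical order); the co-dominance flag is
#' raised when the top two proportions differ by less than `codominant_gap`.
#'
#' @param preds `ov_predictions` or `ov_cell_predictions`.
#' @param sample_id Sample identifier to record.
#' @param mode `"vote"` (default) or `"prob"`.
#' @param codominant_gap Gap below which the top two subtypes are considered
#'   co-dominant (default 0.1).
#' @return One-row data.frame of class `ov_sample_summary`: `sample_id`,
#'   `prop_D..prop_P`, `dominant`, `secondary`, `secondary_prop`, `n_units`,
#'   `co_dominant`.
#' @export
aggregate_sample <- function(preds, sample_id, mode = c("vote", "prob"),
                             codominant_gap = 0.1) {
  mode <- match.arg(mode)
  preds <- as_unit_predictions(preds)
  if (nrow(preds) == 0) stop("no accepted units to aggregate")
  lv <- subtype_levels()
  if (mode == "vote") {
    prop <- as.numeric(table(factor(preds$label, levels = lv))) / nrow(preds)
  } else {
    prop <- colMeans(preds[, paste0("p_", lv), drop = FALSE])
    prop <- as.numeric(prop / sum(prop))
  }
  names(prop) <- lv
  ord <- order(-prop, seq_along(prop))  # ties toward canonical order
  out <- data.frame(sample_id = sample_id, t(prop),
                    dominant = lv[ord[1]], secondary = lv[ord[2]],
                    secondary_prop = prop[ord[2]], n_units = nrow(preds),
                    co_dominant = (prop[ord[1]] - prop[ord[2]]) < codominant_gap,
                    row.names = NULL, stringsAsFactors = FALSE)
  colnames(out)[2:5] <- paste0("prop_", lv)
  structure(out, class = c("ov_sample_summary", "data.frame"))
}

#' Per-spot spatial report with area fractions
#'
#' Joins spot predictions with their array coordinates, computes the area
#' fraction of each subtype over accepted in-tissue spots, and optionally
#' writes a TSV and a scatter figure colored by label (D red, I green,
#' M blue, P yellow).
#'
#' @param preds `ov_predictions` or `ov_cell_predictions` for the spots.
#' @param coords [spatial_coords()] covering all predicted spots.
#' @param path Optional output TSV path.
#' @param figure Optional output figure path (png).
#' @return List of class `ov_spatial_report`: `spots` (data.frame with
#'   coordinates, label, probabilities), `area_fractions` (named numeric over
#'   D, I, M, P).
#' @export
spatial_report <- function(preds, coords, path = NULL, figure = NULL) {
  preds <- as_unit_predictions(preds)
  idx <- match(preds$unit_id, coords$unit_id)
  if (anyNA(idx))
    stop("spot(s) missing from coordinates: ",
         paste(preds$unit_id[is.na(idx)], collapse = ", "))
  lv <- subtype_levels()
  spots <- data.frame(barcode = preds$unit_id,
                      row = coords$row[idx], col = coords$col[idx],
                      label = preds$label,
                      preds[, paste0("p_", lv)],
                      stringsAsFactors = FALSE)
  frac <- as.numeric(table(factor(preds$label, levels = lv))) / nrow(preds)
  names(frac) <- lv
  if (!is.null(path))
    utils::write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(figure)) {
    palette <- c(D = "#d62728", I = "#2ca02c", M = "#1f77b4", P = "#e8d517")
    grDevices::png(figure, width = 720, height = 640)
    graphics::plot(spots$col, -spots$row, pch = 15, cex = 1.4,
                   col = palette[spots$label], xlab = "array column",
                   ylab = "array row", main = "Spot subtype calls",
                   yaxt = "n")
    graphics::legend("topright", legend = lv, col = palette, pch = 15)
    grDevices::dev.off()
  }
  structure(list(spots = spots, area_fractions = frac),
            class = "ov_spatial_report")
}

#' @export
print.ov_spatial_report <- function(x, ...) {
  cat("ov_spatial_report:", nrow(x$spots), "spots; area fractions:\n")
  print(round(x$area_fractions, 3))
  invisible(x)
}
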