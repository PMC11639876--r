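#' The four HGSC molecular subtypes, in canonical order
#'
#' Differentiated (D), immunoreactive (I), mesenchymal (M), proliferative (P).
#' This order is the single source of truth for every label/index mapping in
#' the package: probability columns, confusion matrices, tie-breaks.
#'
#' @return Character vector `c("D", "I", "M", "P")`.
#' @export
subtype_levels <- function() c("D", "I", "M", "P")

#' Construct a count matrix container
#'
#' Wraps a genes-by-units matrix of non-negative integer counts together with
#' the kind of unit it holds (bulk sample, single cell, or spatial spot).
#' All invariants are enforced here so that every reader and simulator funnels
#' through one validator: integral non-negative counts, unique gene and unit
#' identifiers, and a strictly positive library size for every unit.
#'
#' @param counts Numeric matrix, genes in rows, units in columns, with
#'   rownames (gene ids) and colnames (unit ids).
#' @param unit_kind One of `"bulk"`, `"cell"`, `"spot"`.
#' @return An object of class `ov_counts`: the validated integer-mode matrix
#'   with attribute `unit_kind`.
#' @export
count_matrix <- function(counts, unit_kind = c("bulk", "cell", "spot")) {
  unit_kind <- match.arg(unit_kind)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene ids (rownames) and unit ids (colnames)")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_u <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_u))
    stop("duplicate unit ids: ", paste(dup_u, collapse = ", "))
  if (anyNA(counts) || !is.numeric(counts)) {
    bad <- which(is.na(counts) | !is.finite(counts), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric count at gene '%s', unit '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at gene '%s', unit '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint))
    stop(sprintf("non-integer count %g at gene '%s', unit '%s'",
                 counts[nonint[1, 1], nonint[1, 2]],
                 rownames(counts)[nonint[1, 1]], colnames(counts)[nonint[1, 2]]))
  storage.mode(counts) <- "double"
  counts <- round(counts)
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero))
    stop("zero library size for unit(s): ", paste(zero, collapse = ", "))
  structure(counts, unit_kind = unit_kind, class = c("ov_counts", "matrix", "array"))
}

#' @export
print.ov_counts <- function(x, ...) {
  cat(sprintf("ov_counts: %d genes x %d %ss (library sizes %s..%s)\n",
              nrow(x), ncol(x), attr(x, "unit_kind"),
              format(min(colSums(x))), format(max(colSums(x)))))
  invisible(x)
}

unit_kind <- function(x) {
  k <- attr(x, "unit_kind")
  if (is.null(k)) "bulk" else k
}

#' Library sizes (per-unit total counts)
#'
#' @param counts Count matrix (see [count_matrix()]).
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(counts) colSums(as_count_input(counts))

# Accept ov_counts or a bare integer matrix in all analysis entry points.
as_count_input <- function(counts) {
  if (inherits(counts, "ov_counts")) return(counts)
  count_matrix(counts, unit_kind = "bulk")
}

#' Construct a subtype label table
#'
#' @param unit_ids Character vector of unit identifiers.
#' @param subtype Character or factor vector over the four subtype codes
#'   D, I, M, P (see [subtype_levels()]).
#' @return A data.frame with columns `unit_id`, `subtype` (factor with the
#'   canonical level order), class `ov_labels`.
#' @export
label_table <- function(unit_ids, subtype) {
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids))
    stop("duplicate unit ids in label table: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  subtype <- as.character(subtype)
  bad <- setdiff(unique(subtype), subtype_levels())
  if (length(bad))
    stop("invalid subtype code(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(subtype_levels(), collapse = ", "), ")")
  if (length(subtype) != length(unit_ids))
    stop("unit_ids and subtype lengths differ")
  structure(data.frame(unit_id = unit_ids,
                       subtype = factor(subtype, levels = subtype_levels()),
                       stringsAsFactors = FALSE),
            class = c("ov_labels", "data.frame"))
}

# Named factor of subtypes for a set of units, erroring on missing labels.
labels_for_units <- function(labels, unit_ids) {
  stopifnot(is.data.frame(labels))
  idx <- match(unit_ids, labels$unit_id)
  if (anyNA(idx))
    stop("unlabeled unit(s): ", paste(unit_ids[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                                      collapse = ", "))
  out <- labels$subtype[idx]
  names(out) <- unit_ids
  out
}

#' Construct a spatial coordinates table
#'
#' Spot array coordinates and pixel positions as read from a Visium-style
#' tissue positions file. Row/column indices are stored exactly as given
#' (0-based in the 10x convention) with no axis flips.
#'
#' @param unit_ids Spot barcodes.
#' @param row,col Integer array coordinates.
#' @param x_px,y_px Pixel coordinates.
#' @param in_tissue Logical flag per spot.
#' @return Data.frame of class `ov_spatial_coords`.
#' @export
spatial_coords <- function(unit_ids, row, col, x_px, y_px, in_tissue) {
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids))
    stop("duplicate barcode(s) in positions: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  df <- data.frame(unit_id = unit_ids, row = as.integer(row), col = as.integer(col),
                   x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                   in_tissue = as.logical(in_tissue), stringsAsFactors = FALSE)
  it <- df[df$in_tissue, , drop = FALSE]
  key <- paste(it$row, it$col)
  if (anyDuplicated(key))
    stop("duplicate (row, col) among in-tissue spots: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(df, class = c("ov_spatial_coords", "data.frame"))
}
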