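# Readers and writers for the on-disk formats: dense count tables (TSV/CSV),
# 10x-style MatrixMarket triplets with features/barcodes sidecars, Visium-style
# spatial folders, label tables, signature panels and prediction tables.
# Every reader validates through count_matrix()/spatial_coords() and rejects
# invariant violations instead of repairing them.

# Open a path as an already-open text connection, transparently handling
# gzip (magic bytes 1f 8b). Returning it open means downstream readers
# (read.table, readMM, readLines) never close it themselves; callers close
# it via on.exit.
open_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2)
  con <- if (length(magic) == 2 && identical(magic, as.raw(c(0x1f, 0x8b))))
    gzfile(path) else file(path)
  open(con, "rt")
  con
}

sniff_sep <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a dense count table
#'
#' Reads a delimited (tab or comma, auto-detected) table with one header row
#' and one identifier column, in either orientation, and returns a validated
#' genes-by-units [count_matrix()].
#'
#' @param path File path (plain or gzipped).
#' @param orientation `"genes_in_rows"` (default) or `"units_in_rows"`.
#' @param unit_kind Passed to [count_matrix()].
#' @return An `ov_counts` matrix in genes-by-units orientation.
#' @export
read_counts_dense <- function(path, orientation = c("genes_in_rows", "units_in_rows"),
                              unit_kind = "bulk") {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row id '%s', column '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  if (orientation == "units_in_rows") m <- t(m)
  count_matrix(m, unit_kind = unit_kind)
}

#' Write a dense count table (TSV, genes in rows)
#'
#' @param counts Count matrix.
#' @param path Output file path.
#' @param id_col Name for the gene id column.
#' @return The path, invisibly.
#' @export
write_counts_dense <- function(counts, path, id_col = "gene") {
  counts <- as_count_input(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

find_one <- function(dir, candidates, what) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("no ", what, " file found in ", dir,
       " (looked for ", paste(candidates, collapse = ", "), ")")
}

read_id_column <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  as.character(df[[1]])
}

#' Read a 10x-style sparse count folder
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped, following the 10x Genomics triplet convention.
#' Duplicated feature ids are an error, not deduplicated by suffixing.
#'
#' @param dir Directory containing the three files.
#' @param unit_kind Unit kind for the result (default `"cell"`).
#' @return An `ov_counts` matrix (dense, genes by units).
#' @export
read_counts_mtx <- function(dir, unit_kind = "cell") {
  mtx <- find_one(dir, c("matrix.mtx", "matrix.mtx.gz"), "MatrixMarket")
  feat <- find_one(dir, c("features.tsv", "features.tsv.gz",
                          "genes.tsv", "genes.tsv.gz"), "features")
  bc <- find_one(dir, c("barcodes.tsv", "barcodes.tsv.gz"), "barcodes")
  mtx_con <- open_maybe_gz(mtx)
  on.exit(close(mtx_con))
  m <- Matrix::readMM(mtx_con)
  genes <- read_id_column(feat)
  barcodes <- read_id_column(bc)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop(sprintf("MTX header %d x %d inconsistent with %d features / %d barcodes",
                 nrow(m), ncol(m), length(genes), length(barcodes)))
  dense <- as.matrix(m)
  dimnames(dense) <- list(genes, barcodes)
  count_matrix(dense, unit_kind = unit_kind)
}

#' Write a count matrix as a 10x-style sparse folder
#'
#' @param counts Count matrix.
#' @param dir Output directory (created if needed).
#' @param gzip Write gzipped files (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, gzip = FALSE) {
  counts <- as_count_input(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  writer <- function(lines, name) {
    path <- file.path(dir, paste0(name, ext))
    con <- if (gzip) gzfile(path) else file(path)
    writeLines(lines, con)
    close(con)
  }
  # coordinate integer format, 1-based indices, column-major (10x convention)
  nz <- which(unclass(counts) != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2], nz[, 1]), , drop = FALSE]
  writer(c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(nz)),
           sprintf("%d %d %d", nz[, 1], nz[, 2],
                   as.integer(counts[nz]))),
         "matrix.mtx")
  writer(rownames(counts), "features.tsv")
  writer(colnames(counts), "barcodes.tsv")
  invisible(dir)
}

#' Read a Visium-style spatial folder
#'
#' Reads the 10x triplet plus a tissue positions table
#' (`tissue_positions.csv` or `tissue_positions_list.csv`; with or without a
#' header, both dialects accepted: barcode, in_tissue, array row, array col,
#' pixel x, pixel y). The count matrix is restricted to in-tissue spots.
#'
#' @param dir Directory with the count triplet and positions table.
#' @return List with elements `counts` (`ov_counts`, unit_kind `"spot"`) and
#'   `coords` ([spatial_coords()] for all barcodes in the positions file).
#' @export
read_spatial <- function(dir) {
  counts <- read_counts_mtx(dir, unit_kind = "spot")
  pos_path <- find_one(dir, c("tissue_positions.csv", "tissue_positions.csv.gz",
                              "tissue_positions_list.csv",
                              "tissue_positions_list.csv.gz"), "tissue positions")
  con <- open_maybe_gz(pos_path)
  first <- readLines(con, n = 1)
  close(con)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  con2 <- open_maybe_gz(pos_path)
  on.exit(close(con2))
  pos <- utils::read.table(con2, header = has_header, sep = ",",
                           stringsAsFactors = FALSE)
  if (ncol(pos) != 6)
    stop("positions table must have 6 columns, found ", ncol(pos))
  coords <- spatial_coords(unit_ids = pos[[1]], in_tissue = pos[[2]] != 0,
                           row = pos[[3]], col = pos[[4]],
                           x_px = pos[[5]], y_px = pos[[6]])
  missing <- setdiff(colnames(counts), coords$unit_id)
  if (length(missing))
    stop("barcode(s) in counts absent from positions: ",
         paste(missing, collapse = ", "))
  keep <- coords$unit_id[coords$in_tissue]
  keep <- intersect(colnames(counts), keep)
  counts <- count_matrix(unclass(counts)[, keep, drop = FALSE], unit_kind = "spot")
  list(counts = counts, coords = coords)
}

#' Write a spatial folder (counts + positions) the package can read back
#'
#' @param counts Count matrix (spots in columns).
#' @param coords [spatial_coords()] covering the barcodes.
#' @param dir Output directory.
#' @param header Write the positions file with a header row (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_spatial <- function(counts, coords, dir, header = TRUE) {
  write_counts_mtx(counts, dir)
  pos <- data.frame(barcode = coords$unit_id,
                    in_tissue = as.integer(coords$in_tissue),
                    array_row = coords$row, array_col = coords$col,
                    pxl_x = coords$x_px, pxl_y = coords$y_px)
  utils::write.table(pos, file.path(dir, "tissue_positions.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = header)
  invisible(dir)
}

#' Read / write a subtype label table
#'
#' TSV with header columns `unit_id`, `subtype`.
#'
#' @param path File path.
#' @return [label_table()] data.frame.
#' @export
read_labels <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  label_table(df$unit_id, df$subtype)
}

#' @rdname read_labels
#' @param labels Label table to write.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(unit_id = labels$unit_id,
                                subtype = as.character(labels$subtype)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write unit-level subtype predictions
#'
#' Writes a TSV with unit id, the four subtype probabilities in the canonical
#' D, I, M, P order, the argmax label (ties broken toward the first label in
#' canonical order), and the mixed-signature flag. Probabilities are written
#' with 8 significant digits so a read-back reproduces them within 1e-6.
#'
#' @param preds Prediction table as returned by [predict_units()] or
#'   [predict_cells()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(preds, path) {
  df <- as.data.frame(preds)
  pcols <- paste0("p_", subtype_levels())
  stopifnot(all(pcols %in% colnames(df)))
  for (pc in pcols) df[[pc]] <- sprintf("%.8g", df[[pc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("mixed" %in% colnames(df)) df$mixed <- as.logical(df$mixed)
  structure(df, class = c("ov_predictions", "data.frame"))
}

#' Serialize / deserialize a signature panel
#'
#' The panel is written as a TSV with columns `gene`, `role`
#' (`signature`/`control`), `module`, `direction`, accompanied by a JSON
#' provenance sidecar (`<path>.json`) holding the per-gene design statistics
#' the assignments came from.
#'
#' @param panel An `ov_panel` (see [build_panel()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  sig <- data.frame(gene = panel$genes$gene, role = "signature",
                    module = panel$genes$module, direction = panel$genes$direction,
                    stringsAsFactors = FALSE)
  ctl <- data.frame(gene = panel$controls, role = "control",
                    module = NA_character_, direction = NA_character_,
                    stringsAsFactors = FALSE)
  utils::write.table(rbind(sig, ctl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(panel$provenance))
    jsonlite::write_json(panel$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sig <- df[df$role == "signature", , drop = FALSE]
  ctl <- df$gene[df$role == "control"]
  prov <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  new_panel(genes = data.frame(gene = sig$gene, module = sig$module,
                               direction = sig$direction, stringsAsFactors = FALSE),
            controls = ctl, provenance = prov)
}
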