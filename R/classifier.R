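# The four-channel subtype model: one channel network per control gene, each
# trained on control-normalized z-scaled signature features, combined by an
# averaging head. train_subtype_model() is the package's main fitting
# function and returns a classed "ov_model" with print/summary/predict/plot
# methods.

#' Stratified train/test split
#'
#' Deterministic given the seed; per-subtype test counts are within one unit
#' of the global ratio.
#'
#' @param labels [label_table()].
#' @param ratio Train:test ratio, length-2 numeric (default `c(2, 1)`).
#' @param seed Integer seed.
#' @return List with `train` and `test` unit-id vectors.
#' @export
split_train_test <- function(labels, ratio = c(2, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  counts <- table(labels$subtype)
  small <- names(counts)[counts < 3]
  if (length(small))
    stop("subtype(s) with fewer than 3 units: ", paste(small, collapse = ", "))
  train_frac <- ratio[1] / sum(ratio)
  set.seed(seed)
  train <- unlist(lapply(split(labels$unit_id, labels$subtype), function(u) {
    sample(u, round(length(u) * train_frac))
  }), use.names = FALSE)
  list(train = train, test = setdiff(labels$unit_id, train))
}

#' Fit the four-channel subtype model
#'
#' The main fitting function. Given bulk counts, subtype labels, and a
#' signature panel, it (1) computes TMM-normalized log2 CPM, (2) splits the
#' cohort into stratified training and test sets (2:1 by default), (3) builds
#' one feature matrix per control gene by control-gene subtraction and
#' z-scales it with training-only statistics, (4) trains one channel network
#' per control gene with per-epoch checkpointing, and (5) combines the
#' channels by probability averaging and evaluates on the held-out test set.
#'
#' @param counts Bulk count matrix.
#' @param labels [label_table()] covering all units.
#' @param panel `ov_panel` from [build_panel()] (or [read_panel()]).
#' @param config [train_config()].
#' @param spec Optional [channel_spec()]; defaults to the standard ten-layer
#'   ladder sized to the panel.
#' @param mixed_threshold Second-highest ensemble probability at or above
#'   which a unit is flagged as having a mixed signature (default 0.2).
#' @return Object of class `ov_model`.
#' @export
train_subtype_model <- function(counts, labels, panel, config = train_config(),
                                spec = NULL, mixed_threshold = 0.2) {
  counts <- as_count_input(counts)
  stopifnot(inherits(panel, "ov_panel"))
  if (is.null(spec)) spec <- channel_spec(nrow(panel$genes))
  split <- split_train_test(labels, ratio = config$split_ratio,
                            seed = config$seed)
  factors <- tmm_factors(counts)
  expr <- log2cpm(counts, factors)
  lab <- labels_for_units(labels, colnames(expr))

  set.seed(config$seed)
  # validation carve-out at the sample level: every view of a validation
  # sample stays on the validation side
  val_units <- stratified_sample(lab[split$train], config$validation_fraction)
  tr_units <- setdiff(split$train, val_units)

  # multiplatform augmentation: depth-downsampled views emulating Visium
  # spots and droplet cells. Validation views are drawn once and frozen (the
  # checkpoint metric must be comparable across epochs); training views are
  # redrawn every epoch over stratified halves, so the channels see fresh
  # shallow renderings of the same samples throughout training.
  x <- unclass(counts)
  draw_views <- function(ids, fraction) {
    take1 <- stratified_sample(lab[ids], fraction)
    take2 <- stratified_sample(lab[ids], fraction)
    Filter(Negate(is.null), list(
      make_view(x[, take1, drop = FALSE], panel, log(5e4), 0.4,
                c(0, 0.3), ".spot"),
      make_view(x[, take2, drop = FALSE], panel, log(8e3), 0.6,
                c(0.5, 0.85), ".cell")))
  }
  val_views <- if (config$augment) draw_views(val_units, 1) else list()
  init_views <- if (config$augment) draw_views(tr_units, 0.5) else list()

  channels <- list()
  for (cg in panel$controls) {
    bulk_feats <- control_normalize(expr, panel, cg)
    chan_feats <- function(views) {
      do.call(cbind, lapply(views, view_channel_features,
                            panel = panel, cg = cg))
    }
    view_labels <- function(views) {
      base <- unlist(lapply(views, `[[`, "base"), use.names = FALSE)
      ids <- unlist(lapply(views, `[[`, "ids"), use.names = FALSE)
      stats::setNames(lab[base], ids)
    }
    # scaling statistics from the training samples plus one drawn set of
    # training views, then frozen for the whole fit and for prediction
    scal <- fit_scaling(cbind(bulk_feats[, tr_units, drop = FALSE],
                              chan_feats(init_views)))
    Xval <- apply_scaling(cbind(bulk_feats[, val_units, drop = FALSE],
                                chan_feats(val_views)), scal)
    yval <- as.character(c(lab[val_units], view_labels(val_views)))
    Xtr_bulk <- apply_scaling(bulk_feats[, tr_units, drop = FALSE], scal)
    Ytr_bulk <- one_hot(lab[tr_units])
    provider <- if (config$augment) {
      function() {
        vs <- draw_views(tr_units, 0.5)
        vl <- view_labels(vs)
        list(X = cbind(Xtr_bulk, apply_scaling(chan_feats(vs), scal)),
             Y = cbind(Ytr_bulk, one_hot(vl)))
      }
    } else {
      function() list(X = Xtr_bulk, Y = Ytr_bulk)
    }
    ch <- train_channel_core(provider, Xval, yval, spec, config)
    ch$control_gene <- cg
    ch$scaling <- scal
    channels[[cg]] <- ch
  }
  model <- structure(list(panel = panel, channels = channels, spec = spec,
                          config = config, mixed_threshold = mixed_threshold,
                          split = split,
                          version = list(
                            package = as.character(utils::packageVersion("ovsubtype")),
                            bundle_format = 1L)),
                     class = "ov_model")
  test_preds <- predict_units(model, expr[, split$test, drop = FALSE])
  model$eval <- evaluate_predictions(test_preds, labels)
  model$test_predictions <- test_preds
  model
}

#' Combine four trained channels into an ensemble model
#'
#' The ensemble probability vector is the arithmetic mean of the four channel
#' softmax outputs.
#'
#' @param channels Named list of exactly 4 `ov_channel` objects (keyed by
#'   control gene), each carrying `control_gene` and `scaling`.
#' @param panel The shared `ov_panel`.
#' @param config Training configuration to record.
#' @param mixed_threshold Mixed-signature flag threshold.
#' @return `ov_model` (without an evaluation report).
#' @export
build_ensemble <- function(channels, panel, config = train_config(),
                           mixed_threshold = 0.2) {
  if (length(channels) != 4)
    stop("the ensemble requires exactly 4 channels, got ", length(channels))
  for (ch in channels)
    if (!identical(ch$spec$n_inputs, channels[[1]]$spec$n_inputs))
      stop("channels disagree on the signature gene order")
  structure(list(panel = panel, channels = channels,
                 spec = channels[[1]]$spec, config = config,
                 mixed_threshold = mixed_threshold,
                 version = list(
                   package = as.character(utils::packageVersion("ovsubtype")),
                   bundle_format = 1L)),
            class = "ov_model")
}

# One augmentation view: binomially downsample training samples to a shallow
# log-normal depth with per-sample dropout zeroing drawn from a range, then
# precompute log2 CPM and control-gene detection for the channel feature
# builders. Columns losing every control gene (or all counts) are dropped.
make_view <- function(x, panel, meanlog, sdlog, dropout, suffix) {
  d <- stats::rlnorm(ncol(x), meanlog, sdlog)
  p <- pmin(d / colSums(x), 1)
  y <- matrix(stats::rbinom(length(x), x, rep(p, each = nrow(x))),
              nrow(x), ncol(x), dimnames = dimnames(x))
  dr <- stats::runif(ncol(x), dropout[1], dropout[2])
  if (any(dr > 0))
    y <- y * matrix(stats::rbinom(length(y), 1, rep(1 - dr, each = nrow(y))),
                    nrow(y), ncol(y))
  ctl_det <- y[panel$controls, , drop = FALSE] > 0
  keep <- colSums(y) > 0 & colSums(ctl_det) > 0
  if (!any(keep)) return(NULL)
  y <- y[, keep, drop = FALSE]
  base <- colnames(x)[keep]
  colnames(y) <- paste0(base, suffix)
  expr <- log2cpm(y, NULL)
  det <- ctl_det[, keep, drop = FALSE]
  colnames(det) <- colnames(y)
  ctl_expr <- expr[panel$controls, , drop = FALSE]
  fallback <- colSums(ctl_expr * det) / colSums(det)
  list(expr = expr, det = det, fallback = fallback,
       ids = colnames(y), base = base)
}

# Channel features for a view: control value = the channel's control gene
# when detected, else the mean log2 CPM of the detected controls.
view_channel_features <- function(v, panel, cg) {
  ctl_val <- ifelse(v$det[cg, ], v$expr[cg, ], v$fallback)
  sweep(v$expr[panel$genes$gene, , drop = FALSE], 2, ctl_val, "-")
}

# Ensemble probabilities for a log2 CPM matrix whose rows cover the panel.
# Per channel: control-normalize -> stored z-scaling -> softmax; then average.
ensemble_probs <- function(model, expr) {
  missing <- setdiff(c(model$panel$genes$gene, model$panel$controls),
                     rownames(expr))
  if (length(missing))
    stop("panel gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  P <- 0
  for (ch in model$channels) {
    feats <- control_normalize(expr, model$panel, ch$control_gene)
    z <- apply_scaling(feats, ch$scaling)
    P <- P + nn_forward(ch$par, z)
  }
  P <- P / length(model$channels)
  rownames(P) <- subtype_levels()
  colnames(P) <- colnames(expr)
  P
}

probs_to_predictions <- function(P, mixed_threshold, n_detected = NULL) {
  label <- argmax_labels(P)
  second <- apply(P, 2, function(p) sort(p, decreasing = TRUE)[2])
  df <- data.frame(unit_id = colnames(P), t(P), label = label,
                   mixed = second >= mixed_threshold,
                   row.names = NULL, stringsAsFactors = FALSE)
  colnames(df)[2:5] <- paste0("p_", subtype_levels())
  if (!is.null(n_detected)) df$n_panel_genes_detected <- n_detected
  structure(df, class = c("ov_predictions", "data.frame"))
}

#' Predict subtype probabilities for bulk units
#'
#' Strict bulk path: every panel and control gene must be present in the
#' expression matrix. Per unit the four channel probabilities are averaged;
#' the label is the argmax (ties toward the first subtype in canonical
#' order) and the mixed flag is raised when the second-highest probability
#' reaches the model's `mixed_threshold`.
#'
#' @param model `ov_model`.
#' @param expr Log2 CPM matrix (genes by units).
#' @return `ov_predictions` data.frame: unit id, probabilities `p_D..p_P`,
#'   `label`, `mixed`.
#' @export
predict_units <- function(model, expr) {
  probs_to_predictions(ensemble_probs(model, expr), model$mixed_threshold)
}

#' Evaluate predictions against true labels
#'
#' One-vs-rest sensitivity, specificity, precision, accuracy, Cohen's kappa
#' and ROC AUC per subtype, plus overall accuracy, multi-class kappa and
#' macro-averaged AUC, from the 4x4 confusion matrix and the class
#' probabilities.
#'
#' @param preds `ov_predictions` (with probability columns).
#' @param truth [label_table()] covering the predicted units.
#' @return List of class `ov_eval`: `confusion`, `per_class` (data.frame),
#'   `overall` (named vector).
#' @export
evaluate_predictions <- function(preds, truth) {
  lv <- subtype_levels()
  y <- as.character(labels_for_units(truth, preds$unit_id))
  yhat <- preds$label
  cm <- table(truth = factor(y, levels = lv),
              pred = factor(yhat, levels = lv))
  per <- lapply(lv, function(s) {
    if (!any(y == s))
      return(data.frame(subtype = s, sensitivity = NA, specificity = NA,
                        precision = NA, accuracy = NA, kappa = NA, auc = NA))
    tp <- sum(y == s & yhat == s); fn <- sum(y == s & yhat != s)
    fp <- sum(y != s & yhat == s); tn <- sum(y != s & yhat != s)
    po <- (tp + tn) / length(y)
    pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / length(y)^2
    roc <- pROC::roc(response = factor(y == s, levels = c(FALSE, TRUE)),
                     predictor = preds[[paste0("p_", s)]],
                     quiet = TRUE, direction = "<")
    data.frame(subtype = s,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               accuracy = po,
               kappa = if (pe < 1) (po - pe) / (1 - pe) else 1,
               auc = as.numeric(pROC::auc(roc)))
  })
  per <- do.call(rbind, per)
  overall <- c(accuracy = mean(y == yhat),
               kappa = kappa_score(yhat, y),
               macro_auc = mean(per$auc, na.rm = TRUE))
  structure(list(confusion = cm, per_class = per, overall = overall),
            class = "ov_eval")
}

#' @export
print.ov_eval <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nPer-subtype metrics:\n")
  print(x$per_class, digits = 3, row.names = FALSE)
  cat(sprintf("\nOverall: accuracy %.3f, kappa %.3f, macro AUC %.3f\n",
              x$overall["accuracy"], x$overall["kappa"], x$overall["macro_auc"]))
  invisible(x)
}

#' Save / load a fitted model bundle
#'
#' The bundle directory holds the channel weights (`weights.rds`), the panel
#' (`panel.tsv` + provenance JSON), per-channel scaling statistics
#' (`scaling.json`), the configuration incl. seed and package version
#' (`config.json`), and the per-epoch training report
#' (`training_report.tsv`). A reloaded model reproduces predictions within
#' 1e-6.
#'
#' @param model `ov_model`.
#' @param dir Bundle directory.
#' @return `dir` (save) / the reloaded `ov_model` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(lapply(model$channels, function(ch)
    list(par = ch$par, best_epoch = ch$best_epoch, best_kappa = ch$best_kappa,
         control_gene = ch$control_gene)),
    file.path(dir, "weights.rds"))
  write_panel(model$panel, file.path(dir, "panel.tsv"))
  jsonlite::write_json(
    lapply(model$channels, function(ch)
      list(control_gene = ch$control_gene,
           mean = as.list(ch$scaling$mean), sd = as.list(ch$scaling$sd))),
    file.path(dir, "scaling.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(model$config),
         spec = unclass(model$spec),
         mixed_threshold = model$mixed_threshold,
         version = model$version),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- do.call(rbind, lapply(model$channels, function(ch)
    cbind(channel = ch$control_gene, ch$trace)))
  utils::write.table(report, file.path(dir, "training_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("not a model bundle: missing config.json")
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  if (is.null(meta$version$bundle_format) || meta$version$bundle_format != 1)
    stop("model bundle format ", meta$version$bundle_format,
         " not supported by this version (expected 1)")
  weights <- readRDS(file.path(dir, "weights.rds"))
  if (length(weights) != 4)
    stop("bundle has ", length(weights), " channels, expected 4")
  panel <- read_panel(file.path(dir, "panel.tsv"))
  scal <- jsonlite::read_json(file.path(dir, "scaling.json"),
                              simplifyVector = FALSE)
  spec <- channel_spec(meta$spec$n_inputs, meta$spec$hidden_sizes)
  cfg <- do.call(train_config, meta$config[setdiff(names(meta$config), NULL)])
  channels <- list()
  for (i in seq_along(weights)) {
    w <- weights[[i]]
    sc <- scal[[i]]
    stopifnot(identical(w$control_gene, sc$control_gene))
    channels[[w$control_gene]] <- structure(
      list(par = w$par, spec = spec, best_epoch = w$best_epoch,
           best_kappa = w$best_kappa, control_gene = w$control_gene,
           scaling = structure(list(mean = unlist(sc$mean), sd = unlist(sc$sd)),
                               class = "ov_scaling")),
      class = "ov_channel")
  }
  model <- build_ensemble(channels, panel, cfg,
                          mixed_threshold = meta$mixed_threshold)
  report_path <- file.path(dir, "training_report.tsv")
  if (file.exists(report_path))
    model$training_report <- utils::read.table(report_path, header = TRUE,
                                               sep = "\t")
  model
}

#' @export
print.ov_model <- function(x, ...) {
  cat(sprintf(paste0("ov_model: four-channel subtype classifier\n",
                     "  signature genes: %d; control genes: %s\n"),
              nrow(x$panel$genes), paste(names(x$channels), collapse = ", ")))
  for (ch in x$channels)
    cat(sprintf("  channel %-10s best epoch %3d (validation kappa %.3f)\n",
                ch$control_gene, ch$best_epoch, ch$best_kappa))
  if (!is.null(x$eval))
    cat(sprintf("  held-out: accuracy %.3f, kappa %.3f, macro AUC %.3f\n",
                x$eval$overall["accuracy"], x$eval$overall["kappa"],
                x$eval$overall["macro_auc"]))
  invisible(x)
}

#' @export
summary.ov_model <- function(object, ...) {
  print(object)
  if (!is.null(object$eval)) print(object$eval)
  invisible(object$eval)
}

#' Predict method for fitted subtype models
#'
#' Dispatches on the unit kind of `newdata`: bulk counts go through TMM +
#' log2 CPM and the strict [predict_units()] path; cell/spot counts go
#' through the sparse-tolerant [predict_cells()] path (factors fixed at 1,
#' control-gene fallback, minimum panel detection).
#'
#' @param object `ov_model`.
#' @param newdata `ov_counts` matrix, or a log2 CPM matrix when
#'   `type = "expr"`.
#' @param type `"counts"` (default; dispatch on unit kind) or `"expr"`
#'   (already log2 CPM, strict path).
#' @param ... Passed to [predict_cells()] for cell/spot input.
#' @return `ov_predictions` data.frame.
#' @export
predict.ov_model <- function(object, newdata, type = c("counts", "expr"), ...) {
  type <- match.arg(type)
  if (type == "expr") return(predict_units(object, newdata))
  newdata <- as_count_input(newdata)
  if (unit_kind(newdata) %in% c("cell", "spot"))
    return(predict_cells(object, newdata, ...))
  factors <- if (ncol(newdata) >= 2) tmm_factors(newdata) else NULL
  predict_units(object, log2cpm(newdata, factors))
}

#' Plot method: per-channel training traces
#'
#' Validation kappa by epoch for each channel, with the restored best epoch
#' marked.
#'
#' @param x `ov_model` with training traces.
#' @param ... Passed to `matplot`.
#' @export
plot.ov_model <- function(x, ...) {
  traces <- lapply(x$channels, function(ch) ch$trace)
  if (!length(traces) || is.null(traces[[1]]))
    stop("model carries no training traces")
  max_ep <- max(vapply(traces, function(tr) max(tr$epoch), numeric(1)))
  graphics::plot(NULL, xlim = c(1, max_ep), ylim = c(-0.1, 1),
                 xlab = "epoch", ylab = "validation kappa",
                 main = "Channel training traces", ...)
  cols <- c("#d62728", "#2ca02c", "#1f77b4", "#bcbd22")
  for (i in seq_along(traces)) {
    graphics::lines(traces[[i]]$epoch, traces[[i]]$val_kappa, col = cols[i])
    graphics::abline(v = x$channels[[i]]$best_epoch, col = cols[i], lty = 3)
  }
  graphics::legend("bottomright", legend = names(x$channels), col = cols,
                   lty = 1, cex = 0.8)
  invisible(x)
}
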