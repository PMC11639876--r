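# A hand-built ensemble whose channels emit fixed probability vectors: all
# weights zero, output bias = log of the target distribution.
fixed_channel <- function(probs, panel, n_inputs) {
  spec <- channel_spec(n_inputs)
  par <- ovsubtype:::nn_init(spec)
  for (l in seq_along(par$W)) par$W[[l]][] <- 0
  par$b[[length(par$b)]] <- log(pmax(probs, 1e-9))
  structure(list(par = par, spec = spec, best_epoch = 1L, best_kappa = 1,
                 control_gene = NA_character_,
                 scaling = structure(list(
                   mean = stats::setNames(rep(0, n_inputs), panel$genes$gene),
                   sd = stats::setNames(rep(1, n_inputs), panel$genes$gene)),
                   class = "ov_scaling")),
            class = "ov_channel")
}

toy_panel <- function(n = 6) {
  ovsubtype:::new_panel(
    genes = data.frame(gene = sprintf("sig%02d", seq_len(n)),
                       module = rep(bipartition_names(), length.out = n),
                       direction = rep(c("up", "down"), length.out = n),
                       stringsAsFactors = FALSE),
    controls = c("ctlA", "ctlB", "ctlC", "ctlD"))
}

test_that("stratified splitting respects the 2:1 ratio, the seed, and partitions", {
  lab <- label_table(sprintf("u%03d", 1:120), rep(subtype_levels(), each = 30))
  sp <- split_train_test(lab, c(2, 1), seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$test, 40)
  for (s in subtype_levels()) {
    ids <- lab$unit_id[lab$subtype == s]
    expect_length(intersect(sp$train, ids), 20)
  }
  expect_setequal(c(sp$train, sp$test), lab$unit_id)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_train_test(lab, c(2, 1), seed = 5), sp)
  expect_false(identical(split_train_test(lab, c(2, 1), seed = 6), sp))
  lab2 <- label_table(c("a", "b", "c"), c("D", "D", "I"))
  expect_error(split_train_test(lab2), "fewer than 3")
})

test_that("the ensemble averages channel probabilities", {
  panel <- toy_panel()
  n <- nrow(panel$genes)
  chans <- list(fixed_channel(c(1, 0, 0, 0), panel, n),
                fixed_channel(c(1, 0, 0, 0), panel, n),
                fixed_channel(c(0, 1, 0, 0), panel, n),
                fixed_channel(c(0, 1, 0, 0), panel, n))
  for (i in seq_along(chans)) chans[[i]]$control_gene <- panel$controls[i]
  names(chans) <- panel$controls
  model <- build_ensemble(chans, panel)
  e <- matrix(rnorm((n + 4) * 3), n + 4, 3,
              dimnames = list(c(panel$genes$gene, panel$controls),
                              paste0("u", 1:3)))
  P <- ovsubtype:::ensemble_probs(model, e)
  expect_equal(unname(P[, 1]), c(0.5, 0.5, 0, 0), tolerance = 1e-6)
  expect_equal(unname(colSums(P)), rep(1, 3), tolerance = 1e-6)

  # identical channels reduce to a single channel
  same <- chans; for (i in 1:4) { same[[i]] <- chans[[1]]; same[[i]]$control_gene <- panel$controls[i] }
  model2 <- build_ensemble(same, panel)
  P2 <- ovsubtype:::ensemble_probs(model2, e)
  expect_equal(unname(P2[, 2]), c(1, 0, 0, 0), tolerance = 1e-6)

  expect_error(build_ensemble(chans[1:3], panel), "exactly 4")
})

test_that("ensemble probabilities are convex combinations summing to one", {
  panel <- toy_panel()
  n <- nrow(panel$genes)
  set.seed(12)
  chans <- lapply(1:4, function(i) {
    ch <- fixed_channel(rep(0.25, 4), panel, n)
    # random nonzero weights in the last layer -> nondegenerate outputs
    ch$par$b[[length(ch$par$b)]] <- rnorm(4)
    ch$par$W[[length(ch$par$W)]][] <- rnorm(4 * 50, sd = 0.1)
    ch$control_gene <- panel$controls[i]
    ch
  })
  names(chans) <- panel$controls
  model <- build_ensemble(chans, panel)
  e <- matrix(rnorm((n + 4) * 10), n + 4, 10,
              dimnames = list(c(panel$genes$gene, panel$controls),
                              paste0("u", 1:10)))
  P <- ovsubtype:::ensemble_probs(model, e)
  expect_equal(unname(colSums(P)), rep(1, 10), tolerance = 1e-6)
  chP <- lapply(model$channels, function(ch) {
    feats <- control_normalize(e, model$panel, ch$control_gene)
    ovsubtype:::nn_forward(ch$par, apply_scaling(feats, ch$scaling))
  })
  expect_equal(P, Reduce(`+`, chP) / 4, ignore_attr = TRUE)
  expect_true(all(P >= pmin(chP[[1]], chP[[2]], chP[[3]], chP[[4]]) - 1e-12))
})

test_that("evaluation metrics match hand computations", {
  # perfect predictions
  lab <- label_table(paste0("u", 1:40), rep(subtype_levels(), 10))
  P <- ovsubtype:::one_hot(ovsubtype:::labels_for_units(lab, lab$unit_id))
  colnames(P) <- lab$unit_id
  preds <- ovsubtype:::probs_to_predictions(P + 1e-9, 0.2)
  ev <- evaluate_predictions(preds, lab)
  expect_equal(unname(ev$overall["accuracy"]), 1)
  expect_equal(unname(ev$overall["kappa"]), 1)
  expect_true(all(ev$per_class$sensitivity == 1))
  expect_true(all(ev$per_class$auc == 1))

  # binary collapse with confusion [[8,2],[2,8]]: sens/spec 0.8, kappa 0.6
  truth2 <- label_table(paste0("v", 1:20), rep(c("D", "I"), each = 10))
  labels2 <- c(rep("D", 8), rep("I", 2), rep("I", 8), rep("D", 2))
  P2 <- ovsubtype:::one_hot(stats::setNames(labels2, truth2$unit_id)) * 0.9 + 0.025
  colnames(P2) <- truth2$unit_id
  preds2 <- ovsubtype:::probs_to_predictions(P2, 2)
  ev2 <- evaluate_predictions(preds2, truth2)
  d_row <- ev2$per_class[ev2$per_class$subtype == "D", ]
  expect_equal(d_row$sensitivity, 0.8)
  expect_equal(d_row$specificity, 0.8)
  expect_equal(d_row$kappa, 0.6)
  # subtypes absent from the truth are reported as missing
  expect_true(is.na(ev2$per_class$sensitivity[ev2$per_class$subtype == "M"]))

  # uniform-random probabilities give chance-level macro AUC
  set.seed(14)
  n <- 1000
  truth3 <- label_table(paste0("w", 1:n),
                        sample(subtype_levels(), n, replace = TRUE))
  R <- matrix(runif(4 * n), 4, n, dimnames = list(subtype_levels(),
                                                  truth3$unit_id))
  R <- sweep(R, 2, colSums(R), "/")
  ev3 <- evaluate_predictions(ovsubtype:::probs_to_predictions(R, 0.2), truth3)
  expect_gt(unname(ev3$overall["macro_auc"]), 0.4)
  expect_lt(unname(ev3$overall["macro_auc"]), 0.6)
})

test_that("model bundles save and load to identical predictions", {
  sm <- cached_small_model()
  dir <- withr::local_tempdir()
  save_model(sm$model, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.rds", "panel.tsv",
                                               "scaling.json", "config.json",
                                               "training_report.tsv")))))
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$config$seed, sm$model$config$seed)
  expect_true(nzchar(meta$version$package))

  back <- load_model(dir)
  p1 <- predict_units(sm$model, sm$expr)
  p2 <- predict_units(back, sm$expr)
  for (pc in paste0("p_", subtype_levels()))
    expect_equal(p2[[pc]], p1[[pc]], tolerance = 1e-6)

  # a bundle missing one channel refuses to load
  w <- readRDS(file.path(dir, "weights.rds"))
  saveRDS(w[1:3], file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "expected 4")

  # format version mismatch is an explicit error
  saveRDS(w, file.path(dir, "weights.rds"))
  meta_raw <- jsonlite::read_json(file.path(dir, "config.json"))
  meta_raw$version$bundle_format <- 99
  jsonlite::write_json(meta_raw, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir), "format")
})

test_that("predict() dispatches on unit kind and is deterministic", {
  sm <- cached_small_model()
  counts <- sm$sim$counts
  p1 <- predict(sm$model, counts)
  p2 <- predict(sm$model, counts)
  expect_identical(p1, p2)
  # a duplicated unit gets the same prediction as its twin
  expect_equal(unlist(p1[1, paste0("p_", subtype_levels())]),
               unlist(p1[1, paste0("p_", subtype_levels())]))
  # missing panel genes are an error on the bulk path
  expr_missing <- sm$expr[-match(sm$panel$genes$gene[1], rownames(sm$expr)), ]
  expect_error(predict_units(sm$model, expr_missing), "absent")
})
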