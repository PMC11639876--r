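# Small hand-built expression fixture: 16 units (4 per subtype), genes with
# constructed patterns, log2 CPM scale.
sig_fixture <- function() {
  lab <- label_table(sprintf("u%02d", 1:16), rep(c("D", "I", "M", "P"), each = 4))
  sub <- rep(c("D", "I", "M", "P"), each = 4)
  set.seed(17)
  noise <- function() rnorm(16, 0, 0.05)
  e <- rbind(
    di_up   = 8 + 2 * (sub %in% c("D", "I")) + noise(),
    d_down  = 8 - 2 * (sub == "D") + noise(),
    flat    = rep(8, 16),  # exactly constant: every bipartition test degenerates
    dp_up   = 8 + 2 * (sub %in% c("D", "P")) + noise())
  colnames(e) <- lab$unit_id
  list(expr = e, labels = lab)
}

test_that("DE gene union behaves as a set union", {
  mk <- function(genes, flagged) {
    structure(data.frame(gene = genes, is_de = genes %in% flagged),
              class = c("ov_de", "data.frame"))
  }
  universe <- c("g1", "g2", "g3", "g4")
  expect_equal(union_de_genes(list(mk(universe, c("g1", "g2")),
                                   mk(universe, c("g2", "g3")))),
               c("g1", "g2", "g3"))
  expect_equal(union_de_genes(list(mk(universe, character()))), character())
})

test_that("expression mask is a detection-fraction filter", {
  m <- matrix(c(1, 0, 0, 2, 0, 0, 3, 1, 0, 4, 0, 1), nrow = 3,
              dimnames = list(c("always", "rare", "half"), paste0("u", 1:4)))
  m <- m + 0; m["always", ] <- c(1, 2, 3, 4)
  m["rare", ] <- c(0, 0, 0, 1)
  m["half", ] <- c(0, 0, 2, 2)
  expect_true("always" %in% expression_mask(m, 0.5))
  expect_false("rare" %in% expression_mask(m, 0.5))
  expect_true("half" %in% expression_mask(m, 0.5))
  # threshold 1.0 is the intersection of per-unit nonzero sets
  expect_equal(expression_mask(m, 1.0), "always")
  # an all-zero gene is excluded at any threshold (build via valid matrix)
  m2 <- rbind(m, zero = 0)
  expect_false("zero" %in% expression_mask(m2, 1e-9))
})

test_that("module assignment picks the sharpest bipartition with direction", {
  fx <- sig_fixture()
  res <- assign_modules(rownames(fx$expr), fx$expr, fx$labels)
  expect_equal(res$module[res$gene == "di_up"], "DIvsMP")
  expect_equal(res$direction[res$gene == "di_up"], "up")
  expect_equal(res$module[res$gene == "d_down"], "DvsOther")
  expect_equal(res$direction[res$gene == "d_down"], "down")
  expect_equal(res$module[res$gene == "dp_up"], "DPvsIM")
  expect_equal(res$direction[res$gene == "dp_up"], "up")
  expect_false("flat" %in% res$gene)
  expect_true("flat" %in% attr(res, "dropped"))
})

test_that("module assignment is invariant to unit order", {
  fx <- sig_fixture()
  res1 <- assign_modules(rownames(fx$expr), fx$expr, fx$labels)
  set.seed(1)
  perm <- sample(ncol(fx$expr))
  res2 <- assign_modules(rownames(fx$expr), fx$expr[, perm],
                         fx$labels[perm, ])
  expect_equal(res1, res2, ignore_attr = TRUE)
})

test_that("control-gene selection enforces all three criteria", {
  genes <- c("stable_high", "stable_low", "de_gene", "stable_high2",
             "stable_high3", "stable_high4", "stable_high5")
  mk_de <- function(lfc) {
    structure(data.frame(gene = genes, log2fc = lfc,
                         p_mw = c(.8, .9, .01, .7, .6, .5, .9),
                         p_qlf = c(.9, .8, .20, .9, .9, .9, .8),
                         fdr_mw = 1, fdr_qlf = 1,
                         is_de = FALSE),
              class = c("ov_de", "data.frame"))
  }
  res <- list(mk_de(c(0.05, 0.02, 1.5, 0.01, 0.1, 0.12, 0.05)))
  set.seed(41)
  e <- matrix(rnorm(7 * 20, mean = 9, sd = 0.2), 7, 20,
              dimnames = list(genes, sprintf("u%02d", 1:20)))
  e["stable_low", ] <- rnorm(20, 6.5, 0.2)        # below the expression floor
  e["stable_high", ] <- rnorm(20, 9.5, 0.02)      # lowest CV -> ranked first
  lab <- label_table(colnames(e), rep(c("D", "I", "M", "P"), 5))
  picked <- select_control_genes(res, e, lab, k = 4)
  expect_length(picked, 4)
  expect_equal(picked[1], "stable_high")
  expect_false("stable_low" %in% picked)   # expression floor
  expect_false("de_gene" %in% picked)      # |log2fc| and p criteria
  expect_error(select_control_genes(res, e, lab, k = 6), "control candidates")
})

test_that("panel construction recovers planted structure on synthetic data", {
  # scaled-down module layout keeps the planted DE fraction realistic (~6%)
  cfg <- sim_config(n_genes = 800, modules = small_modules(),
                    n_per_subtype = c(D = 30, I = 30, M = 30, P = 30),
                    seed = 71)
  sim <- simulate_bulk(cfg)
  f <- tmm_factors(sim$counts)
  e <- log2cpm(sim$counts, f)
  res <- run_all_designs(e, sim$counts, sim$labels, factors = f)
  panel <- build_panel(res, e, sim$labels)
  truth <- sim$truth$genes

  # panel and controls are disjoint; modules/directions are well-formed
  expect_length(intersect(panel$genes$gene, panel$controls), 0)
  expect_length(panel$controls, 4)
  expect_true(all(panel$genes$module %in% bipartition_names()))
  expect_true(all(panel$genes$direction %in% c("up", "down")))

  # planted bipartition genes come back with the right module and direction
  m <- merge(panel$genes, truth, by = "gene")
  bip <- m[m$pattern %in% bipartition_names(), ]
  n_planted_bip <- sum(truth$pattern %in% bipartition_names(), na.rm = TRUE)
  expect_gt(nrow(bip) / n_planted_bip, 0.85)
  expect_gt(mean(bip$module == bip$pattern & bip$direction.x == bip$direction.y),
            0.9)

  # controls are planted housekeeping genes
  hk <- truth$gene[truth$role == "housekeeping"]
  expect_true(all(panel$controls %in% hk))

  # masks excluding genes remove them from the panel
  mask <- setdiff(truth$gene, panel$genes$gene[1:10])
  panel2 <- build_panel(res, e, sim$labels, masks = list(mask))
  expect_length(intersect(panel2$genes$gene, panel$genes$gene[1:10]), 0)

  # serialization round-trip is lossless
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$genes, panel$genes, ignore_attr = TRUE)
  expect_equal(back$controls, panel$controls)
})
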