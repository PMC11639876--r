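# Shared fitted models, built lazily and cached for the whole test run.
#
# - cached_e2e(): the full default-conditions pipeline (subtype counts
#   108/91/98/116, planted effect 1.5, fixed seed): simulate, ten designs,
#   panel, four-channel training. Built once; several test files score
#   different properties of it.
# - cached_small_model(): a quick low-epoch model on a small cohort for
#   plumbing tests (serialization, CLI, prediction mechanics).

.ov_test_cache <- new.env(parent = emptyenv())

cached_e2e <- function() {
  if (is.null(.ov_test_cache$e2e)) {
    sim <- simulate_bulk(sim_config(seed = 20240301))
    factors <- tmm_factors(sim$counts)
    expr <- log2cpm(sim$counts, factors)
    results <- run_all_designs(expr, sim$counts, sim$labels, factors = factors)
    # multiplatform masks from auxiliary single-cell and spatial datasets
    # sharing the gene universe (the "expressed everywhere" filter)
    aux_cfg <- sim$truth$config
    aux_cfg$seed <- 20240302L
    aux_sc <- simulate_sc(aux_cfg, genes = sim$truth$genes)
    aux_cfg$seed <- 20240303L
    aux_sp <- simulate_spatial(aux_cfg, genes = sim$truth$genes)
    masks <- list(expression_mask(aux_sc$counts, 0.05),
                  expression_mask(aux_sp$counts, 0.05))
    panel <- build_panel(results, expr, sim$labels, masks = masks)
    model <- train_subtype_model(sim$counts, sim$labels, panel,
                                 config = train_config(seed = 42))
    .ov_test_cache$e2e <- list(sim = sim, factors = factors, expr = expr,
                               results = results, panel = panel, model = model)
  }
  .ov_test_cache$e2e
}

cached_small_model <- function() {
  if (is.null(.ov_test_cache$small)) {
    cfg <- sim_config(n_genes = 700, n_per_subtype = c(D = 20, I = 20, M = 20, P = 20),
                      seed = 99)
    sim <- simulate_bulk(cfg)
    factors <- tmm_factors(sim$counts)
    expr <- log2cpm(sim$counts, factors)
    results <- run_all_designs(expr, sim$counts, sim$labels, factors = factors)
    panel <- build_panel(results, expr, sim$labels)
    model <- train_subtype_model(sim$counts, sim$labels, panel,
                                 config = train_config(seed = 7, max_epochs = 30,
                                                       patience = 10))
    .ov_test_cache$small <- list(sim = sim, cfg = cfg, expr = expr,
                                 panel = panel, model = model)
  }
  .ov_test_cache$small
}
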