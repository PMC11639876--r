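# Synthetic count-data generator with the statistical structure the method
# assumes: four subtypes, planted gene modules following the signature
# table's up/down layout (the four D bipartitions plus I/M/P-specific
# columns), stable high-expression housekeeping genes, negative-binomial
# counts with log-normal library sizes, and single-cell / spatial variants
# with shallow depth and dropout. Every emitted dataset carries its ground
# truth so recovery can be scored exactly.

#' Expression patterns a planted gene module can follow
#'
#' The four bipartitions (which have an unambiguous expected module
#' assignment) plus the three one-vs-rest patterns for I, M, P mirroring the
#' subtype-specific signature columns; the latter straddle two bipartitions
#' by construction.
#'
#' @return Character vector of pattern names.
#' @export
module_patterns <- function() {
  c(bipartition_names(), "IvsOther", "MvsOther", "PvsOther")
}

# Per-subtype log2 multipliers for one pattern at planted effect `lfc`:
# 2-vs-2 bipartitions put +lfc/2 on the first side and -lfc/2 on the second;
# 1-vs-3 patterns put the full +lfc on the singleton subtype.
pattern_log2_shift <- function(pattern, lfc) {
  lv <- subtype_levels()
  shift <- stats::setNames(numeric(4), lv)
  if (pattern %in% c("DvsOther", "IvsOther", "MvsOther", "PvsOther")) {
    shift[substr(pattern, 1, 1)] <- lfc
  } else {
    sides <- bipartition_sides()[[pattern]]
    shift[sides$a] <- lfc / 2
    shift[sides$b] <- -lfc / 2
  }
  shift
}

#' Simulation configuration
#'
#' Defaults emulate a labeled bulk RNA-seq training cohort: subtype sample
#' counts 108/91/98/116 (D/I/M/P), planted modules following the signature
#' table's seven up/down columns (4 bipartition modules for D, one
#' subtype-specific column each for I, M, P), planted effect 1.5 log2 units,
#' NB dispersion 0.1 (housekeeping genes 0.02 — stability is what makes a
#' control gene), log-normal library sizes around 1e7, and a background of
#' null genes with log-normal baseline expression.
#'
#' @param n_genes Total number of genes (default 5000, putting the 357
#'   planted module genes at ~7% of the transcriptome — the DE fraction the
#'   signature workflow encounters on real data; a much higher planted
#'   fraction makes compositional CPM shifts and TMM trimming artifacts
#'   unrealistically large).
#' @param modules Data.frame with columns `pattern`, `up`, `down`; defaults
#'   to the seven-column signature layout (0/4, 33/19, 7/2, 1/30 for the D
#'   bipartitions; 29/4, 91/0, 18/119 for I, M, P).
#' @param lfc Planted absolute log2 fold change per module gene (default 1.5).
#' @param n_housekeeping Number of stable high-expression genes (default 20).
#' @param hk_log2cpm Range of housekeeping baseline log2 CPM (default 8.5-10).
#' @param hk_dispersion NB dispersion of housekeeping genes (default 0.02).
#' @param null_log2cpm_mean,null_log2cpm_sd Normal parameters of null-gene
#'   baseline log2 CPM (defaults 5, 2).
#' @param planted_log2cpm Range of module-gene baseline log2 CPM (default 4-8).
#' @param dispersion NB dispersion for non-housekeeping genes (default 0.1).
#' @param lib_meanlog,lib_sdlog Log-normal bulk library-size parameters
#'   (defaults log(1e7), 0.35).
#' @param n_per_subtype Named or positional counts for D, I, M, P (default
#'   c(108, 91, 98, 116)).
#' @param n_cells Cells for [simulate_sc()] (default 500).
#' @param sc_depth_meanlog,sc_depth_sdlog Per-cell depth log-normal
#'   parameters (defaults log(1e4), 0.5).
#' @param dropout Independent zeroing probability for single-cell counts
#'   (default 0.6).
#' @param cells_per_spot Mean cells pooled per spatial spot (default 5).
#' @param grid_nrow,grid_ncol Spatial grid dimensions (defaults 20, 20).
#' @param seed Integer seed.
#' @return List of class `ov_simconfig`.
#' @export
sim_config <- function(n_genes = 5000,
                       modules = data.frame(
                         pattern = module_patterns(),
                         up = c(0L, 33L, 7L, 1L, 29L, 91L, 18L),
                         down = c(4L, 19L, 2L, 30L, 4L, 0L, 119L),
                         stringsAsFactors = FALSE),
                       lfc = 1.5,
                       n_housekeeping = 20,
                       hk_log2cpm = c(8.5, 10),
                       hk_dispersion = 0.02,
                       null_log2cpm_mean = 5, null_log2cpm_sd = 2,
                       planted_log2cpm = c(4, 8),
                       dispersion = 0.1,
                       lib_meanlog = log(1e7), lib_sdlog = 0.35,
                       n_per_subtype = c(D = 108, I = 91, M = 98, P = 116),
                       n_cells = 500,
                       sc_depth_meanlog = log(1e4), sc_depth_sdlog = 0.5,
                       dropout = 0.6,
                       cells_per_spot = 5,
                       grid_nrow = 20, grid_ncol = 20,
                       seed = 1L) {
  stopifnot(all(modules$up >= 0), all(modules$down >= 0),
            all(modules$pattern %in% module_patterns()),
            dispersion > 0, hk_dispersion > 0,
            dropout >= 0, dropout < 1, lfc >= 0)
  n_module <- sum(modules$up + modules$down)
  if (n_module + n_housekeeping > n_genes)
    stop(sprintf("modules (%d) + housekeeping (%d) exceed n_genes (%d)",
                 n_module, n_housekeeping, n_genes))
  if (is.null(names(n_per_subtype))) names(n_per_subtype) <- subtype_levels()
  structure(list(n_genes = n_genes, modules = modules, lfc = lfc,
                 n_housekeeping = n_housekeeping, hk_log2cpm = hk_log2cpm,
                 hk_dispersion = hk_dispersion,
                 null_log2cpm_mean = null_log2cpm_mean,
                 null_log2cpm_sd = null_log2cpm_sd,
                 planted_log2cpm = planted_log2cpm,
                 dispersion = dispersion,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 n_per_subtype = n_per_subtype,
                 n_cells = n_cells,
                 sc_depth_meanlog = sc_depth_meanlog,
                 sc_depth_sdlog = sc_depth_sdlog,
                 dropout = dropout, cells_per_spot = cells_per_spot,
                 grid_nrow = grid_nrow, grid_ncol = grid_ncol,
                 seed = as.integer(seed)),
            class = "ov_simconfig")
}

# Draw the gene-level ground truth: roles, patterns, directions, baseline
# relative expression rates (normalized to sum 1) and per-gene dispersions.
sim_gene_truth <- function(cfg) {
  n_module <- sum(cfg$modules$up + cfg$modules$down)
  n_null <- cfg$n_genes - n_module - cfg$n_housekeeping
  gene <- sprintf("G%05d", seq_len(cfg$n_genes))
  role <- c(rep("module", n_module), rep("housekeeping", cfg$n_housekeeping),
            rep("null", n_null))
  pattern <- rep(NA_character_, cfg$n_genes)
  direction <- rep(NA_character_, cfg$n_genes)
  i <- 1
  for (r in seq_len(nrow(cfg$modules))) {
    for (d in c("up", "down")) {
      k <- cfg$modules[[d]][r]
      if (k > 0) {
        pattern[i:(i + k - 1)] <- cfg$modules$pattern[r]
        direction[i:(i + k - 1)] <- d
        i <- i + k
      }
    }
  }
  base_l2 <- numeric(cfg$n_genes)
  base_l2[role == "module"] <- stats::runif(n_module, cfg$planted_log2cpm[1],
                                            cfg$planted_log2cpm[2])
  base_l2[role == "housekeeping"] <- stats::runif(cfg$n_housekeeping,
                                                  cfg$hk_log2cpm[1],
                                                  cfg$hk_log2cpm[2])
  base_l2[role == "null"] <- pmin(pmax(stats::rnorm(
    n_null, cfg$null_log2cpm_mean, cfg$null_log2cpm_sd), 0), 12)
  rate <- 2^base_l2
  rate <- rate / sum(rate)
  disp <- ifelse(role == "housekeeping", cfg$hk_dispersion, cfg$dispersion)
  data.frame(gene = gene, role = role, pattern = pattern,
             direction = direction, base_rate = rate, dispersion = disp,
             lfc = ifelse(role == "module", cfg$lfc, 0),
             stringsAsFactors = FALSE)
}

# Genes x 4 matrix of subtype multipliers from the truth table. Each subtype
# column is renormalized so the total expected rate is 1, keeping expected
# library size equal to the drawn depth. Counts are compositional, so the
# planted modules still shift every other gene's expected CPM between
# subtypes by the (small) module mass imbalance; that shift scales with the
# planted fraction of the transcriptome, which is why the default gene count
# keeps the DE fraction at the realistic ~7% level.
subtype_multipliers <- function(truth, lfc) {
  lv <- subtype_levels()
  mult <- matrix(1, nrow(truth), 4, dimnames = list(truth$gene, lv))
  mod <- which(truth$role == "module")
  for (g in mod) {
    shift <- pattern_log2_shift(truth$pattern[g], lfc)
    if (truth$direction[g] == "down") shift <- -shift
    mult[g, ] <- 2^shift
  }
  sweep(mult, 2, colSums(mult * truth$base_rate), "/")
}

# NB counts for a set of units: mu[g, u] = rate[g] * mult[g, subtype_u] * depth_u.
sim_nb_counts <- function(truth, mult, subtypes, depths, unit_ids) {
  mu <- sweep(mult[, as.character(subtypes), drop = FALSE], 2, depths, "*") *
    truth$base_rate
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / truth$dispersion, ncol(mu))),
                   nrow(mu), ncol(mu), dimnames = list(truth$gene, unit_ids))
  counts
}

#' Simulate a labeled bulk RNA-seq cohort
#'
#' Gene baseline rates are drawn from the configured log-normal/uniform
#' mixtures, subtype effects are applied multiplicatively per planted module
#' (a `DIvsMP` up gene is elevated in D and I units and reduced in M and P),
#' counts are negative-binomial at `rate * library size`, and housekeeping
#' genes have zero planted effect with a high stable baseline. Deterministic
#' under the configured seed.
#'
#' @param cfg [sim_config()].
#' @param genes Optional gene-truth table from a previous simulation (its
#'   `truth$genes`), so that several datasets share one gene universe —
#'   baselines, roles and planted patterns — the way real cohorts share one
#'   transcriptome. Default: drawn fresh from the seed.
#' @return List with `counts` (`ov_counts`, bulk), `labels`
#'   ([label_table()]), `truth` (list with per-gene `genes` table, per-unit
#'   `units` table, and the config).
#' @export
simulate_bulk <- function(cfg = sim_config(), genes = NULL) {
  set.seed(cfg$seed)
  truth <- if (is.null(genes)) sim_gene_truth(cfg) else genes
  mult <- subtype_multipliers(truth, cfg$lfc)
  n <- sum(cfg$n_per_subtype)
  subtypes <- factor(rep(names(cfg$n_per_subtype), cfg$n_per_subtype),
                     levels = subtype_levels())
  unit_ids <- sprintf("S%04d", seq_len(n))
  depths <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)
  counts <- sim_nb_counts(truth, mult, subtypes, depths, unit_ids)
  keep <- colSums(counts) > 0
  counts <- count_matrix(counts[, keep, drop = FALSE], unit_kind = "bulk")
  labels <- label_table(unit_ids[keep], as.character(subtypes)[keep])
  list(counts = counts, labels = labels,
       truth = list(genes = truth,
                    units = data.frame(unit_id = unit_ids[keep],
                                       subtype = as.character(subtypes)[keep],
                                       depth = depths[keep],
                                       stringsAsFactors = FALSE),
                    config = cfg))
}

#' Simulate droplet single-cell RNA-seq counts
#'
#' Per-cell subtype is drawn from `weights`; per-cell depth is log-normal and
#' much smaller than bulk; counts are negative-binomial at the bulk-like
#' expected rate thinned to the cell depth, followed by independent dropout
#' zeroing at the configured rate. Cells left with a zero library are
#' discarded (recorded in the truth table).
#'
#' @param cfg [sim_config()].
#' @param weights Subtype mixture weights (length 4, sums to 1), in D, I, M,
#'   P order.
#' @param genes Optional shared gene-truth table (see [simulate_bulk()]).
#' @return List with `counts` (`ov_counts`, cell) and `truth`.
#' @export
simulate_sc <- function(cfg = sim_config(), weights = c(0.25, 0.25, 0.25, 0.25),
                        genes = NULL) {
  stopifnot(length(weights) == 4, abs(sum(weights) - 1) < 1e-8,
            all(weights >= 0))
  set.seed(cfg$seed)
  truth <- if (is.null(genes)) sim_gene_truth(cfg) else genes
  mult <- subtype_multipliers(truth, cfg$lfc)
  subtypes <- factor(sample(subtype_levels(), cfg$n_cells, replace = TRUE,
                            prob = weights), levels = subtype_levels())
  unit_ids <- sprintf("CELL%05d", seq_len(cfg$n_cells))
  depths <- stats::rlnorm(cfg$n_cells, cfg$sc_depth_meanlog, cfg$sc_depth_sdlog)
  counts <- sim_nb_counts(truth, mult, subtypes, depths, unit_ids)
  if (cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(counts), 1, 1 - cfg$dropout),
                   nrow(counts), ncol(counts))
    counts <- counts * mask
  }
  keep <- colSums(counts) > 0
  cm <- count_matrix(counts[, keep, drop = FALSE], unit_kind = "cell")
  list(counts = cm,
       truth = list(genes = truth,
                    units = data.frame(unit_id = unit_ids,
                                       subtype = as.character(subtypes),
                                       depth = depths, kept = keep,
                                       stringsAsFactors = FALSE),
                    config = cfg))
}

#' Build a region map with given subtype area fractions
#'
#' Assigns grid cells (column-major bands) to subtypes so that area
#' fractions match `fractions` to grid resolution.
#'
#' @param nrow,ncol Grid dimensions.
#' @param fractions Named numeric over a subset of D, I, M, P, summing to 1.
#' @return Character matrix (`nrow` x `ncol`) of subtype codes.
#' @export
region_map_fractions <- function(nrow, ncol, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(names(fractions) %in% subtype_levels()))
  n <- nrow * ncol
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_left <- n * fractions - sizes
    add <- order(frac_left, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  matrix(rep(names(fractions), sizes), nrow, ncol)
}

#' Simulate a Visium-style spatial section
#'
#' One spot per grid cell; each spot's counts are a pool of a small random
#' number of cells of its region's subtype (Poisson around
#' `cells_per_spot`, at least one), drawn with the single-cell depth model
#' but without extra dropout (pooling averages it out). Coordinates follow
#' the positions-table convention (0-based rows/columns, pixel coordinates a
#' fixed multiple).
#'
#' @param cfg [sim_config()].
#' @param region_map Character matrix (`grid_nrow` x `grid_ncol`) of subtype
#'   codes; default a half/half M|P split.
#' @param genes Optional shared gene-truth table (see [simulate_bulk()]).
#' @return List with `counts` (`ov_counts`, spot), `coords`
#'   ([spatial_coords()]), `truth` (incl. per-spot region subtype).
#' @export
simulate_spatial <- function(cfg = sim_config(),
                             region_map = region_map_fractions(
                               cfg$grid_nrow, cfg$grid_ncol,
                               c(M = 0.5, P = 0.5)),
                             genes = NULL) {
  stopifnot(is.matrix(region_map),
            nrow(region_map) == cfg$grid_nrow,
            ncol(region_map) == cfg$grid_ncol,
            all(region_map %in% subtype_levels()))
  set.seed(cfg$seed)
  truth <- if (is.null(genes)) sim_gene_truth(cfg) else genes
  mult <- subtype_multipliers(truth, cfg$lfc)
  grid <- expand.grid(row = seq_len(cfg$grid_nrow) - 1L,
                      col = seq_len(cfg$grid_ncol) - 1L)
  n <- nrow(grid)
  region <- region_map[cbind(grid$row + 1L, grid$col + 1L)]
  unit_ids <- sprintf("SPOT_%02d_%02d", grid$row, grid$col)
  ncells <- pmax(1L, stats::rpois(n, cfg$cells_per_spot))
  depths <- vapply(ncells, function(k)
    sum(stats::rlnorm(k, cfg$sc_depth_meanlog, cfg$sc_depth_sdlog)),
    numeric(1))
  counts <- sim_nb_counts(truth, mult, factor(region, subtype_levels()),
                          depths, unit_ids)
  keep <- colSums(counts) > 0
  cm <- count_matrix(counts[, keep, drop = FALSE], unit_kind = "spot")
  coords <- spatial_coords(unit_ids = unit_ids, row = grid$row, col = grid$col,
                           x_px = grid$col * 100 + 50,
                           y_px = grid$row * 100 + 50,
                           in_tissue = keep)
  list(counts = cm, coords = coords,
       truth = list(genes = truth,
                    units = data.frame(unit_id = unit_ids, subtype = region,
                                       row = grid$row, col = grid$col,
                                       n_cells = ncells, depth = depths,
                                       kept = keep, stringsAsFactors = FALSE),
                    config = cfg))
}
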