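## End-to-end orchestration: calibrate -> fit -> AIC-select -> stochastic
## map -> null-simulate -> binned, null-subtracted rate curves, globally and
## per clade.  One top-level seed deterministically spawns every
## per-tree / per-map / per-null substream, so a run is reproducible from
## its config alone.

#' Pipeline configuration
#'
#' @param tree a `time_tree` (with tip stratigraphic intervals) or a path to
#'   a Newick/NEXUS file.
#' @param tip_ranges tip-range data frame or CSV path
#'   (`taxon,areas,first_ma,last_ma`).
#' @param adjacency adjacency matrix, CSV path, or `NULL` (fully connected,
#'   with a warning at run time).
#' @param areas area codes; defaults to the adjacency matrix's dimnames.
#' @param stages stage table, CSV path, or `NULL` for the packaged
#'   Carboniferous--Permian table.
#' @param variants cladogenesis variants to fit and compare.
#' @param n_trees number of calibrated tree replicates (polytomy resolution +
#'   tip-age draw + minimum-age dating per replicate).
#' @param n_maps stochastic maps per tree.
#' @param n_null null histories per tree.
#' @param max_range_size range-size cap.
#' @param root_max maximum root age (Ma); the tetrapod analysis used 409.4.
#' @param min_branch minimum branch duration (Myr).
#' @param window study window `c(older, younger)` Ma; bins and rate curves
#'   are clipped to it, and tips first appearing after its younger edge are
#'   dropped after calibration.  `NULL` uses the stage table's span.
#' @param clades named list of tip-label vectors for per-clade rate curves.
#' @param se_mode `"pooled"` or `"per_tree"` (see [aggregate_series()]).
#' @param seed top-level integer seed.
#' @param out_dir output directory; `NULL` for an in-memory run only.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tree, tip_ranges, adjacency = NULL, areas = NULL,
                            stages = NULL, variants = CLADO_VARIANTS,
                            n_trees = 5L, n_maps = 5L, n_null = 5L,
                            max_range_size = 2L, root_max = 409.4,
                            min_branch = 0.1, window = NULL,
                            clades = list(), se_mode = "pooled",
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_trees >= 1L, n_maps >= 1L, n_null >= 1L)
  structure(list(tree = tree, tip_ranges = tip_ranges, adjacency = adjacency,
                 areas = areas, stages = stages,
                 variants = match.arg(variants, CLADO_VARIANTS,
                                      several.ok = TRUE),
                 n_trees = as.integer(n_trees), n_maps = as.integer(n_maps),
                 n_null = as.integer(n_null),
                 max_range_size = as.integer(max_range_size),
                 root_max = root_max, min_branch = min_branch,
                 window = window, clades = clades, se_mode = se_mode,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' File paths in the YAML are interpreted relative to the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is needed to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (f in c("tree", "tip_ranges", "adjacency", "stages")) {
    if (!is.null(y[[f]]) && is.character(y[[f]])) y[[f]] <- rel(y[[f]])
  }
  do.call(pipeline_config, y)
}

resolve_inputs <- function(config) {
  tree <- config$tree
  if (is.character(tree)) tree <- read_tree(tree)
  tips <- config$tip_ranges
  if (is.character(tips)) tips <- read_tip_ranges(tips)
  ## tree tips may lack strat ages: take them from the tip-range table
  strat <- tip_strat(tips)
  tree$tip_fad[names(strat$fad)] <- strat$fad
  tree$tip_lad[names(strat$lad)] <- strat$lad
  adjacency <- config$adjacency
  if (is.character(adjacency)) adjacency <- read_adjacency(adjacency)
  areas <- config$areas
  if (is.null(areas)) {
    areas <- if (!is.null(adjacency)) rownames(adjacency) else {
      sort(unique(trimws(unlist(strsplit(tips$areas, "[+;,]")))))
    }
  }
  if (is.null(adjacency)) {
    warning("no adjacency matrix supplied: assuming all areas adjacent")
  }
  stages <- config$stages
  if (is.null(stages)) stages <- read_stage_table()
  if (is.character(stages)) stages <- read_stage_table(stages)
  window <- config$window
  if (is.null(window)) window <- c(max(stages$older_ma), min(stages$younger_ma))
  stages <- stages[stages$older_ma <= window[1L] + 1e-9 &
                     stages$younger_ma >= window[2L] - 1e-9, ]
  if (nrow(stages) == 0L) stop("study window covers no stage")
  class(stages) <- c("stage_table", "data.frame")
  space <- build_state_space(areas, adjacency,
                             max_range_size = config$max_range_size)
  list(tree = tree, tips = tips, space = space, stages = stages,
       window = window)
}

#' Run the full dispersal/vicariance pipeline
#'
#' Stages, in order, all seeded from `config$seed`:
#' 1. build `n_trees` calibrated tree replicates (random polytomy
#'    resolution, uniform tip-age draws, minimum-age dating under
#'    `root_max`, post-window tips dropped);
#' 2. fit every requested cladogenesis variant to each replicate and pick
#'    the best variant by total AIC across replicates;
#' 3. sample `n_maps` stochastic biogeographic histories per tree under the
#'    per-tree best-variant fit;
#' 4. simulate `n_null` null histories per tree under the same fit;
#' 5. bin dispersal and vicariance events into half-stage bins, normalise by
#'    bin duration, average, subtract the null mean, attach SE bands —
#'    globally and for each configured clade.
#'
#' When `out_dir` is set, writes `aic_table.csv`, `ancestral_ranges.csv`,
#' `rates_global.csv`, one `rates_<clade>.csv` per clade, the calibrated
#' trees, and `manifest.json` (config summary, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `aic`, `best_variant`, `fits`, `trees`,
#'   `histories`, `null_histories`, `rates` (global `rate_series`),
#'   `clade_rates`, `marginals`, `space`, `bins`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_inputs(config)
  bins <- make_substage_bins(inp$stages)
  seeds <- derive_seeds(config$seed, 3L + 2L * config$n_trees)
  stage <- "calibrate"
  out <- tryCatch({
    ## -- calibrate replicates ------------------------------------------
    trees <- lapply(seq_len(config$n_trees), function(i) {
      t <- resolve_polytomies(inp$tree, seed = seeds[2L + i])
      t <- draw_tip_ages(t, seed = seeds[2L + config$n_trees + i])
      t <- calibrate_node_ages(t, root_max = config$root_max,
                               min_branch = config$min_branch)
      t$clades <- lapply(config$clades, intersect, y = t$phy$tip.label)
      drop_post_window_clades(t, window_end = inp$window[2L])
    })
    ## -- fit variants, AIC-select --------------------------------------
    stage <- "fit"
    fits <- lapply(trees, function(t) {
      fl <- lapply(config$variants, function(v) {
        fit_ml(t, inp$tips, variant = v, space = inp$space)
      })
      names(fl) <- config$variants
      fl
    })
    if (length(config$variants) > 1L) {
      total <- vapply(config$variants, function(v) {
        sum(vapply(fits, function(f) f[[v]]$logLik, numeric(1)))
      }, numeric(1))
      k_tot <- 2L * config$n_trees
      aic <- data.frame(variant = config$variants,
                        logLik = total, k = k_tot,
                        AIC = 2 * k_tot - 2 * total)
      aic <- aic[order(aic$AIC), ]
      aic$dAIC <- aic$AIC - aic$AIC[1L]
      rownames(aic) <- NULL
      best_variant <- aic$variant[1L]
    } else {
      best_variant <- config$variants
      aic <- NULL
    }
    best_fits <- lapply(fits, function(f) f[[best_variant]])
    ## -- stochastic maps ------------------------------------------------
    stage <- "map"
    histories <- sample_histories(
      trees, inp$tips, lapply(best_fits, function(f) f$model), inp$space,
      n_maps = config$n_maps, seed = seeds[1L])
    tree_id <- rep(seq_len(config$n_trees), each = config$n_maps)
    ## -- null ensemble ---------------------------------------------------
    stage <- "null"
    null_seeds <- derive_seeds(seeds[2L], config$n_trees * config$n_null)
    null_histories <- vector("list", config$n_trees * config$n_null)
    idx <- 0L
    for (ti in seq_len(config$n_trees)) {
      for (j in seq_len(config$n_null)) {
        idx <- idx + 1L
        null_histories[[idx]] <- simulate_null_history(
          trees[[ti]], best_fits[[ti]]$model, inp$space,
          seed = null_seeds[idx])
      }
    }
    ## -- rates -----------------------------------------------------------
    stage <- "rates"
    obs <- lapply(histories, function(h) {
      counts_to_rates(bin_events(h$events, bins, warn = FALSE), bins)
    })
    nl <- lapply(null_histories, function(h) {
      counts_to_rates(bin_events(h$events, bins, warn = FALSE), bins)
    })
    nmat <- vapply(nl, function(p) p$rate, numeric(nrow(nl[[1L]])))
    null_mean <- cbind(nl[[1L]][, c("bin", "kind")],
                       rate = rowMeans(matrix(nmat, nrow = nrow(nl[[1L]]))))
    rates <- aggregate_series(obs, null_mean = null_mean, bins = bins,
                              clade = "all", se_mode = config$se_mode,
                              tree_id = tree_id)
    clade_rates <- lapply(names(config$clades), function(cl) {
      clade_series(histories, null_histories, clade = cl, bins = bins,
                   se_mode = config$se_mode, tree_id = tree_id)
    })
    names(clade_rates) <- names(config$clades)
    ## -- marginals on the first replicate -------------------------------
    stage <- "marginals"
    marginals <- ancestral_marginals(trees[[1L]], inp$tips,
                                     best_fits[[1L]]$model, inp$space)
    list(aic = aic, best_variant = best_variant, fits = best_fits,
         trees = trees, histories = histories,
         null_histories = null_histories, rates = rates,
         clade_rates = clade_rates, marginals = marginals,
         space = inp$space, bins = bins, seed = config$seed)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed (seed ", config$seed, "): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  invisible(out)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(out$aic)) utils::write.csv(out$aic, p("aic_table.csv"),
                                          row.names = FALSE)
  marg <- data.frame(node = rownames(out$marginals),
                     map_range = colnames(out$marginals)[
                       max.col(out$marginals, ties.method = "first")],
                     out$marginals, check.names = FALSE)
  utils::write.csv(marg, p("ancestral_ranges.csv"), row.names = FALSE)
  write_rate_series(out$rates, p("rates_global.csv"))
  for (cl in names(out$clade_rates)) {
    write_rate_series(out$clade_rates[[cl]],
                      p(paste0("rates_", gsub("\\W+", "_", cl), ".csv")))
  }
  writeLines(vapply(out$trees, write_tree, character(1)),
             p("calibrated_trees.nwk"))
  manifest <- list(
    package = "pangaea",
    version = as.character(utils::packageVersion("pangaea")),
    seed = config$seed,
    best_variant = out$best_variant,
    n_trees = config$n_trees, n_maps = config$n_maps,
    n_null = config$n_null,
    max_range_size = config$max_range_size,
    root_max = config$root_max,
    areas = out$space$areas,
    n_bins = nrow(out$bins)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Re-run the analysis with an alternative region system
#'
#' Truncates the tree at `truncate_at` Ma (tips first appearing after the
#' truncation age are dropped; the study window is clipped), swaps in the
#' alternative area codes and adjacency, and runs the standard pipeline.
#' Every retained tip must be mapped in `tip_ranges`.
#'
#' @param config a [pipeline_config()] (its `tip_ranges` must use the
#'   alternative region codes).
#' @param areas,adjacency the alternative region system.
#' @param truncate_at truncation age (Ma); bins stop here.
#' @return as [run_pipeline()].
#' @export
run_region_rerun <- function(config, areas, adjacency, truncate_at) {
  config$areas <- areas
  config$adjacency <- adjacency
  window <- config$window
  if (is.null(window)) {
    st <- if (is.null(config$stages)) read_stage_table() else config$stages
    if (is.character(st)) st <- read_stage_table(st)
    window <- c(max(st$older_ma), min(st$younger_ma))
  }
  config$window <- c(window[1L], max(window[2L], truncate_at))
  run_pipeline(config)
}
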