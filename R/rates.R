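## Binned, duration-normalised, null-subtracted dispersal and vicariance
## rate curves with standard-error bands — the pipeline's headline product.

RATE_KINDS <- c("dispersal", "vicariance")

#' Count events per time bin and kind
#'
#' Cladogenetic bookkeeping kinds (`sympatry`, `subset sympatry`,
#' `range copy`) and `reseed` events never feed the rate curves: only the
#' kinds named in `kinds` are counted.  Events outside the bin window are
#' excluded with a warning (never silently).
#'
#' @param events event data frame (from a `biogeo_history`).
#' @param bins a `time_bins` data frame.
#' @param kinds event kinds to count (default dispersal and vicariance).
#' @param warn warn about out-of-window events.
#' @return data frame `bin, kind, count` with one row per (bin, kind),
#'   bins ordered old to young; attribute `n_excluded` counts dropped events.
#' @export
bin_events <- function(events, bins, kinds = RATE_KINDS, warn = TRUE) {
  validate_bins(bins)
  ev <- events[events$kind %in% kinds, , drop = FALSE]
  lab <- assign_time_to_bin(ev$time_ma, bins, warn = warn)
  n_excluded <- sum(is.na(lab))
  grid <- expand.grid(bin = bins$label, kind = kinds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(lab[!is.na(lab)], levels = bins$label),
               factor(ev$kind[!is.na(lab)], levels = kinds))
  grid$count <- as.vector(tab[cbind(grid$bin, grid$kind)])
  structure(grid, n_excluded = n_excluded)
}

#' Convert per-bin counts to per-Myr rates
#'
#' Each bin's event count is divided by the bin's duration, giving events
#' per Myr.
#'
#' @param counts output of [bin_events()].
#' @param bins the same `time_bins`.
#' @return the counts data frame with a `rate` column added.
#' @export
counts_to_rates <- function(counts, bins) {
  dur <- bins$duration[match(counts$bin, bins$label)]
  if (any(is.na(dur))) stop("counts refer to bins not in the bin table")
  counts$rate <- counts$count / dur
  counts
}

#' Aggregate observed and null rate iterations into a rate series
#'
#' Per bin and kind: the mean rate over stochastic-mapping iterations, the
#' standard error of that mean (sd across iterations / sqrt(n)), the mean
#' null rate, and the corrected rate (observed mean minus null mean).
#' Negative corrected rates are reported as-is — they mean the observed rate
#' is below the chance expectation for this tree shape — and are never
#' clipped.
#'
#' @param observed matrix of per-iteration rates (rows = bin x kind in the
#'   order of `template`, columns = iterations), or a list of
#'   [counts_to_rates()] outputs.
#' @param null_mean data frame from [null_rates()] (or a numeric vector of
#'   per-row null means aligned with `template`), or `NULL` for no
#'   subtraction.
#' @param template data frame with `bin` and `kind` columns defining row
#'   order (taken from the first list element when `observed` is a list).
#' @param bins the `time_bins` used (carried into the output).
#' @param clade clade label for the output (default `"all"`).
#' @param se_mode `"pooled"` (sd over all iterations, the default) or
#'   `"per_tree"` (sd over per-tree iteration means; supply `tree_id`).
#' @param tree_id iteration-to-tree assignment for `se_mode = "per_tree"`.
#' @return a `rate_series` data frame: `bin, older_ma, younger_ma, kind,
#'   clade, observed, null, corrected, se, n_iter`.
#' @export
aggregate_series <- function(observed, null_mean = NULL, template = NULL,
                             bins, clade = "all",
                             se_mode = c("pooled", "per_tree"),
                             tree_id = NULL) {
  se_mode <- match.arg(se_mode)
  if (is.list(observed) && !is.matrix(observed)) {
    template <- observed[[1L]][, c("bin", "kind")]
    observed <- vapply(observed, function(p) p$rate,
                       numeric(nrow(template)))
    observed <- matrix(observed, nrow = nrow(template))
  }
  if (is.null(template)) stop("template (bin/kind row order) is required")
  n_iter <- ncol(observed)
  if (n_iter < 2L) stop("need at least two iterations for a standard error")
  obs_mean <- rowMeans(observed)
  if (se_mode == "pooled") {
    se <- apply(observed, 1L, stats::sd) / sqrt(n_iter)
  } else {
    if (is.null(tree_id)) stop("per_tree SE needs tree_id")
    per_tree <- vapply(split(seq_len(n_iter), tree_id), function(ix) {
      rowMeans(observed[, ix, drop = FALSE])
    }, numeric(nrow(observed)))
    per_tree <- matrix(per_tree, nrow = nrow(observed))
    se <- apply(per_tree, 1L, stats::sd) / sqrt(ncol(per_tree))
  }
  nullv <- if (is.null(null_mean)) {
    rep(0, nrow(template))
  } else if (is.data.frame(null_mean)) {
    key_t <- paste(template$bin, template$kind)
    key_n <- paste(null_mean$bin, null_mean$kind)
    null_mean$rate[match(key_t, key_n)]
  } else {
    null_mean
  }
  if (anyNA(nullv)) stop("null rates do not cover every (bin, kind)")
  bi <- match(template$bin, bins$label)
  out <- data.frame(
    bin = template$bin,
    older_ma = bins$older_ma[bi],
    younger_ma = bins$younger_ma[bi],
    kind = template$kind,
    clade = clade,
    observed = obs_mean,
    null = nullv,
    corrected = obs_mean - nullv,
    se = se,
    n_iter = n_iter,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Restrict a history's events to a clade's subtree
#'
#' Keeps cladogenetic events at nodes inside the clade (its MRCA and
#' descendants) and anagenetic events on branches whose child node is a
#' descendant of the MRCA (the MRCA's own subtending branch is outside).
#'
#' @param history a `biogeo_history`.
#' @param clade clade name (in `tree$clades`) or character vector of tips.
#' @return the filtered event data frame.
#' @export
clade_events <- function(history, clade) {
  tree <- history$tree
  tips <- if (is.character(clade) && length(clade) == 1L &&
              clade %in% names(tree$clades)) tree$clades[[clade]] else clade
  unknown <- setdiff(tips, tree$phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip(s) in clade definition: ", paste(unknown, collapse = ", "))
  }
  mrca <- clade_mrca(tree, tips)
  nodes <- clade_node_set(tree$phy, mrca)
  ev <- history$events
  clado <- !is.na(ev$left)
  keep <- (clado & ev$node %in% nodes) |
    (!clado & ev$node %in% setdiff(nodes, mrca))
  ev[keep, , drop = FALSE]
}

## mrca and all its descendants (tips + internals)
clade_node_set <- function(phy, mrca) {
  nt <- ape::Ntip(phy)
  if (mrca <= nt) return(mrca)
  ch <- children_of(phy)
  out <- integer(0)
  stack <- mrca
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    if (v > nt) stack <- c(stack, ch[[v]])
  }
  sort(out)
}

#' Per-clade rate series from sampled and null histories
#'
#' Applies [clade_events()] to every observed and null history, bins and
#' normalises the restricted events identically to the global series, and
#' aggregates.  The clade null is restricted with exactly the same filter as
#' the observed events (one shared counting path).
#'
#' @param histories list of `biogeo_history` (stochastic maps).
#' @param null_histories list of `biogeo_history` (null simulations), or
#'   `NULL` for no subtraction.
#' @param clade clade name or tip set (see [clade_events()]).
#' @param bins a `time_bins` data frame.
#' @param ... passed to [aggregate_series()].
#' @return a `rate_series` data frame.
#' @export
clade_series <- function(histories, null_histories = NULL, clade, bins, ...) {
  obs <- lapply(histories, function(h) {
    counts_to_rates(bin_events(clade_events(h, clade), bins, warn = FALSE),
                    bins)
  })
  nullv <- NULL
  if (!is.null(null_histories)) {
    nl <- lapply(null_histories, function(h) {
      counts_to_rates(bin_events(clade_events(h, clade), bins, warn = FALSE),
                      bins)
    })
    rates <- vapply(nl, function(p) p$rate, numeric(nrow(nl[[1L]])))
    nullv <- cbind(nl[[1L]][, c("bin", "kind")],
                   rate = rowMeans(matrix(rates, nrow = nrow(nl[[1L]]))))
  }
  lab <- if (is.character(clade) && length(clade) == 1L) clade else "clade"
  aggregate_series(obs, null_mean = nullv, bins = bins, clade = lab, ...)
}
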