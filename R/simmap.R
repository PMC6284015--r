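## Biogeographic stochastic mapping: sample complete timed histories
## (node ranges, cladogenetic events, and endpoint-conditioned anagenetic
## paths along branches) consistent with the fitted model and the tip data.

#' Precompute a stochastic-mapping engine for one tree
#'
#' Runs the pruning pass once and caches the generator, propagators and
#' cladogenesis table so that many histories can be sampled cheaply.
#'
#' @inheritParams biogeo_loglik
#' @return an opaque `biogeo_mapper` object used by [sample_history()].
#' @export
biogeo_mapper <- function(tree, tip_ranges, model, space) {
  tip_ranges <- as_tip_masks(tip_ranges, space)
  pr <- prune_tree(tree, tip_ranges, model, space)
  lik <- sum(root_prior(pr$K) * pr$D[[root_node(tree)]])
  if (lik <= 0) stop("tip data impossible under the model: cannot map")
  out <- list(tree = tree, space = space, model = model, pr = pr,
              tip_ranges = tip_ranges,
              omega = max(-diag(pr$Q)),
              R = NULL)
  if (out$omega > 0) {
    out$R <- diag(nrow(pr$Q)) + pr$Q / out$omega
  }
  class(out) <- "biogeo_mapper"
  out
}

sample_idx <- function(w) {
  tot <- sum(w)
  if (tot <= 0) stop("zero-probability draw: inconsistent upstream sample")
  sample.int(length(w), 1L, prob = w)
}

#' Sample ranges at every node, jointly conditioned on the tip data
#'
#' Root-to-tip conditional draws: the root range from its posterior, then at
#' each node a cladogenetic outcome and daughter node ranges given the
#' parent.  Across repeated draws the per-node range frequencies converge to
#' [ancestral_marginals()].  Set `method = "independent"` to draw each node
#' independently from its marginal instead (sensitivity analysis only: the
#' independent scheme can produce inconsistent parent-child pairs).
#'
#' @param mapper a `biogeo_mapper` (or pass `tree, tip_ranges, model, space`
#'   to [sample_history()] directly).
#' @param seed integer seed.
#' @param method `"joint"` (default) or `"independent"`.
#' @return list with `node_state` (state index per node, length
#'   `Ntip + Nnode`), `branch_top` (state index at the top of each node's
#'   subtending branch) and `clado` (data frame of cladogenetic events).
#' @export
sample_node_ranges <- function(mapper, seed = NULL, method = "joint") {
  method <- match.arg(method, c("joint", "independent"))
  if (!is.null(seed)) set.seed(seed)
  pr <- mapper$pr
  space <- mapper$space
  tree <- mapper$tree
  rt <- root_node(tree)
  K <- pr$K
  node_state <- integer(pr$ntot)
  branch_top <- rep(NA_integer_, pr$ntot)
  if (method == "independent") {
    marg <- ancestral_marginals(tree, mapper$tip_ranges, mapper$model, space)
    for (v in (pr$nt + 1L):pr$ntot) {
      node_state[v] <- sample_idx(marg[paste0("nd", v), ])
    }
    for (i in seq_len(pr$nt)) {
      node_state[i] <- match(mapper$tip_ranges[[tree$phy$tip.label[i]]],
                             space$masks)
    }
    return(list(node_state = node_state, branch_top = branch_top,
                clado = NULL))
  }
  node_state[rt] <- sample_idx(root_prior(K) * pr$D[[rt]])
  clado <- NULL
  stack <- rt
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    s <- node_state[v]
    ev <- pr$clado[[s]]
    li <- match(ev$left, space$masks)
    ri <- match(ev$right, space$masks)
    kids <- pr$ch[[v]]
    w <- ev$weight * pr$M[[kids[1L]]][li] * pr$M[[kids[2L]]][ri]
    r <- sample_idx(w)
    clado <- rbind(clado, data.frame(
      node = v, time_ma = tree$age[v], kind = ev$kind[r],
      before = space$masks[s], left = ev$left[r], right = ev$right[r],
      stringsAsFactors = FALSE))
    tops <- c(li[r], ri[r])
    for (j in 1:2) {
      k <- kids[j]
      branch_top[k] <- tops[j]
      bottom <- sample_idx(pr$P[[k]][tops[j], ] * pr$D[[k]])
      node_state[k] <- bottom
      if (k > pr$nt) stack <- c(stack, k)
    }
  }
  list(node_state = node_state, branch_top = branch_top, clado = clado)
}

## endpoint-conditioned CTMC path by uniformization.  a, b are state indices
## (1..K+1), t the branch duration.  Returns data.frame(u, from, to) with u
## the fractional time of each real jump in (0, 1).
sample_path_uniformized <- function(mapper, a, b, t, n_cap = 10000L) {
  if (t <= 0 || mapper$omega == 0) {
    if (a != b) stop("zero-length branch with differing endpoints")
    return(data.frame(u = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- mapper$R
  mu <- mapper$omega * t
  Pab <- mapper$pr$prop(t)[a, b]
  if (Pab <= 0) stop("endpoints have zero transition probability")
  ## draw jump count: p(n) proportional to dpois(n, mu) * R^n[a, b]
  u <- stats::runif(1L) * Pab
  Rpow <- list(diag(nrow(R)))  # R^0
  acc <- stats::dpois(0, mu) * Rpow[[1L]][a, b]
  n <- 0L
  while (acc < u && n < n_cap) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    acc <- acc + stats::dpois(n, mu) * Rpow[[n + 1L]][a, b]
  }
  if (n == 0L) {
    return(data.frame(u = numeric(0), from = integer(0), to = integer(0)))
  }
  ## jump chain bridge
  states <- integer(n + 1L)
  states[1L] <- a
  for (k in seq_len(n)) {
    w <- R[states[k], ] * Rpow[[n - k + 1L]][, b]
    states[k + 1L] <- sample_idx(w)
  }
  if (states[n + 1L] != b) stop("uniformization bridge failed to hit endpoint")
  times <- sort(stats::runif(n))
  real <- states[-1L] != states[-(n + 1L)]
  data.frame(u = times[real], from = states[-(n + 1L)][real],
             to = states[-1L][real])
}

#' Sample an endpoint-conditioned anagenetic path along one branch
#'
#' Uniformization with an exact jump-count draw; virtual (self) jumps are
#' removed; events are timestamped in Ma within the branch interval.
#'
#' @param mapper a `biogeo_mapper`.
#' @param top_state,bottom_state state indices at the older and younger end.
#' @param older,younger branch interval edges (Ma).
#' @return data frame of anagenetic `EventRecord`s: `kind`
#'   (`"dispersal"`/`"local extinction"`), `time_ma`, `before`, `after`
#'   (range bitmasks).
#' @export
sample_branch_path <- function(mapper, top_state, bottom_state,
                               older, younger) {
  t <- older - younger
  path <- sample_path_uniformized(mapper, top_state, bottom_state, t)
  space <- mapper$space
  n_areas <- length(space$areas)
  K <- length(space$masks)
  mask_of <- function(idx) ifelse(idx > K, 0L, space$masks[pmax(idx, 1L)])
  if (nrow(path) == 0L) {
    return(data.frame(kind = character(0), time_ma = numeric(0),
                      before = integer(0), after = integer(0)))
  }
  before <- mask_of(path$from)
  after <- mask_of(path$to)
  kind <- ifelse(mask_size(after, n_areas) > mask_size(before, n_areas),
                 "dispersal", "local extinction")
  data.frame(kind = kind, time_ma = older - path$u * t,
             before = before, after = after, stringsAsFactors = FALSE)
}

#' Sample one complete biogeographic history
#'
#' Joint node-range draw followed by endpoint-conditioned path sampling on
#' every branch; cladogenetic events are classified from the variant's event
#' table.
#'
#' @inheritParams biogeo_loglik
#' @param mapper optionally a prebuilt [biogeo_mapper()]; when supplied,
#'   `tree`/`tip_ranges`/`model`/`space` are taken from it.
#' @param seed integer seed.
#' @return a `biogeo_history`: list with `tree`, `space`, `node_range`
#'   (bitmask per node), `events` (data frame: `kind`, `time_ma`, `node`,
#'   `before`, `after`, `left`, `right`), `seed`.
#' @export
sample_history <- function(tree = NULL, tip_ranges = NULL, model = NULL,
                           space = NULL, seed = NULL, mapper = NULL) {
  if (is.null(mapper)) {
    mapper <- biogeo_mapper(tree, tip_ranges, model, space)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- sample_node_ranges(mapper, seed = NULL, method = "joint")
  pr <- mapper$pr
  tree <- mapper$tree
  space <- mapper$space
  events <- with(draw$clado, data.frame(
    kind = kind, time_ma = time_ma, node = node, before = before,
    after = NA_integer_, left = left, right = right,
    stringsAsFactors = FALSE))
  e <- tree$phy$edge
  for (i in seq_len(nrow(e))) {
    child <- e[i, 2L]
    anag <- sample_branch_path(mapper, draw$branch_top[child],
                               draw$node_state[child],
                               older = tree$age[e[i, 1L]],
                               younger = tree$age[child])
    if (nrow(anag) > 0L) {
      events <- rbind(events, data.frame(
        kind = anag$kind, time_ma = anag$time_ma, node = child,
        before = anag$before, after = anag$after,
        left = NA_integer_, right = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  events <- events[order(-events$time_ma), ]
  rownames(events) <- NULL
  out <- list(tree = tree, space = space,
              node_range = space$masks[draw$node_state],
              events = events, seed = seed)
  class(out) <- "biogeo_history"
  out
}

#' @exportS3Method base::print
print.biogeo_history <- function(x, ...) {
  cat("biogeo_history:", nrow(x$events), "events on",
      ape::Ntip(x$tree$phy), "tips\n")
  print(table(x$events$kind))
  invisible(x)
}

#' Classify a cladogenetic daughter pair
#'
#' Recomputes the event kind from the ancestor and daughter ranges:
#' vicariance iff the daughters are disjoint non-empty subsets partitioning
#' the ancestor range (impossible for single-area ancestors); sympatry when a
#' single-area ancestor is copied; range copy when a wider ancestor is copied;
#' subset sympatry when one daughter is a single area within the ancestor
#' range and the other keeps the full range.
#'
#' @param ancestor,left,right range bitmasks.
#' @param n_areas number of areas.
#' @return event-kind string.
#' @export
classify_cladogenetic_event <- function(ancestor, left, right, n_areas) {
  sz <- mask_size(ancestor, n_areas)
  if (left == ancestor && right == ancestor) {
    return(if (sz == 1L) "sympatry" else "range copy")
  }
  if (bitwAnd(left, right) == 0L && bitwOr(left, right) == ancestor &&
      left != 0L && right != 0L) {
    if (sz == 1L) stop("vicariance at a single-area ancestor is impossible")
    return("vicariance")
  }
  one_single <- function(a, b) {
    mask_size(a, n_areas) == 1L && bitwAnd(a, ancestor) == a && b == ancestor
  }
  if (one_single(left, right) || one_single(right, left)) {
    return("subset sympatry")
  }
  stop("daughter pair not generatable from ancestor under any variant")
}

#' Re-classify all cladogenetic events of a history
#'
#' Validation helper: recomputes every node's event kind from its ranges and
#' errors if a recorded kind disagrees or a pair is not generatable.
#'
#' @param history a `biogeo_history`.
#' @return the history's cladogenetic events with recomputed `kind`.
#' @export
classify_cladogenetic_events <- function(history) {
  ev <- history$events[!is.na(history$events$left), , drop = FALSE]
  n_areas <- length(history$space$areas)
  ev$kind <- vapply(seq_len(nrow(ev)), function(i) {
    classify_cladogenetic_event(ev$before[i], ev$left[i], ev$right[i],
                                n_areas)
  }, character(1))
  ev
}

#' Validate a biogeographic history
#'
#' Checks the structural invariants shared by data-conditioned and null
#' histories: every range permitted; every dispersal gains exactly one area
#' adjacent to the occupied range; every local extinction loses exactly one
#' area; no vicariance at single-area ancestors; all event times within the
#' tree's time span; branch paths consistent with node ranges.
#'
#' @param history a `biogeo_history`.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_history <- function(history) {
  stopifnot(inherits(history, "biogeo_history"))
  space <- history$space
  tree <- history$tree
  n_areas <- length(space$areas)
  ev <- history$events
  ok_range <- function(m) m %in% space$masks
  span_old <- root_age(tree) + 1e-9
  span_young <- min(tree$age) - 1e-9
  if (any(ev$time_ma > span_old | ev$time_ma < span_young)) {
    stop("event outside the tree's time span")
  }
  anag <- ev[is.na(ev$left), , drop = FALSE]
  for (i in seq_len(nrow(anag))) {
    b <- anag$before[i]; a <- anag$after[i]
    gained <- bitwAnd(a, bitwNot(b))
    lost <- bitwAnd(b, bitwNot(a))
    if (anag$kind[i] == "dispersal") {
      if (mask_size(gained, n_areas) != 1L || lost != 0L) {
        stop("dispersal must gain exactly one area")
      }
      if (!ok_range(a)) stop("dispersal into a range outside the space")
      ga <- mask_areas(gained, n_areas)
      if (!any(space$adjacency[mask_areas(b, n_areas), ga])) {
        stop("dispersal into a non-adjacent area")
      }
    } else if (anag$kind[i] == "local extinction") {
      if (mask_size(lost, n_areas) != 1L || gained != 0L) {
        stop("local extinction must lose exactly one area")
      }
      if (a != 0L && !ok_range(a)) stop("extinction leaves an impermissible range")
    } else if (anag$kind[i] == "reseed") {
      if (mask_size(b, n_areas) != 1L || mask_size(a, n_areas) != 1L) {
        stop("reseed must move between single areas")
      }
      if (a != b &&
          !space$adjacency[mask_areas(b, n_areas), mask_areas(a, n_areas)]) {
        stop("reseed into a non-adjacent area")
      }
    } else {
      stop("unknown anagenetic event kind: ", anag$kind[i])
    }
  }
  clado <- ev[!is.na(ev$left), , drop = FALSE]
  for (i in seq_len(nrow(clado))) {
    kind <- classify_cladogenetic_event(clado$before[i], clado$left[i],
                                        clado$right[i], n_areas)
    if (kind != clado$kind[i]) {
      stop("recorded cladogenetic kind '", clado$kind[i],
           "' disagrees with ranges ('", kind, "')")
    }
    if (kind == "vicariance" && mask_size(clado$before[i], n_areas) == 1L) {
      stop("vicariance at a single-area ancestor")
    }
  }
  ## branch-path endpoint consistency
  check_branch_consistency(history)
  invisible(TRUE)
}

## replay each branch's anagenetic events and confirm they connect the
## parent's daughter range to the child's node range
check_branch_consistency <- function(history) {
  tree <- history$tree
  ev <- history$events
  clado <- ev[!is.na(ev$left), , drop = FALSE]
  e <- tree$phy$edge
  ch <- children_of(tree$phy)
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; v <- e[i, 2L]
    row <- clado[clado$node == p, , drop = FALSE]
    if (nrow(row) != 1L) stop("missing cladogenetic record at node ", p)
    start <- if (ch[[p]][1L] == v) row$left else row$right
    anag <- ev[is.na(ev$left) & ev$node == v, , drop = FALSE]
    anag <- anag[order(-anag$time_ma), , drop = FALSE]
    cur <- start
    for (j in seq_len(nrow(anag))) {
      if (anag$before[j] != cur) stop("branch path discontinuity at node ", v)
      cur <- anag$after[j]
    }
    if (cur != history$node_range[v]) {
      stop("branch path does not end at the child's range (node ", v, ")")
    }
  }
  invisible(TRUE)
}

#' Sample many histories over a set of trees
#'
#' `n_maps` histories per tree, each with its own deterministic sub-seed
#' derived from `seed`.  Histories are processed one at a time: supply `FUN`
#' to reduce each history (e.g. to binned event counts) so the full set is
#' never held in memory.
#'
#' @param trees a `time_tree` or list of them.
#' @param tip_ranges tip ranges (shared across trees).
#' @param model fitted `biogeo_model`, or a list of one model per tree.
#' @param space a `range_space`.
#' @param n_maps histories per tree.
#' @param seed top-level integer seed.
#' @param FUN function applied to each `biogeo_history`; default returns the
#'   history itself.
#' @return list of `FUN` results, length `n_trees * n_maps`.
#' @export
sample_histories <- function(trees, tip_ranges, model, space, n_maps,
                             seed = 1L, FUN = identity) {
  if (inherits(trees, "time_tree")) trees <- list(trees)
  seeds <- derive_seeds(seed, length(trees) * n_maps)
  out <- vector("list", length(trees) * n_maps)
  idx <- 0L
  for (ti in seq_along(trees)) {
    m <- if (is.list(model) && !inherits(model, "biogeo_model")) {
      model[[ti]]
    } else {
      model
    }
    mapper <- biogeo_mapper(trees[[ti]], tip_ranges, m, space)
    for (j in seq_len(n_maps)) {
      idx <- idx + 1L
      out[[idx]] <- FUN(sample_history(mapper = mapper, seed = seeds[idx]))
    }
  }
  out
}

## deterministic substream seeds below 2^31 from one top-level seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
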