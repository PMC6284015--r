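## The null model: forward simulation of biogeographic histories over the
## same tree under the fitted anagenetic rates and cladogenetic event table,
## unanchored to the tip data.  Null histories answer "how many dispersal and
## vicariance events would this tree shape produce by chance?" — their mean
## binned rates are subtracted from the observed (stochastic-mapped) rates.

#' Simulate one null biogeographic history
#'
#' The root range is drawn at random (uniform over the permitted space by
#' default, or uniform over single areas), then ranges evolve forward along
#' every branch under the anagenetic generator, with a cladogenetic outcome
#' drawn from the variant's event table at every node.  The area-adjacency
#' matrix constrains every dispersal, and vicariance never occurs at
#' single-area ancestors, exactly as in the data-conditioned analysis.
#'
#' If a lineage loses its last area (total local extinction) the default
#' policy re-seeds it into a random area adjacent to the lost one (recorded
#' as a `"reseed"` event, which never feeds the rate curves) so the ensemble
#' size stays fixed; `extinct = "discard"` instead throws away the history
#' and restarts it with a fresh sub-seed.
#'
#' @param tree a calibrated, binary `time_tree`.
#' @param model a `biogeo_model`.
#' @param space a `range_space`.
#' @param seed integer seed.
#' @param root_sample `"uniform"` (any permitted range) or `"single"`
#'   (single areas only).
#' @param extinct total-extinction policy: `"reseed"` (default) or
#'   `"discard"`.
#' @param max_restarts restart cap under `extinct = "discard"`.
#' @return a `biogeo_history` (attribute `n_reseeds` counts re-seed events).
#' @export
simulate_null_history <- function(tree, model, space, seed = NULL,
                                  root_sample = c("uniform", "single"),
                                  extinct = c("reseed", "discard"),
                                  max_restarts = 100L) {
  root_sample <- match.arg(root_sample)
  extinct <- match.arg(extinct)
  validate_time_tree(tree)
  if (!is_binary_rooted(tree$phy)) stop("null simulation requires a binary tree")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_restarts)) {
    h <- try_null_history(tree, model, space, root_sample, extinct)
    if (!is.null(h)) {
      h$seed <- seed
      return(h)
    }
  }
  stop("null history discarded ", max_restarts,
       " times (total extinction); use extinct = 'reseed'")
}

try_null_history <- function(tree, model, space, root_sample, extinct) {
  n_areas <- length(space$areas)
  Q <- anagenetic_generator(space, model)
  K <- length(space$masks)
  clado <- cladogenesis_table(space, model$variant)
  phy <- tree$phy
  ch <- children_of(phy)
  nt <- ape::Ntip(phy)
  ntot <- nt + phy$Nnode
  rt <- nt + 1L
  node_range <- integer(ntot)
  sizes <- mask_size(space$masks, n_areas)
  root_idx <- if (root_sample == "single") {
    sample(which(sizes == 1L), 1L)
  } else {
    sample.int(K, 1L)
  }
  node_range[rt] <- space$masks[root_idx]
  events <- NULL
  n_reseeds <- 0L
  stack <- rt
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    s <- match(node_range[v], space$masks)
    ev <- clado[[s]]
    r <- sample_idx(ev$weight)
    events <- rbind(events, data.frame(
      kind = ev$kind[r], time_ma = tree$age[v], node = v,
      before = node_range[v], after = NA_integer_,
      left = ev$left[r], right = ev$right[r], stringsAsFactors = FALSE))
    daughters <- c(ev$left[r], ev$right[r])
    for (j in 1:2) {
      k <- ch[[v]][j]
      res <- evolve_branch(daughters[j], tree$age[v], tree$age[k],
                           Q, space, extinct)
      if (is.null(res)) return(NULL)  # discard policy hit total extinction
      n_reseeds <- n_reseeds + res$n_reseeds
      if (!is.null(res$events)) {
        res$events$node <- k
        events <- rbind(events, res$events)
      }
      node_range[k] <- res$final
      if (k > nt) stack <- c(stack, k)
    }
  }
  events <- events[order(-events$time_ma), ]
  rownames(events) <- NULL
  out <- list(tree = tree, space = space, node_range = node_range,
              events = events, seed = NULL)
  class(out) <- "biogeo_history"
  attr(out, "n_reseeds") <- n_reseeds
  out
}

## forward Gillespie simulation of one branch; returns NULL if the lineage
## goes fully extinct under the discard policy
evolve_branch <- function(start_mask, older, younger, Q, space, extinct) {
  n_areas <- length(space$areas)
  K <- length(space$masks)
  cur <- match(start_mask, space$masks)
  t <- older
  events <- NULL
  n_reseeds <- 0L
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break
    t <- t - stats::rexp(1L, rate)
    if (t <= younger) break
    j <- sample_idx(Q[cur, -cur])
    j <- if (j >= cur) j + 1L else j
    before <- space$masks[cur]
    if (j == K + 1L) {
      ## total local extinction of a single-area lineage
      if (extinct == "discard") return(NULL)
      lost <- mask_areas(before, n_areas)
      nbr <- setdiff(which(space$adjacency[lost, ]), lost)
      dest <- if (length(nbr) == 0L) lost else nbr[sample.int(length(nbr), 1L)]
      after <- bitwShiftL(1L, dest - 1L)
      events <- rbind(events, data.frame(
        kind = "reseed", time_ma = t, node = NA_integer_,
        before = before, after = after,
        left = NA_integer_, right = NA_integer_, stringsAsFactors = FALSE))
      n_reseeds <- n_reseeds + 1L
      cur <- match(after, space$masks)
    } else {
      after <- space$masks[j]
      kind <- if (mask_size(after, n_areas) > mask_size(before, n_areas)) {
        "dispersal"
      } else {
        "local extinction"
      }
      events <- rbind(events, data.frame(
        kind = kind, time_ma = t, node = NA_integer_,
        before = before, after = after,
        left = NA_integer_, right = NA_integer_, stringsAsFactors = FALSE))
      cur <- j
    }
  }
  list(final = space$masks[cur], events = events, n_reseeds = n_reseeds)
}

#' Mean per-bin null rates from a simulated ensemble
#'
#' Simulates `n_null` forward histories and returns, for each time bin and
#' event kind, the mean of the per-history binned rates (event count divided
#' by bin duration).
#'
#' @inheritParams simulate_null_history
#' @param n_null ensemble size.
#' @param bins a `time_bins` data frame.
#' @param kinds event kinds to count.
#' @return data frame `bin, kind, rate` (mean over the ensemble), plus the
#'   per-history rate matrix as attribute `per_history`.
#' @export
null_rates <- function(tree, model, space, n_null, bins, seed = 1L,
                       root_sample = "uniform", extinct = "reseed") {
  seeds <- derive_seeds(seed, n_null)
  per <- lapply(seq_len(n_null), function(i) {
    h <- simulate_null_history(tree, model, space, seed = seeds[i],
                               root_sample = root_sample, extinct = extinct)
    counts_to_rates(bin_events(h$events, bins, warn = FALSE), bins)
  })
  template <- per[[1L]][, c("bin", "kind")]
  rates <- vapply(per, function(p) p$rate, numeric(nrow(template)))
  rates <- matrix(rates, nrow = nrow(template))
  out <- cbind(template, rate = rowMeans(rates))
  attr(out, "per_history") <- rates
  out
}
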