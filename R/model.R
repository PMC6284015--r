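## Adjacency-constrained dispersal-extinction range evolution with three
## cladogenesis variants (DEC-like, DIVA-like, BAYAREA-like).  Anagenesis is a
## continuous-time Markov chain on the permitted ranges plus an absorbing
## null (empty) range; cladogenesis is a per-ancestor-range distribution over
## ordered daughter-range pairs.  No founder/jump events exist anywhere in the
## model: on a supercontinent the only dispersal routes are via adjacent
## areas, so a daughter range can never appear outside the ancestor's
## adjacency neighbourhood.

CLADO_VARIANTS <- c("DEC-like", "DIVA-like", "BAYAREA-like")

#' Specify a biogeographic model
#'
#' @param d anagenetic dispersal rate: expected range expansions per
#'   lineage-Myr per available (occupied-area, adjacent-empty-area) pair.
#' @param e anagenetic local-extinction rate: expected area losses per
#'   lineage-Myr per occupied area.
#' @param variant cladogenesis rule set, one of `"DEC-like"`, `"DIVA-like"`,
#'   `"BAYAREA-like"`.
#' @return a `biogeo_model` list.
#' @export
biogeo_model <- function(d, e, variant = "DIVA-like") {
  variant <- match.arg(variant, CLADO_VARIANTS)
  if (d < 0 || e < 0) stop("rates d and e must be non-negative")
  structure(list(d = d, e = e, variant = variant), class = "biogeo_model")
}

#' @exportS3Method base::print
print.biogeo_model <- function(x, ...) {
  cat(sprintf("biogeo_model: %s, d = %.5g /lineage-Myr, e = %.5g /lineage-Myr\n",
              x$variant, x$d, x$e))
  invisible(x)
}

#' Anagenetic rate generator over ranges
#'
#' Builds the CTMC generator Q over the permitted ranges plus a final
#' absorbing null (empty-range) state.  Range R gains area a (a not in R,
#' R+a permitted) at rate `d` times the number of areas of R adjacent to a;
#' R loses each occupied area at rate `e` (losses whose remainder is not a
#' permitted range are dropped; a single-area range decays to the null
#' state).  Rows sum to zero.
#'
#' @param space a `range_space`.
#' @param model a `biogeo_model` (only `d` and `e` are used).
#' @return square matrix, `length(space$masks) + 1` states; the last
#'   row/column is the null range.
#' @export
anagenetic_generator <- function(space, model) {
  masks <- space$masks
  n_areas <- length(space$areas)
  K <- length(masks)
  Q <- matrix(0, K + 1L, K + 1L,
              dimnames = list(c(space$labels, "0"), c(space$labels, "0")))
  adj <- space$adjacency
  for (i in seq_len(K)) {
    occ <- mask_areas(masks[i], n_areas)
    ## dispersal: gain one adjacent area
    if (model$d > 0) {
      for (a in setdiff(seq_len(n_areas), occ)) {
        nsrc <- sum(adj[occ, a])
        if (nsrc == 0) next
        target <- bitwOr(masks[i], bitwShiftL(1L, a - 1L))
        j <- match(target, masks)
        if (!is.na(j)) Q[i, j] <- Q[i, j] + model$d * nsrc
      }
    }
    ## local extinction: lose one occupied area
    if (model$e > 0) {
      for (a in occ) {
        target <- bitwAnd(masks[i], bitwNot(bitwShiftL(1L, a - 1L)))
        if (target == 0L) {
          Q[i, K + 1L] <- Q[i, K + 1L] + model$e
        } else {
          j <- match(target, masks)
          if (!is.na(j)) Q[i, j] <- Q[i, j] + model$e
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability propagator for a generator
#'
#' Returns a function `P(t)` computing `expm(Q t)`.  An eigendecomposition is
#' used when the eigenvector matrix is well conditioned (one decomposition,
#' then two small matrix products per branch); otherwise each call falls back
#' to `Matrix::expm` (scaling and squaring).  Tiny negative entries from
#' round-off are clipped to zero and rows renormalised.
#'
#' @param Q square generator matrix.
#' @return function of `t` returning the transition-probability matrix.
#' @export
make_propagator <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      kappa <- max(Mod(eg$vectors)) * max(Mod(Vi)) * n
      use_eigen <- is.finite(kappa) && kappa < 1e8
    }
  }
  fix <- function(P) {
    P[P < 0] <- 0
    sw <- rowSums(P)
    sw[sw == 0] <- 1
    P / sw
  }
  if (use_eigen) {
    V <- eg$vectors
    lam <- eg$values
    function(t) {
      if (t == 0) return(diag(n))
      P <- Re(V %*% (exp(lam * t) * Vi))
      dimnames(P) <- dimnames(Q)
      fix(P)
    }
  } else {
    function(t) {
      if (t == 0) return(diag(n))
      P <- as.matrix(Matrix::expm(Q * t))
      dimnames(P) <- dimnames(Q)
      fix(P)
    }
  }
}

## ordered splits of mask into two disjoint non-empty covering subsets, both
## permitted; returns matrix with columns left, right
ordered_splits <- function(mask, space) {
  n_areas <- length(space$areas)
  occ <- mask_areas(mask, n_areas)
  k <- length(occ)
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  out <- NULL
  ## iterate over non-empty proper sub-subsets
  for (s in seq_len(bitwShiftL(1L, k) - 2L)) {
    left <- areas_mask(occ[bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) != 0L])
    right <- bitwAnd(mask, bitwNot(left))
    if (left %in% space$masks && right %in% space$masks) {
      out <- rbind(out, c(left, right))
    }
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}

#' Cladogenetic event table
#'
#' For each ancestor range, the distribution over ordered daughter-range
#' pairs at a speciation node, under one of three rule sets:
#'
#' * `DIVA-like` — single-area ancestors speciate sympatrically (both
#'   daughters copy the area); wider ancestors undergo vicariance only: every
#'   ordered split of the range into two disjoint, non-empty, permitted
#'   subsets (any sizes), equal weights.
#' * `DEC-like` — as classic DEC: single-area sympatry; for wider ranges,
#'   subset sympatry (one daughter is one area of the range, the other keeps
#'   the full range, both orders) plus vicariance restricted to splits where
#'   one daughter is a single area; equal weights.
#' * `BAYAREA-like` — no range change at nodes: both daughters copy the
#'   ancestor range exactly.
#'
#' Weights are normalised per ancestor range.  Vicariance is impossible for
#' single-area ancestors in every variant, and no daughter range outside the
#' permitted space is ever produced.
#'
#' @param space a `range_space`.
#' @param variant cladogenesis rule set.
#' @return list (one element per ancestor range, in `space$masks` order) of
#'   data frames with columns `left`, `right` (bitmasks), `weight`, `kind`.
#' @export
cladogenesis_table <- function(space, variant = "DIVA-like") {
  variant <- match.arg(variant, CLADO_VARIANTS)
  n_areas <- length(space$areas)
  lapply(space$masks, function(m) {
    sz <- length(mask_areas(m, n_areas))
    if (sz == 1L || variant == "BAYAREA-like") {
      kind <- if (sz == 1L) "sympatry" else "range copy"
      ev <- data.frame(left = m, right = m, weight = 1, kind = kind,
                       stringsAsFactors = FALSE)
      return(ev)
    }
    if (variant == "DIVA-like") {
      sp <- ordered_splits(m, space)
      ev <- data.frame(left = sp[, 1L], right = sp[, 2L],
                       weight = rep(1, nrow(sp)),
                       kind = rep("vicariance", nrow(sp)),
                       stringsAsFactors = FALSE)
    } else {  # DEC-like
      occ <- mask_areas(m, n_areas)
      singles <- bitwShiftL(1L, occ - 1L)
      ss <- data.frame(left = c(singles, rep(m, sz)),
                       right = c(rep(m, sz), singles),
                       weight = 1, kind = "subset sympatry",
                       stringsAsFactors = FALSE)
      sp <- ordered_splits(m, space)
      if (nrow(sp) > 0L) {
        sizes_l <- mask_size(sp[, 1L], n_areas)
        sizes_r <- mask_size(sp[, 2L], n_areas)
        sp <- sp[sizes_l == 1L | sizes_r == 1L, , drop = FALSE]
      }
      vic <- data.frame(left = sp[, 1L], right = sp[, 2L],
                        weight = rep(1, nrow(sp)),
                        kind = rep("vicariance", nrow(sp)),
                        stringsAsFactors = FALSE)
      ev <- rbind(ss, vic)
    }
    if (nrow(ev) == 0L || sum(ev$weight) == 0) {
      stop("no permitted cladogenetic outcome for ancestor range ",
           format_range(m, space$areas),
           " under ", variant, " (range cannot split within the space)")
    }
    ev$weight <- ev$weight / sum(ev$weight)
    ev
  })
}

## tip conditional-likelihood matrix: rows = states (incl. null), cols = tips
tip_conditionals <- function(tree, tip_ranges, space) {
  nt <- ape::Ntip(tree$phy)
  labs <- tree$phy$tip.label
  miss <- setdiff(labs, names(tip_ranges))
  if (length(miss) > 0L) {
    stop("no tip range for: ", paste(miss, collapse = ", "))
  }
  K <- length(space$masks)
  L <- matrix(0, K + 1L, nt)
  for (i in seq_len(nt)) {
    m <- tip_ranges[[labs[i]]]
    j <- match(m, space$masks)
    if (is.na(j)) {
      stop("tip range of '", labs[i], "' (",
           format_range(m, space$areas), ") is not in the permitted space")
    }
    L[j, i] <- 1
  }
  L
}

## shared pruning engine.  Returns per-node quantities needed by the
## likelihood, the marginals and the stochastic mapper:
##   M[[node]]  "up message" at the top of node's branch (data below | state
##              at top of branch), for non-root nodes
##   D[[node]]  (data below node | state at node before cladogenesis)
##   P[[node]]  branch propagator matrix for node's subtending branch
prune_tree <- function(tree, tip_ranges, model, space) {
  validate_time_tree(tree)
  phy <- tree$phy
  if (!is_binary_rooted(phy)) stop("likelihood requires a binary tree")
  nt <- ape::Ntip(phy)
  ntot <- nt + phy$Nnode
  Q <- anagenetic_generator(space, model)
  prop <- make_propagator(Q)
  ch <- children_of(phy)
  tipL <- tip_conditionals(tree, tip_ranges, space)
  clado <- cladogenesis_table(space, model$variant)
  K <- length(space$masks)
  D <- vector("list", ntot)
  M <- vector("list", ntot)
  P <- vector("list", ntot)
  blen <- numeric(ntot)
  blen[phy$edge[, 2L]] <- tree$age[phy$edge[, 1L]] - tree$age[phy$edge[, 2L]]
  ## postorder over nodes: process children before parents
  ord <- rev(unique(phy$edge[, 1L]))  # cladewise parents reversed = postorder
  for (i in seq_len(nt)) D[[i]] <- tipL[, i]
  combine <- function(v) {
    kids <- ch[[v]]
    dv <- numeric(K + 1L)
    ml <- M[[kids[1L]]]; mr <- M[[kids[2L]]]
    for (s in seq_len(K)) {
      ev <- clado[[s]]
      li <- match(ev$left, space$masks)
      ri <- match(ev$right, space$masks)
      dv[s] <- sum(ev$weight * ml[li] * mr[ri])
    }
    dv
  }
  for (v in ord) {
    for (k in ch[[v]]) {
      Pk <- prop(blen[k])
      P[[k]] <- Pk
      M[[k]] <- as.vector(Pk %*% D[[k]])
    }
    D[[v]] <- combine(v)
  }
  list(D = D, M = M, P = P, Q = Q, prop = prop, clado = clado, ch = ch,
       blen = blen, K = K, nt = nt, ntot = ntot)
}

root_prior <- function(K) c(rep(1 / K, K), 0)

#' Log-likelihood of tip ranges under a biogeographic model
#'
#' Felsenstein pruning over the anagenetic CTMC (branch transitions by matrix
#' exponential) with cladogenetic mixing at nodes and a flat root prior over
#' the permitted ranges.
#'
#' @param tree a calibrated, binary `time_tree`.
#' @param tip_ranges named list/vector of range bitmasks (one per tip; see
#'   [parse_range()]), or a tip-range data frame from [read_tip_ranges()].
#' @param model a `biogeo_model`.
#' @param space a `range_space`.
#' @return log-likelihood (scalar).
#' @export
biogeo_loglik <- function(tree, tip_ranges, model, space) {
  tip_ranges <- as_tip_masks(tip_ranges, space)
  pr <- prune_tree(tree, tip_ranges, model, space)
  lik <- sum(root_prior(pr$K) * pr$D[[root_node(tree)]])
  if (lik <= 0) return(-Inf)
  log(lik)
}

## accept data.frame (taxon/areas) or named masks
as_tip_masks <- function(tip_ranges, space) {
  if (is.data.frame(tip_ranges)) {
    masks <- parse_range(tip_ranges$areas, space$areas)
    return(as.list(stats::setNames(masks, tip_ranges$taxon)))
  }
  if (is.null(names(tip_ranges))) stop("tip_ranges must be named by taxon")
  as.list(tip_ranges)
}

#' Maximum-likelihood fit of dispersal and extinction rates
#'
#' Bounded multi-start optimisation of (d, e) on the log scale via
#' `optim(method = "L-BFGS-B")`.
#'
#' @inheritParams biogeo_loglik
#' @param variant cladogenesis rule set to fit.
#' @param starts matrix of (d, e) starting points; default three spread
#'   starts.
#' @param lower,upper box bounds on the rates (events per lineage-Myr).
#' @return a `biogeo_fit`: list with `model` (fitted `biogeo_model`),
#'   `logLik`, `convergence` (0 = converged), `starts` diagnostics, `k`
#'   (number of free parameters, 2) and `n_tips`.
#' @export
fit_ml <- function(tree, tip_ranges, variant = "DIVA-like", space,
                   starts = NULL, lower = 1e-6, upper = 10) {
  variant <- match.arg(variant, CLADO_VARIANTS)
  tip_ranges <- as_tip_masks(tip_ranges, space)
  if (is.null(starts)) {
    starts <- rbind(c(0.01, 0.01), c(0.1, 0.02), c(0.005, 0.1))
  }
  nll <- function(par) {
    m <- biogeo_model(exp(par[1L]), exp(par[2L]), variant)
    ll <- biogeo_loglik(tree, tip_ranges, m, space)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  diag_tab <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(pmin(pmax(starts[s, ], lower), upper)), nll,
                   method = "L-BFGS-B",
                   lower = log(lower), upper = log(upper),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    diag_tab <- rbind(diag_tab,
                      data.frame(start_d = starts[s, 1L], start_e = starts[s, 2L],
                                 d = exp(fit$par[1L]), e = exp(fit$par[2L]),
                                 logLik = -fit$value,
                                 convergence = fit$convergence))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ML optimisation failed from every start")
  out <- list(model = biogeo_model(exp(best$par[1L]), exp(best$par[2L]),
                                   variant),
              logLik = -best$value, convergence = best$convergence,
              starts = diag_tab, k = 2L, n_tips = ape::Ntip(tree$phy))
  class(out) <- "biogeo_fit"
  out
}

#' @exportS3Method base::print
print.biogeo_fit <- function(x, ...) {
  cat(sprintf("biogeo_fit (%s): d = %.5g, e = %.5g, lnL = %.4f (%s)\n",
              x$model$variant, x$model$d, x$model$e, x$logLik,
              if (x$convergence == 0) "converged" else "NOT converged"))
  invisible(x)
}

#' Compare fitted cladogenesis variants by AIC
#'
#' AIC = 2k - 2 lnL with k = 2 (d, e) for every variant.  The lowest AIC
#' wins; exact ties are reported via the `tie` attribute rather than broken
#' silently.
#'
#' @param fits named list of `biogeo_fit` objects fitted to identical data.
#' @return data frame `variant, logLik, k, AIC, dAIC, best`, ordered by AIC,
#'   with attribute `best` (character) and `tie` (logical).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fitted variants to compare")
  n_tips <- vapply(fits, function(f) f$n_tips, integer(1))
  if (length(unique(n_tips)) != 1L) {
    stop("fits appear to be on different data (tip counts differ)")
  }
  tab <- data.frame(
    variant = vapply(fits, function(f) f$model$variant, character(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    k = vapply(fits, function(f) f$k, integer(1))
  )
  tab$AIC <- 2 * tab$k - 2 * tab$logLik
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  tie <- sum(abs(tab$AIC - tab$AIC[1L]) < 1e-8) > 1L
  tab$best <- abs(tab$AIC - tab$AIC[1L]) < 1e-8
  rownames(tab) <- NULL
  attr(tab, "best") <- tab$variant[1L]
  attr(tab, "tie") <- tie
  tab
}

#' Marginal ancestral-range probabilities
#'
#' Up-down pass: for each internal node, the posterior probability of each
#' permitted range immediately before the node's cladogenetic event, given
#' all tip data.  Rows sum to one.
#'
#' @inheritParams biogeo_loglik
#' @return matrix, internal nodes (ape numbering, rownames `ndN`) by
#'   permitted ranges.
#' @export
ancestral_marginals <- function(tree, tip_ranges, model, space) {
  tip_ranges <- as_tip_masks(tip_ranges, space)
  pr <- prune_tree(tree, tip_ranges, model, space)
  post <- downpass(tree, pr, space)
  nt <- pr$nt
  out <- t(vapply((nt + 1L):pr$ntot,
                  function(v) post[[v]][seq_len(pr$K)], numeric(pr$K)))
  rownames(out) <- paste0("nd", (nt + 1L):pr$ntot)
  colnames(out) <- space$labels
  sw <- rowSums(out)
  if (any(sw <= 0)) stop("zero marginal mass at a node: data impossible under model")
  out / sw
}

## F-messages: P(data not below v, state of v = s); post = normalised F*D
downpass <- function(tree, pr, space) {
  phy <- tree$phy
  rt <- root_node(tree)
  K <- pr$K
  F <- vector("list", pr$ntot)
  F[[rt]] <- root_prior(K)
  post <- vector("list", pr$ntot)
  post[[rt]] <- F[[rt]] * pr$D[[rt]]
  ## preorder: cladewise edge order visits parents before children
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    kids <- pr$ch[[p]]
    sib <- kids[kids != v]
    side <- if (kids[1L] == v) "left" else "right"
    G <- numeric(K + 1L)
    Fp <- F[[p]]
    for (s in seq_len(K)) {
      if (Fp[s] == 0) next
      ev <- pr$clado[[s]]
      mine <- match(if (side == "left") ev$left else ev$right, space$masks)
      theirs <- match(if (side == "left") ev$right else ev$left, space$masks)
      w <- ev$weight * pr$M[[sib]][theirs] * Fp[s]
      for (r in seq_along(mine)) G[mine[r]] <- G[mine[r]] + w[r]
    }
    F[[v]] <- as.vector(G %*% pr$P[[v]])
    post[[v]] <- F[[v]] * pr$D[[v]]
  }
  post
}
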