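# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written as brute-force enumerations, independent
# of the message-passing code paths they check.

## 3 areas in a chain A-B-C (A and C not adjacent)
adj_chain3 <- function() {
  m <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 1, 1), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m
}

space_chain3 <- function(cap = 2) {
  build_state_space(c("A", "B", "C"), adj_chain3(), max_range_size = cap)
}

space_full <- function(n = 3, cap = 2) {
  build_state_space(LETTERS[seq_len(n)], max_range_size = cap)
}

tree3 <- function() read_tree("((A:10,B:10):5,C:15);")
tree4_ladder <- function() read_tree("(((A:4,B:6):3,C:8):2,D:11);")
tree4_balanced <- function() read_tree("((A:3,B:3):9,(C:5,D:7):4);")

## clade strings (tip-set per internal node, root excluded for rooted
## comparison including root makes no difference)
clades_of <- function(phy) {
  nt <- ape::Ntip(phy)
  ids <- unique(phy$edge[, 1])
  sort(vapply(ids, function(v) {
    tips <- phy$tip.label[intersect(seq_len(nt), unlist(desc_set(phy, v)))]
    paste(sort(tips), collapse = "|")
  }, character(1)))
}

desc_set <- function(phy, v) {
  nt <- ape::Ntip(phy)
  if (v <= nt) return(v)
  kids <- phy$edge[phy$edge[, 1] == v, 2]
  unlist(lapply(kids, desc_set, phy = phy))
}

## --- independent likelihood oracle: explicit enumeration ------------------
enum_loglik <- function(tree, tips, model, space) {
  Q <- anagenetic_generator(space, model)
  prop <- make_propagator(Q)
  clado <- cladogenesis_table(space, model$variant)
  phy <- tree$phy
  nt <- ape::Ntip(phy)
  K <- length(space$masks)
  ch <- lapply(seq_len(nt + phy$Nnode), function(v) {
    phy$edge[phy$edge[, 1] == v, 2]
  })
  blen <- numeric(nt + phy$Nnode)
  blen[phy$edge[, 2]] <- tree$age[phy$edge[, 1]] - tree$age[phy$edge[, 2]]
  P <- lapply(seq_along(blen), function(v) prop(blen[v]))
  tipstate <- vapply(phy$tip.label,
                     function(l) match(tips[[l]], space$masks), integer(1))
  below <- function(v, s) {
    ev <- clado[[s]]
    tot <- 0
    for (r in seq_len(nrow(ev))) {
      li <- match(ev$left[r], space$masks)
      ri <- match(ev$right[r], space$masks)
      contrib <- ev$weight[r]
      for (side in 1:2) {
        k <- ch[[v]][side]
        top <- if (side == 1) li else ri
        if (k <= nt) {
          contrib <- contrib * P[[k]][top, tipstate[phy$tip.label[k]]]
        } else {
          sub <- 0
          for (s2 in seq_len(K)) sub <- sub + P[[k]][top, s2] * below(k, s2)
          contrib <- contrib * sub
        }
      }
      tot <- tot + contrib
    }
    tot
  }
  lik <- 0
  for (s in seq_len(K)) lik <- lik + (1 / K) * below(nt + 1L, s)
  log(lik)
}

## --- independent marginals oracle: joint enumeration ----------------------
enum_marginals <- function(tree, tips, model, space) {
  Q <- anagenetic_generator(space, model)
  prop <- make_propagator(Q)
  clado <- cladogenesis_table(space, model$variant)
  phy <- tree$phy
  nt <- ape::Ntip(phy)
  K <- length(space$masks)
  ch <- lapply(seq_len(nt + phy$Nnode), function(v) {
    phy$edge[phy$edge[, 1] == v, 2]
  })
  blen <- numeric(nt + phy$Nnode)
  blen[phy$edge[, 2]] <- tree$age[phy$edge[, 1]] - tree$age[phy$edge[, 2]]
  P <- lapply(seq_along(blen), function(v) prop(blen[v]))
  tipstate <- vapply(phy$tip.label,
                     function(l) match(tips[[l]], space$masks), integer(1))
  internal <- (nt + 1L):(nt + phy$Nnode)
  grids <- do.call(expand.grid, rep(list(seq_len(K)), length(internal)))
  joint <- numeric(nrow(grids))
  for (g in seq_len(nrow(grids))) {
    s <- as.integer(grids[g, ])
    names(s) <- internal
    p <- 1 / K
    for (v in internal) {
      ev <- clado[[s[as.character(v)]]]
      tot <- 0
      for (r in seq_len(nrow(ev))) {
        li <- match(ev$left[r], space$masks)
        ri <- match(ev$right[r], space$masks)
        c1 <- ch[[v]][1]
        c2 <- ch[[v]][2]
        b1 <- if (c1 <= nt) tipstate[phy$tip.label[c1]] else s[as.character(c1)]
        b2 <- if (c2 <= nt) tipstate[phy$tip.label[c2]] else s[as.character(c2)]
        tot <- tot + ev$weight[r] * P[[c1]][li, b1] * P[[c2]][ri, b2]
      }
      p <- p * tot
    }
    joint[g] <- p
  }
  out <- t(vapply(seq_along(internal), function(i) {
    vapply(seq_len(K), function(st) sum(joint[grids[[i]] == st]), numeric(1))
  }, numeric(K)))
  out / rowSums(out)
}

## --- hand-rolled Fitch length with a forced all-absent root ---------------
## characters are columns of an MRP matrix; "?" contributes the full state
## set; the root is constrained to state "0" (absence ancestral)
fitch_oracle <- function(phy, m) {
  nt <- ape::Ntip(phy)
  total <- 0
  for (j in seq_len(ncol(m))) {
    steps <- 0
    sets <- vector("list", nt + phy$Nnode)
    for (i in seq_len(nt)) {
      x <- m[phy$tip.label[i], j]
      sets[[i]] <- if (x == "?") c("0", "1") else x
    }
    ord <- rev(unique(ape::reorder.phylo(phy, "cladewise")$edge[, 1]))
    chl <- lapply(seq_len(nt + phy$Nnode), function(v) {
      phy$edge[phy$edge[, 1] == v, 2]
    })
    for (v in ord) {
      cur <- NULL
      for (k in chl[[v]]) {
        if (is.null(cur)) {
          cur <- sets[[k]]
        } else {
          inter <- intersect(cur, sets[[k]])
          if (length(inter) == 0) {
            cur <- union(cur, sets[[k]])
            steps <- steps + 1
          } else {
            cur <- inter
          }
        }
      }
      sets[[v]] <- cur
    }
    if (!("0" %in% sets[[nt + 1L]])) steps <- steps + 1
    total <- total + steps
  }
  total
}

## random compatible source-tree set: prune a common binary reference tree
## to overlapping taxon subsets
random_compatible_sources <- function(n_taxa, n_trees, min_keep = 4) {
  ref <- ape::rtree(n_taxa, br = NULL)
  src <- lapply(seq_len(n_trees), function(i) {
    keep <- sample(ref$tip.label, sample(min_keep:n_taxa, 1))
    ape::keep.tip(ref, keep)
  })
  list(ref = ref, sources = src)
}

## does `super` display `src` (all src clades present after restriction)?
displays <- function(super, src) {
  sub <- ape::keep.tip(super, intersect(super$tip.label, src$tip.label))
  all(clades_of(src) %in% clades_of(sub))
}

## small calibrated tree + simulated ranges bundle for sampler tests
fixture_mapped <- function(seed = 1, d = 0.05, e = 0.02,
                           variant = "DIVA-like") {
  sp <- space_chain3()
  tr <- tree3()
  tips <- list(A = parse_range("A", sp$areas),
               B = parse_range("A+B", sp$areas),
               C = parse_range("C", sp$areas))
  m <- biogeo_model(d, e, variant)
  list(space = sp, tree = tr, tips = tips, model = m,
       mapper = biogeo_mapper(tr, tips, m, sp))
}
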