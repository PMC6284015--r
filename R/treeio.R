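## Time-calibrated fossil trees.  A `time_tree` wraps an ape "phylo" with
## explicit node ages (Ma before present, larger = older), per-tip
## stratigraphic ranges (first/last appearance) and optional named clades.

#' Construct a time_tree
#'
#' @param phy an ape `phylo` (rooted).
#' @param tip_fad,tip_lad numeric vectors of first/last appearance ages (Ma),
#'   named by tip label, or `NULL` when unknown.
#' @param age numeric vector of node ages, length `Ntip + Nnode` in ape node
#'   numbering; if `NULL` and `phy` has branch lengths, ages are computed from
#'   root-to-node path lengths with the youngest tip placed at `youngest_age`.
#' @param youngest_age age (Ma) assigned to the youngest tip when ages are
#'   derived from branch lengths.
#' @param clades named list of character vectors of tip labels (MRCA
#'   circumscriptions).
#' @return an object of class `time_tree`.
#' @export
time_tree <- function(phy, tip_fad = NULL, tip_lad = NULL, age = NULL,
                      youngest_age = 0, clades = list()) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  if (is.null(attr(phy, "order")) || attr(phy, "order") != "cladewise") {
    phy <- ape::reorder.phylo(phy, "cladewise")
  }
  ntot <- ape::Ntip(phy) + phy$Nnode
  if (is.null(age)) {
    if (!is.null(phy$edge.length)) {
      depth <- ape::node.depth.edgelength(phy)
      root_age <- max(depth[seq_len(ape::Ntip(phy))]) + youngest_age
      age <- root_age - depth
    } else {
      age <- rep(NA_real_, ntot)
    }
  }
  if (length(age) != ntot) stop("age must have one entry per node")
  fad <- lad <- stats::setNames(rep(NA_real_, ape::Ntip(phy)), phy$tip.label)
  if (!is.null(tip_fad)) fad[names(tip_fad)] <- tip_fad
  if (!is.null(tip_lad)) lad[names(tip_lad)] <- tip_lad
  bad <- !is.na(fad) & !is.na(lad) & fad < lad
  if (any(bad)) {
    stop("inverted stratigraphic interval (first < last appearance) for: ",
         paste(names(fad)[bad], collapse = ", "))
  }
  out <- list(phy = phy, age = age, tip_fad = fad, tip_lad = lad,
              clades = clades)
  class(out) <- "time_tree"
  out
}

#' @exportS3Method base::print
print.time_tree <- function(x, ...) {
  nt <- ape::Ntip(x$phy)
  cat("time_tree: ", nt, " tips, ", x$phy$Nnode, " internal nodes",
      if (is_binary_rooted(x$phy)) ", binary" else ", has polytomies", "\n",
      sep = "")
  if (!anyNA(x$age)) {
    cat("root age ", format(root_age(x), digits = 6), " Ma; tip ages ",
        format(min(x$age[seq_len(nt)]), digits = 6), "-",
        format(max(x$age[seq_len(nt)]), digits = 6), " Ma\n", sep = "")
  }
  if (length(x$clades)) {
    cat("clades:", paste(names(x$clades), collapse = ", "), "\n")
  }
  invisible(x)
}

root_node <- function(tree) ape::Ntip(tree$phy) + 1L
#' @rdname time_tree
#' @param tree a `time_tree`.
#' @export
root_age <- function(tree) tree$age[root_node(tree)]

## check internal nodes older than children; returns invisibly
validate_time_tree <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "time_tree"))
  e <- tree$phy$edge
  if (!anyNA(tree$age)) {
    bad <- tree$age[e[, 1L]] < tree$age[e[, 2L]] - tol
    if (any(bad)) stop("node ages are not monotone along ", sum(bad), " edge(s)")
    if (any(tree$age < -tol)) stop("negative node age")
  }
  invisible(tree)
}

## set phy$edge.length from node ages
sync_edge_lengths <- function(tree) {
  e <- tree$phy$edge
  tree$phy$edge.length <- tree$age[e[, 1L]] - tree$age[e[, 2L]]
  tree
}

#' Read a tree from Newick or NEXUS text
#'
#' `x` may be a file path or a literal Newick string.  NEXUS files (detected
#' by a `#NEXUS` header) are read via their TREES block; only the first tree
#' is returned unless `all = TRUE`.
#'
#' @param x path or Newick string.
#' @param tip_fad,tip_lad optional named stratigraphic ages passed on to
#'   [time_tree()].
#' @param youngest_age age of the youngest tip (Ma) used to anchor node ages.
#' @param all return a list of `time_tree` for multi-tree NEXUS/Newick input.
#' @return a `time_tree` (or list of them).
#' @export
read_tree <- function(x, tip_fad = NULL, tip_lad = NULL, youngest_age = 0,
                      all = FALSE) {
  is_literal <- grepl("^\\s*\\(", x) || grepl(";", x, fixed = TRUE)
  if (!is_literal && !file.exists(x)) stop("file not found: ", x)
  nexus <- FALSE
  if (!is_literal) {
    head <- readLines(x, n = 1L, warn = FALSE)
    nexus <- grepl("^#NEXUS", head, ignore.case = TRUE)
  }
  phy <- tryCatch(
    if (nexus) ape::read.nexus(x)
    else if (is_literal) ape::read.tree(text = x)
    else ape::read.tree(x),
    error = function(e) stop("tree parse error: ", conditionMessage(e))
  )
  if (is.null(phy)) stop("tree parse error: no tree found in input")
  wrap <- function(p) time_tree(p, tip_fad = tip_fad, tip_lad = tip_lad,
                                youngest_age = youngest_age)
  if (inherits(phy, "multiPhylo")) {
    if (all) return(lapply(phy, wrap)) else return(wrap(phy[[1L]]))
  }
  if (all) list(wrap(phy)) else wrap(phy)
}

#' Write a time_tree as Newick text
#'
#' Branch lengths (Myr) are recomputed from node ages when ages are known and
#' are always written.
#'
#' @param tree a `time_tree`.
#' @param path output file; `NULL` returns the Newick string.
#' @export
write_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (!anyNA(tree$age)) tree <- sync_edge_lengths(tree)
  txt <- ape::write.tree(tree$phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

children_of <- function(phy) {
  ch <- vector("list", ape::Ntip(phy) + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2L])
  }
  ch
}

## uniform random rooted binary shape over k items by sequential insertion:
## item j+1 is attached at any of the 2j-1 positions (each edge, or above the
## current local root) with equal probability, which makes all (2k-3)!! rooted
## shapes equally likely.
random_nesting <- function(items) {
  k <- length(items)
  if (k == 1L) return(items[[1L]])
  shape <- list(items[[1L]], items[[2L]])
  if (k >= 3L) {
    for (j in 3L:k) {
      npos <- 2L * (j - 1L) - 1L
      pos <- sample.int(npos, 1L)
      shape <- insert_at(shape, items[[j]], pos)$shape
    }
  }
  shape
}

## positions are counted in preorder: position 1 = above this subtree's root,
## then recursively inside child 1, then child 2.
insert_at <- function(shape, item, pos) {
  if (pos == 1L) return(list(shape = list(shape, item), used = 1L))
  used <- 1L
  if (!is.list(shape)) return(list(shape = shape, used = used))
  for (i in 1:2) {
    sub <- count_pos(shape[[i]])
    if (pos - used <= sub) {
      r <- insert_at(shape[[i]], item, pos - used)
      shape[[i]] <- r$shape
      return(list(shape = shape, used = pos))
    }
    used <- used + sub
  }
  stop("internal error: insertion position out of range")
}

count_pos <- function(shape) {
  if (!is.list(shape)) return(1L)
  1L + count_pos(shape[[1L]]) + count_pos(shape[[2L]])
}

#' Randomly resolve polytomies
#'
#' Every multifurcation is replaced by a uniformly drawn rooted binary
#' resolution of its children (each of the `(2k-3)!!` local shapes equally
#' likely); newly created internal edges get zero length.  Binary trees are
#' returned unchanged.  Reproducible under `seed`.
#'
#' @param tree a `time_tree`.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return a binary `time_tree`.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phy
  if (is_binary_rooted(phy)) return(tree)
  ch <- children_of(phy)
  has_len <- !is.null(phy$edge.length)
  len <- function(node) {
    if (!has_len) return("")
    i <- which(phy$edge[, 2L] == node)
    paste0(":", format(phy$edge.length[i], digits = 15))
  }
  nwk_shape <- function(shape) {
    if (!is.list(shape)) return(shape)  # already a formatted child string
    paste0("(", nwk_shape(shape[[1L]]), ",", nwk_shape(shape[[2L]]), ")",
           if (has_len) ":0" else "")
  }
  nwk <- function(v) {
    if (v <= ape::Ntip(phy)) return(paste0(phy$tip.label[v], len(v)))
    kids <- vapply(ch[[v]], nwk, character(1))
    if (length(kids) == 1L) return(paste0("(", kids, ")", len(v)))
    if (length(kids) == 2L) {
      return(paste0("(", kids[1L], ",", kids[2L], ")", len(v)))
    }
    shape <- random_nesting(as.list(sample(kids)))
    body <- nwk_shape(shape)
    ## strip the ":0" the shape writer put on the local root; the polytomy
    ## node keeps its own incoming edge length
    if (has_len) body <- sub(":0$", "", body)
    paste0(body, len(v))
  }
  txt <- paste0(nwk(root_node(tree)), ";")
  newphy <- ape::read.tree(text = txt)
  time_tree(newphy, tip_fad = tree$tip_fad, tip_lad = tree$tip_lad,
            age = NULL, clades = tree$clades)
}

#' Draw tip ages uniformly within stratigraphic ranges
#'
#' Each tip's age is sampled from Uniform(last appearance, first appearance);
#' zero-width intervals give the exact age.  Internal node ages are reset to
#' `NA` (they are assigned by [calibrate_node_ages()]).
#'
#' @param tree a `time_tree` whose tips carry stratigraphic intervals.
#' @param seed integer seed.
#' @return the tree with tip ages set.
#' @export
draw_tip_ages <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (!is.null(seed)) set.seed(seed)
  nt <- ape::Ntip(tree$phy)
  fad <- tree$tip_fad[tree$phy$tip.label]
  lad <- tree$tip_lad[tree$phy$tip.label]
  if (anyNA(fad) || anyNA(lad)) {
    stop("every tip needs a stratigraphic interval before drawing ages")
  }
  tree$age[seq_len(nt)] <- stats::runif(nt, min = lad, max = fad)
  tree$age[(nt + 1L):(nt + tree$phy$Nnode)] <- NA_real_
  tree
}

#' Minimum-age node calibration with a root maximum
#'
#' Assigns each internal node the age of its oldest child plus `min_branch`
#' (postorder), so every branch is at least `min_branch` Myr long and node
#' ages are monotone.  Errors if the resulting root age would exceed
#' `root_max`.
#'
#' @param tree a `time_tree` with tip ages set (see [draw_tip_ages()]).
#' @param root_max maximum permitted root age (Ma).
#' @param min_branch minimum branch duration (Myr), default 0.1.
#' @param seed accepted for interface symmetry with the other calibration
#'   steps; the assignment itself is deterministic given the tip ages.
#' @return a calibrated `time_tree` with branch lengths synced to ages.
#' @export
calibrate_node_ages <- function(tree, root_max = Inf, min_branch = 0.1,
                                seed = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  nt <- ape::Ntip(tree$phy)
  if (anyNA(tree$age[seq_len(nt)])) stop("tip ages must be drawn first")
  if (min_branch <= 0) stop("min_branch must be positive")
  age <- tree$age
  e <- tree$phy$edge
  ## postorder: children before parents
  for (i in rev(seq_len(nrow(e)))) {
    p <- e[i, 1L]; c <- e[i, 2L]
    cand <- age[c] + min_branch
    if (is.na(age[p]) || cand > age[p]) age[p] <- cand
  }
  rt <- root_node(tree)
  if (age[rt] > root_max + 1e-9) {
    stop(sprintf(
      "calibration infeasible: minimum root age %.4f exceeds root_max %.4f",
      age[rt], root_max))
  }
  tree$age <- age
  validate_time_tree(sync_edge_lengths(tree))
}

#' Drop tips whose occurrence postdates the study window
#'
#' Tips with first appearance younger than `window_end` (kept during
#' calibration for their ghost lineages) are removed; ages of all retained
#' nodes are unchanged.
#'
#' @param tree a calibrated `time_tree`.
#' @param window_end youngest age of the study window (Ma).
#' @return a pruned `time_tree`.
#' @export
drop_post_window_clades <- function(tree, window_end) {
  stopifnot(inherits(tree, "time_tree"))
  fad <- tree$tip_fad[tree$phy$tip.label]
  drop <- tree$phy$tip.label[!is.na(fad) & fad < window_end]
  if (length(drop) == 0L) return(tree)
  keep_n <- ape::Ntip(tree$phy) - length(drop)
  if (keep_n < 2L) stop("dropping post-window tips would leave < 2 tips")
  prune_to_tips(tree, setdiff(tree$phy$tip.label, drop))
}

## prune to a tip set, preserving ages of retained nodes via node labels
prune_to_tips <- function(tree, keep) {
  phy <- tree$phy
  nt <- ape::Ntip(phy)
  phy$node.label <- paste0("nd", seq_len(phy$Nnode))
  node_age <- stats::setNames(tree$age[(nt + 1L):(nt + phy$Nnode)],
                              phy$node.label)
  tip_age <- stats::setNames(tree$age[seq_len(nt)], phy$tip.label)
  sub <- ape::keep.tip(phy, keep)
  nt2 <- ape::Ntip(sub)
  age <- unname(c(tip_age[sub$tip.label], node_age[sub$node.label]))
  sub$node.label <- NULL
  time_tree(sub,
            tip_fad = tree$tip_fad[sub$tip.label],
            tip_lad = tree$tip_lad[sub$tip.label],
            age = age,
            clades = lapply(tree$clades, intersect, y = sub$tip.label))
}

#' Time-slice a tree, keeping ghost lineages
#'
#' A tip is retained if its observed stratigraphic range *or* its subtending
#' lineage (from its parent node's age down to its own age — the ghost
#' lineage) intersects the slice.
#'
#' @param tree a calibrated `time_tree`.
#' @param older,younger slice edges (Ma), `older > younger`.
#' @return character vector of retained tip labels (empty, with a warning,
#'   when the slice misses the tree entirely).
#' @export
time_slice <- function(tree, older, younger) {
  stopifnot(inherits(tree, "time_tree"), older > younger)
  phy <- tree$phy
  nt <- ape::Ntip(phy)
  parent <- integer(nt)
  parent[phy$edge[phy$edge[, 2L] <= nt, 2L]] <-
    phy$edge[phy$edge[, 2L] <= nt, 1L]
  keep <- logical(nt)
  for (i in seq_len(nt)) {
    lo_obs <- tree$tip_lad[phy$tip.label[i]]
    hi_obs <- tree$tip_fad[phy$tip.label[i]]
    hi_br <- tree$age[parent[i]]
    lo_br <- tree$age[i]
    hit <- function(hi, lo) !is.na(hi) && !is.na(lo) && hi >= younger && lo <= older
    keep[i] <- hit(hi_obs, lo_obs) || hit(hi_br, lo_br)
  }
  if (!any(keep)) warning("time slice does not intersect the tree")
  phy$tip.label[keep]
}

#' Extract the subtree of a named clade
#'
#' The clade is the MRCA circumscription of its defining tips.
#'
#' @param tree a `time_tree`.
#' @param clade either a name in `tree$clades` or a character vector of tip
#'   labels.
#' @return a `time_tree` rooted at the MRCA of the defining tips.
#' @export
clade_subtree <- function(tree, clade) {
  tips <- if (is.character(clade) && length(clade) == 1L &&
              clade %in% names(tree$clades)) tree$clades[[clade]] else clade
  unknown <- setdiff(tips, tree$phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip(s) in clade definition: ",
         paste(unknown, collapse = ", "))
  }
  if (length(tips) < 1L) stop("clade definition is empty")
  mrca <- clade_mrca(tree, tips)
  desc <- descendant_tips(tree$phy, mrca)
  prune_to_tips(tree, tree$phy$tip.label[desc])
}

clade_mrca <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$phy$tip.label))
  ape::getMRCA(tree$phy, tips)
}

descendant_tips <- function(phy, node) {
  nt <- ape::Ntip(phy)
  if (node <= nt) return(node)
  ch <- children_of(phy)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= nt) out <- c(out, v) else stack <- c(stack, ch[[v]])
  }
  sort(out)
}

## rooted binarity: every internal node has exactly two children
is_binary_rooted <- function(phy) {
  phy$Nnode == ape::Ntip(phy) - 1L
}
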