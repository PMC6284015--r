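## Matrix Representation with Parsimony: code each internal node of each
## rooted source tree as a binary character (members 1, non-members 0, taxa
## absent from that source tree "?"), export the matrix, and — for small
## instances — find all most-parsimonious supertrees by exhaustive
## enumeration.

#' Encode source trees as an MRP matrix
#'
#' One character per internal node (the root of each source tree is skipped:
#' its all-ones column cannot affect parsimony).  Identical source trees
#' yield duplicated characters on purpose — MRP does not deduplicate.
#'
#' @param trees list of rooted ape `phylo` objects (or `time_tree`s), each
#'   with at least 3 tips; names are used as tree identifiers.
#' @return an `mrp_matrix`: character matrix (taxa x characters) with
#'   entries `"1"`, `"0"`, `"?"`, plus attribute `source` mapping characters
#'   to source trees.
#' @export
encode_mrp <- function(trees) {
  trees <- lapply(trees, function(t) if (inherits(t, "time_tree")) t$phy else t)
  if (length(trees) < 1L) stop("no source trees")
  ids <- names(trees)
  if (is.null(ids)) ids <- paste0("tree", seq_along(trees))
  for (t in trees) {
    if (ape::Ntip(t) < 3L) stop("each source tree needs at least 3 tips")
    if (anyDuplicated(t$tip.label)) {
      stop("duplicate taxon labels within a source tree")
    }
  }
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  cols <- list()
  src <- character(0)
  for (ti in seq_along(trees)) {
    phy <- trees[[ti]]
    nt <- ape::Ntip(phy)
    rt <- nt + 1L
    for (v in setdiff(unique(phy$edge[, 1L]), rt)) {
      members <- phy$tip.label[descendant_tips(phy, v)]
      col <- rep("?", length(taxa))
      names(col) <- taxa
      col[phy$tip.label] <- "0"
      col[members] <- "1"
      cols[[length(cols) + 1L]] <- col
      src <- c(src, ids[ti])
    }
  }
  if (length(cols) == 0L) {
    m <- matrix(character(0), nrow = length(taxa), ncol = 0L,
                dimnames = list(taxa, NULL))
  } else {
    m <- do.call(cbind, cols)
    colnames(m) <- paste0("c", seq_len(ncol(m)))
  }
  structure(m, source = src, class = c("mrp_matrix", class(m)))
}

#' @exportS3Method base::print
print.mrp_matrix <- function(x, ...) {
  cat("MRP matrix:", nrow(x), "taxa x", ncol(x), "characters\n")
  invisible(x)
}

mrp_phydat <- function(m, extra_taxon = NULL) {
  rows <- lapply(seq_len(nrow(m)), function(i) m[i, , drop = TRUE])
  names(rows) <- rownames(m)
  if (!is.null(extra_taxon)) rows[[extra_taxon]] <- rep("0", ncol(m))
  contrast <- matrix(c(1, 0,
                       0, 1,
                       1, 1), ncol = 2, byrow = TRUE,
                     dimnames = list(c("0", "1", "?"), c("0", "1")))
  phangorn::phyDat(do.call(rbind, rows), type = "USER", contrast = contrast)
}

#' Exhaustive maximum-parsimony search for small MRP matrices
#'
#' Enumerates every rooted binary topology on the matrix's taxa and scores
#' each with Fitch parsimony, treating `"?"` as missing.  Rooting is made
#' informative by attaching a hypothetical all-zero outgroup at the root
#' (character absence is ancestral in MRP coding); the outgroup is removed
#' from the returned trees.  All minimal trees are returned — ties are
#' reported, never broken.
#'
#' @param m an `mrp_matrix`.
#' @param max_taxa refuse instances larger than this (default 9; the
#'   enumeration is factorial — full-scale matrices belong in a dedicated
#'   heuristic search program such as TNT, via [write_mrp_tnt()]).
#' @return list with `trees` (multiPhylo of rooted MP trees) and `score`
#'   (parsimony length).
#' @export
exact_parsimony <- function(m, max_taxa = 9L) {
  taxa <- rownames(m)
  if (length(taxa) > max_taxa) {
    stop("instance has ", length(taxa), " taxa (> max_taxa = ", max_taxa,
         "); analyse the exported matrix in an external parsimony program")
  }
  if (length(taxa) < 3L) stop("need at least 3 taxa")
  og <- "mrp_root_outgroup"
  dat <- mrp_phydat(m, extra_taxon = og)
  cand <- phangorn::allTrees(length(taxa) + 1L, rooted = FALSE,
                             tip.label = c(taxa, og))
  scores <- phangorn::parsimony(cand, dat)
  best <- which(scores == min(scores))
  mp <- lapply(cand[best], function(t) {
    t <- ape::root(t, outgroup = og, resolve.root = TRUE)
    ape::drop.tip(t, og)
  })
  class(mp) <- "multiPhylo"
  list(trees = mp, score = min(scores))
}

#' Strict consensus of trees on one taxon set
#'
#' Retains exactly the clades common to all input trees.
#'
#' @param trees list or multiPhylo of rooted trees on the same taxon set.
#' @return a `phylo` (possibly non-binary).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(sets)) != 1L) {
    stop("all trees must share one taxon set for a strict consensus")
  }
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Export an MRP matrix
#'
#' `write_mrp_nexus()` writes a NEXUS DATA block (datatype standard, missing
#' `?`); `write_mrp_tnt()` writes a TNT `xread` block.  Both are meant for
#' full-scale heuristic searches in external software — this package never
#' shells out.
#'
#' @param m an `mrp_matrix`.
#' @param path output file path.
#' @export
write_mrp_nexus <- function(m, path) {
  taxa <- rownames(m)
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "MATRIX",
    sprintf("%s %s", format(taxa), apply(m, 1L, paste, collapse = "")),
    ";",
    "END;"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mrp_nexus
#' @export
write_mrp_tnt <- function(m, path) {
  lines <- c(
    "xread",
    sprintf("%d %d", ncol(m), nrow(m)),
    sprintf("%s %s", rownames(m), apply(m, 1L, paste, collapse = "")),
    ";"
  )
  writeLines(lines, path)
  invisible(path)
}
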