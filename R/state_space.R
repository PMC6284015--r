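## Ranges are encoded as integer bitmasks over the ordered area list:
## area i (1-based) occupies bit 2^(i-1).  The empty ("null") range is mask 0
## and is kept out of the permitted set; the anagenetic generator appends it
## as an explicit absorbing state.

mask_areas <- function(mask, n_areas) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_areas) - 1L)) != 0L)
}

areas_mask <- function(idx) {
  if (length(idx) == 0L) return(0L)
  Reduce(bitwOr, bitwShiftL(1L, as.integer(idx) - 1L))
}

mask_size <- function(mask, n_areas) {
  vapply(mask, function(m) length(mask_areas(m, n_areas)), integer(1))
}

#' Format a range bitmask as an area-code string
#'
#' @param mask integer bitmask(s).
#' @param areas character vector of ordered area codes.
#' @param sep separator between area codes.
#' @return character vector; the empty range prints as `"0"`.
#' @export
format_range <- function(mask, areas, sep = "+") {
  vapply(mask, function(m) {
    idx <- mask_areas(m, length(areas))
    if (length(idx) == 0L) "0" else paste(areas[idx], collapse = sep)
  }, character(1))
}

#' Parse an area-code string into a range bitmask
#'
#' Accepts `"+"`, `";"` or `","` separated area codes, e.g. `"ENA+WEu"`.
#'
#' @inheritParams format_range
#' @param x character vector of range strings.
#' @return integer bitmask vector.
#' @export
parse_range <- function(x, areas) {
  vapply(x, function(s) {
    s <- trimws(s)
    if (s == "" || s == "0") return(0L)
    codes <- trimws(strsplit(s, "[+;,]")[[1]])
    idx <- match(codes, areas)
    if (anyNA(idx)) {
      stop("unknown area code(s): ", paste(codes[is.na(idx)], collapse = ", "))
    }
    areas_mask(idx)
  }, integer(1), USE.NAMES = FALSE)
}

range_connected <- function(mask, adjacency) {
  idx <- mask_areas(mask, nrow(adjacency))
  k <- length(idx)
  if (k <= 1L) return(TRUE)
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- idx[1L]
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (a in frontier) {
      reach <- which(adjacency[a, idx] & !seen)
      if (length(reach) > 0L) {
        seen[reach] <- TRUE
        nxt <- c(nxt, idx[reach])
      }
    }
    frontier <- nxt
  }
  all(seen)
}

validate_adjacency <- function(adjacency, areas = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix")
  }
  adjacency <- adjacency != 0
  if (!isTRUE(all(adjacency == t(adjacency)))) stop("adjacency must be symmetric")
  diag(adjacency) <- TRUE
  if (!is.null(areas)) dimnames(adjacency) <- list(areas, areas)
  if (nrow(adjacency) > 1L && !any(adjacency[upper.tri(adjacency)])) {
    stop("adjacency has no off-diagonal links: every area is isolated")
  }
  adjacency
}

#' Build the permitted range state space
#'
#' Enumerates every non-empty subset of the areas that (i) has at most
#' `max_range_size` areas and (ii) is connected under the area-adjacency
#' relation (dispersal cannot assemble a range that straddles a barrier).
#' Connectivity can be switched off, in which case only the size cap applies.
#'
#' @param areas character vector of area codes (order is preserved and defines
#'   the bit layout of range masks).
#' @param adjacency square 0/1 or logical matrix, symmetric; the diagonal is
#'   forced `TRUE`.  `NULL` means all areas mutually adjacent.
#' @param max_range_size largest number of areas a single range may span.
#' @param connected_only require ranges to be adjacency-connected
#'   (default `TRUE`).
#' @return an object of class `range_space`: list with `areas`, `adjacency`,
#'   `masks` (integer bitmasks of the permitted ranges, deterministic order:
#'   increasing size, then increasing mask), `labels`, `max_range_size`,
#'   `connected_only`.
#' @examples
#' sp <- build_state_space(c("A", "B", "C"), max_range_size = 2)
#' sp$labels
#' @export
build_state_space <- function(areas, adjacency = NULL,
                              max_range_size = 4L, connected_only = TRUE) {
  areas <- as.character(areas)
  n <- length(areas)
  if (n < 1L) stop("need at least one area")
  if (anyDuplicated(areas)) stop("duplicate area codes")
  if (max_range_size < 1L) stop("max_range_size must be >= 1")
  if (is.null(adjacency)) {
    adjacency <- matrix(TRUE, n, n, dimnames = list(areas, areas))
  } else {
    adjacency <- validate_adjacency(adjacency, areas)
  }
  if (n > 20L) stop("bitmask state space supports at most 20 areas")
  all_masks <- seq_len(bitwShiftL(1L, n) - 1L)
  sizes <- mask_size(all_masks, n)
  keep <- sizes <= max_range_size
  if (connected_only) {
    keep[keep] <- vapply(all_masks[keep], range_connected, logical(1),
                         adjacency = adjacency)
  }
  masks <- all_masks[keep]
  ord <- order(mask_size(masks, n), masks)
  masks <- masks[ord]
  out <- list(areas = areas, adjacency = adjacency, masks = masks,
              labels = format_range(masks, areas),
              max_range_size = as.integer(max_range_size),
              connected_only = connected_only)
  class(out) <- "range_space"
  out
}

#' @exportS3Method base::print
print.range_space <- function(x, ...) {
  cat("Range state space: ", length(x$areas), " areas, ",
      length(x$masks), " permitted ranges (max size ", x$max_range_size,
      if (x$connected_only) ", adjacency-connected" else "", ")\n", sep = "")
  cat("Areas:", paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

state_index <- function(space, mask) {
  i <- match(mask, space$masks)
  if (anyNA(i)) {
    stop("range(s) not in permitted state space: ",
         paste(format_range(mask[is.na(i)], space$areas), collapse = ", "))
  }
  i
}

#' Read / write an area-adjacency matrix as CSV
#'
#' Square 0/1 matrix with the area codes as both header row and first column.
#'
#' @param path file path.
#' @return for the reader, a logical matrix with area-code dimnames.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m))) {
    stop("adjacency CSV row and column names differ")
  }
  validate_adjacency(m, rownames(m))
}

#' @rdname read_adjacency
#' @param adjacency logical/0-1 square matrix with dimnames.
#' @export
write_adjacency <- function(adjacency, path) {
  m <- ifelse(adjacency != 0, 1L, 0L)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
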