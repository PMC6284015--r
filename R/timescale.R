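## Geological timescale handling: stage tables, informal half-stage ("substage")
## time bins, and assignment of event times to bins.  Ages are Ma before
## present, larger = older.

#' Read and validate a geological stage table
#'
#' The table must list stages in order from oldest to youngest, with strictly
#' decreasing, contiguous boundary ages (each stage's younger boundary equals
#' the next stage's older boundary).
#'
#' @param path CSV with columns `stage,older_ma,younger_ma,period`; if `NULL`,
#'   the packaged Carboniferous--Permian table is used.  Boundary ages in the
#'   packaged table follow the ICS International Chronostratigraphic Chart
#'   (v2023/06); they are data, not code, and can be replaced by pointing
#'   `path` at an edited copy.
#' @return a `stage_table` data frame.
#' @export
read_stage_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "carboniferous_permian_stages.csv",
                        package = "pangaea", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_stage_table(df)
}

#' @rdname read_stage_table
#' @param df data frame with columns `stage`, `older_ma`, `younger_ma`,
#'   `period`.
#' @export
as_stage_table <- function(df) {
  need <- c("stage", "older_ma", "younger_ma", "period")
  if (!all(need %in% names(df))) {
    stop("stage table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df) < 1L) stop("empty stage table")
  if (any(df$older_ma <= df$younger_ma)) {
    stop("each stage must have older_ma > younger_ma")
  }
  if (nrow(df) > 1L) {
    if (any(diff(df$older_ma) >= 0)) {
      stop("stages must be ordered oldest to youngest with decreasing ages")
    }
    gaps <- df$younger_ma[-nrow(df)] - df$older_ma[-1L]
    if (any(abs(gaps) > 1e-9)) {
      stop("stage table is not contiguous at: ",
           paste(df$stage[-nrow(df)][abs(gaps) > 1e-9], collapse = ", "))
    }
  }
  class(df) <- c("stage_table", "data.frame")
  df
}

#' Build informal substage bins by halving each stage
#'
#' Each international stage is split at its midpoint into an `-early` and a
#' `-late` half of equal duration; the bins tile the table's time span without
#' gaps or overlap.
#'
#' @param stages a `stage_table` (see [read_stage_table()]).
#' @return a `time_bins` data frame with columns `label`, `older_ma`,
#'   `younger_ma`, `duration`, ordered old to young.
#' @examples
#' st <- as_stage_table(data.frame(stage = "Kasimovian", older_ma = 307,
#'                                 younger_ma = 303.7, period = "Carboniferous"))
#' make_substage_bins(st)
#' @export
make_substage_bins <- function(stages) {
  stages <- as_stage_table(as.data.frame(stages))
  mid <- (stages$older_ma + stages$younger_ma) / 2
  out <- data.frame(
    label = as.vector(rbind(paste0(stages$stage, "-early"),
                            paste0(stages$stage, "-late"))),
    older_ma = as.vector(rbind(stages$older_ma, mid)),
    younger_ma = as.vector(rbind(mid, stages$younger_ma)),
    stringsAsFactors = FALSE
  )
  out$duration <- out$older_ma - out$younger_ma
  class(out) <- c("time_bins", "data.frame")
  out
}

validate_bins <- function(bins) {
  stopifnot(all(c("label", "older_ma", "younger_ma", "duration") %in%
                  names(bins)))
  if (any(bins$duration <= 0)) stop("bins must have positive duration")
  if (nrow(bins) > 1L &&
      any(abs(bins$younger_ma[-nrow(bins)] - bins$older_ma[-1L]) > 1e-9)) {
    stop("bins must tile the window contiguously, old to young")
  }
  invisible(bins)
}

#' Assign event times to substage bins
#'
#' The interval convention is half-open with the older edge inclusive:
#' a time `t` belongs to the bin with `older_ma >= t > younger_ma`, except
#' that the youngest bin also includes its own younger edge so the bins
#' partition the closed study window.  Times outside the window return `NA`
#' with a warning (events are dropped loudly, never silently).
#'
#' @param t numeric vector of times (Ma).
#' @param bins a `time_bins` data frame.
#' @param warn warn about out-of-window times (default `TRUE`).
#' @return character vector of bin labels (`NA` for out-of-window times).
#' @export
assign_time_to_bin <- function(t, bins, warn = TRUE) {
  validate_bins(bins)
  oldest <- bins$older_ma[1L]
  youngest <- bins$younger_ma[nrow(bins)]
  ## index by how many older edges are >= t; older edge inclusive
  idx <- findInterval(-t, -bins$older_ma)
  out <- rep(NA_character_, length(t))
  inwin <- t <= oldest & t >= youngest
  hit <- inwin & idx >= 1L & idx <= nrow(bins)
  out[hit] <- bins$label[idx[hit]]
  if (warn && any(!inwin)) {
    warning(sum(!inwin), " event time(s) outside the study window [",
            youngest, ", ", oldest, "] Ma were dropped")
  }
  out
}

#' @rdname make_substage_bins
#' @param bins a `time_bins` data frame.
#' @param path output CSV path.
#' @export
write_bins <- function(bins, path) {
  utils::write.csv(as.data.frame(bins), path, row.names = FALSE)
  invisible(path)
}
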