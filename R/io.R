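## Tabular I/O: tip-range tables and rate tables are plain CSV.

#' Read / write a tip-range table
#'
#' CSV schema: `taxon,areas,first_ma,last_ma` where `areas` is a
#' semicolon-separated list of area codes (e.g. `"ENA;WEu"`).
#'
#' @param path CSV path.
#' @return data frame with columns `taxon`, `areas`, `first_ma`, `last_ma`.
#' @export
read_tip_ranges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "areas", "first_ma", "last_ma")
  if (!all(need %in% names(df))) {
    stop("tip-range CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in tip-range table")
  df[, need]
}

#' @rdname read_tip_ranges
#' @param df tip-range data frame.
#' @export
write_tip_ranges <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## tip-range data frame -> named fad/lad vectors
tip_strat <- function(df) {
  list(fad = stats::setNames(df$first_ma, df$taxon),
       lad = stats::setNames(df$last_ma, df$taxon))
}

#' Export a rate series as CSV
#'
#' Schema: `bin,older_ma,younger_ma,kind,clade,observed,null,corrected,se,n_iter`.
#'
#' @param series rate-series data frame from [aggregate_series()].
#' @param path output CSV path.
#' @export
write_rate_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
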