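#' Normalize gene symbols
#'
#' Gene symbols are compared after uppercasing and trimming surrounding
#' whitespace. No synonym or alias resolution is attempted.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c(" col2a1", "Fbn1 "))
normalize_symbol <- function(x) {
  toupper(stringr::str_trim(as.character(x)))
}

#' Normalize disease names
#'
#' Disease names act as identity keys when merging association sources, so
#' they are lowercased, trimmed, and internal whitespace runs are collapsed
#' to single spaces. The original string should be retained by callers that
#' need it for display.
#'
#' @param x Character vector of raw disease names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_disease(c("  Marfan   Syndrome ", "ALPORT syndrome"))
normalize_disease <- function(x) {
  tolower(stringr::str_squish(as.character(x)))
}

# Round half-up to `digits` decimals (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Shared accessor for the per-read bookkeeping attached by the readers.

#' Retrieve the load report attached to a table by a reader
#'
#' Every reader records how many raw rows it saw and what happened to them.
#' The counts always satisfy `rows_in = records_out + dropped + rejected`,
#' where `dropped` aggregates rows missing a mandatory field
#' (`dropped_missing`) and exact duplicates removed (`dropped_duplicate`),
#' and `rejected` counts rows with invalid values (for example a p-value
#' outside (0, 1], or a self-interaction pair).
#'
#' @param x A tibble returned by one of the `read_*` functions.
#' @return A named list of counts.
#' @export
load_report <- function(x) {
  attr(x, "load_report")
}

new_load_report <- function(rows_in, records_out, dropped_missing = 0L,
                            dropped_duplicate = 0L, rejected = 0L, ...) {
  rep <- list(
    rows_in = as.integer(rows_in),
    records_out = as.integer(records_out),
    dropped = as.integer(dropped_missing + dropped_duplicate),
    dropped_missing = as.integer(dropped_missing),
    dropped_duplicate = as.integer(dropped_duplicate),
    rejected = as.integer(rejected),
    ...
  )
  stopifnot(rep$rows_in == rep$records_out + rep$dropped + rep$rejected)
  rep
}

with_load_report <- function(x, report) {
  attr(x, "load_report") <- report
  x
}
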