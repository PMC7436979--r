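#' Normalize gene symbols
#'
#' Gene identifiers throughout the package are HGNC-style official symbols:
#' trimmed, uppercased, non-empty strings without internal whitespace. This is
#' the single normalization applied everywhere; no alias mapping is attempted
#' (inputs are expected to carry official symbols already), but see
#' [apply_alias_table()] for an optional explicit remapping.
#'
#' @param x character vector of raw symbols.
#' @param drop_invalid if `TRUE` (default), empty/NA entries are silently
#'   dropped and entries with internal whitespace raise an error; if `FALSE`
#'   an error is raised on any invalid entry.
#' @return character vector of normalized symbols (order preserved,
#'   duplicates kept — callers deduplicate where their contract requires it).
#' @export
#' @examples
#' normalize_genes(c(" tp53", "IL6 ", "il6"))
normalize_genes <- function(x, drop_invalid = TRUE) {
  x <- toupper(trimws(as.character(x)))
  bad <- is.na(x) | x == ""
  if (any(bad)) {
    if (!drop_invalid) stop("empty or missing gene symbol", call. = FALSE)
    x <- x[!bad]
  }
  ws <- grepl("[[:space:]]", x)
  if (any(ws)) {
    stop(sprintf("gene symbols may not contain whitespace: %s",
                 paste(utils::head(x[ws], 3L), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Remap gene identifiers through a two-column alias table
#'
#' Optional pre-processing step for inputs whose identifiers are not official
#' symbols. Identifiers found in the table's first column are replaced by the
#' second column; everything else passes through unchanged. Both sides are
#' normalized first.
#'
#' @param x character vector of identifiers.
#' @param alias data frame whose first two columns are (alias, symbol).
#' @return character vector of remapped, normalized symbols.
#' @export
apply_alias_table <- function(x, alias) {
  stopifnot(is.data.frame(alias), ncol(alias) >= 2L)
  from <- normalize_genes(alias[[1L]])
  to <- normalize_genes(alias[[2L]])
  stopifnot(length(from) == length(to))
  x <- normalize_genes(x)
  idx <- match(x, from)
  ifelse(is.na(idx), x, to[idx])
}
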