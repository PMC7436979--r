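# Internal helpers shared across modules.

#' Evaluate code with a local RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their seed and never
#' clobber global randomness.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Read a delimited table; separator inferred from the file extension
# (.csv -> comma, anything else -> tab).
read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, blank.lines.skip = TRUE,
                    strip.white = TRUE)
}

# Case-insensitive column lookup. `wanted` is either an explicit name (from a
# user dialect) or a vector of conventional candidates. Leading '#' in the
# header (STRING export writes "#node1") is ignored.
find_column <- function(df, wanted, what, required = TRUE) {
  cols <- sub("^#", "", tolower(names(df)))
  for (w in tolower(wanted)) {
    hit <- which(cols == w)
    if (length(hit)) return(names(df)[hit[1L]])
  }
  if (required) {
    stop(sprintf("required column '%s' (one of: %s) not found in table",
                 what, paste(wanted, collapse = ", ")), call. = FALSE)
  }
  NULL
}

# Canonical JSON of a config list, used for the run-report config hash.
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
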