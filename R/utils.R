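# Internal helpers shared across modules.

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Empty strings after
#' normalization are dropped by callers, never kept as identifiers.
#' @param x character vector of raw symbols
#' @return normalized character vector
#' @keywords internal
#' @noRd
norm_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Run code with a temporary RNG state so generators are pure in (spec, seed)
# and never disturb the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "nbhub_format_error")
}

abort_range <- function(msg) {
  rlang::abort(msg, class = "nbhub_range_error")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "nbhub_config_error")
}
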