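# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_config <- function(...) {
  stop(structure(
    class = c("tm_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
stop_data <- function(...) {
  stop(structure(
    class = c("tm_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Delimiter sniffing for CSV/TSV: tab wins if the header contains one.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Full-precision numeric formatting for text round-trips.
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}
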