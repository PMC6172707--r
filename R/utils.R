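# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("tmtsplice_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("tmtsplice_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_config(name, " must be a single number in [", lower, ", ", upper, "]")
  invisible(x)
}

# attach a filter log (input count, output count, reason histogram) to `x`
with_filter_log <- function(x, n_in, n_out, reasons = integer(0)) {
  attr(x, "filter_log") <- list(n_in = n_in, n_out = n_out,
                                reasons = reasons)
  x
}

#' Retrieve the filter log attached to a filtering result
#'
#' Every filtering operation in the package records how many records went in,
#' how many came out, and a histogram of exclusion reasons.
#'
#' @param x An object returned by a filtering operation.
#' @return A list with elements `n_in`, `n_out` and `reasons`, or `NULL`.
#' @export
filter_log <- function(x) attr(x, "filter_log")

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# pairwise mean of two vectors, used for the TOM "mean" denominator
pmean <- function(a, b) (a + b) / 2
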