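# Internal helpers shared across modules.

#' @noRd
fishda_stop <- function(message, class) {
  stop(structure(
    class = c(class, "fishda_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so seeded rendering does not disturb a caller's
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

#' Recursively strip S3 classes for JSON serialization
#' @noRd
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @noRd
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
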