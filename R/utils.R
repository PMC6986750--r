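# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr` and
#' restores the previous state on exit, so generators are pure functions of
#' (arguments, seed) without clobbering global randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Ordered month labels of the growth-response window
#'
#' Sixteen labels spanning June of the year prior to ring formation
#' (`p06`..`p12`) through September of the ring-formation year
#' (`c01`..`c09`). Correlations between the growth index and lagged monthly
#' climate are computed for exactly these months.
#'
#' @return character vector of 16 labels in fixed order.
#' @export
#' @examples
#' month_window()
month_window <- function() {
  c(sprintf("p%02d", 6:12), sprintf("c%02d", 1:9))
}

# Split a month label into lag ("p" prior year / "c" current year) and month.
parse_month_label <- function(label) {
  if (!label %in% month_window())
    stop("month label '", label, "' is not in the 16-month window ",
         "(p06..p12, c01..c09)", call. = FALSE)
  list(lag = substr(label, 1, 1), month = as.integer(substr(label, 2, 3)))
}

# stopifnot with a readable message
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
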