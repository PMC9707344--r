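# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed neurokin error
#'
#' All anticipated failure modes raise conditions inheriting from
#' `neurokin_error` plus a specific subclass, so callers can distinguish
#' format errors from degenerate data without matching message text.
#'
#' @param message error message.
#' @param class specific condition class, e.g. `"neurokin_format_error"`.
#' @keywords internal
nk_stop <- function(message, class) {
  stop(structure(
    class = c(class, "neurokin_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Round x to the nearest odd integer >= 3 (filter window lengths).
odd_window <- function(x) {
  k <- max(3L, as.integer(round(x)))
  if (k %% 2L == 0L) k + 1L else k
}

# Euclidean norm of rows of a matrix (or of a vector).
row_norms <- function(m) {
  if (is.null(dim(m))) return(abs(m))
  sqrt(rowSums(m^2))
}

# Polyline arc length of an ordered set of points (matrix, one row per point).
polyline_length <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Derive a stream-specific RNG seed from a base seed, keeping the result
# within the 32-bit signed integer range R requires.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 7919 + as.numeric(p) * 104729) %% 2147483629
  as.integer(acc) + 1L
}
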