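#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_mcda <- function(msg, class) {
  stop(structure(
    class = c(class, "mcda_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Round a weight vector for display so the printed values sum to 100
#'
#' Largest-remainder rounding at two decimal places: each weight is floored
#' to 0.01 and the remaining hundredths are handed out in order of largest
#' fractional remainder, so the displayed set sums to exactly 100.00 whenever
#' the full-precision weights do.
#'
#' @param weights numeric vector of percentage weights summing to 100.
#' @param digits decimal places to keep (default 2, as weights are printed).
#' @return numeric vector, same names, summing to `round(sum(weights), digits)`.
#' @export
#' @examples
#' display_weights(c(a = 100 / 3, b = 100 / 3, c = 100 / 3))
display_weights <- function(weights, digits = 2) {
  stopifnot(is.numeric(weights), all(is.finite(weights)))
  scale <- 10^digits
  scaled <- weights * scale
  floors <- floor(scaled)
  units_left <- round(sum(scaled)) - sum(floors)
  out <- floors
  if (units_left > 0) {
    take <- order(scaled - floors, decreasing = TRUE)[seq_len(units_left)]
    out[take] <- out[take] + 1
  }
  out / scale
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All fixture generators funnel through this.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
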