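# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operators (e.g. the random-neighbor DSPO) do not
#' perturb global reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Local extrema (interior maxima and minima) of a numeric trace.
# Plateaus are collapsed to their first sample.  Returns a data.frame with
# the sample index, value and kind (+1 max, -1 min), ordered by index.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(data.frame(index = integer(), value = numeric(), kind = integer()))
  }
  d <- diff(x)
  s <- sign(d)
  # carry the last nonzero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turns <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1
  data.frame(
    index = turns,
    value = x[turns],
    kind = as.integer(-s[turns]) # slope was +1 before a max
  )
}

# Significant alternating extrema: keep extrema whose adjacent swings
# (absolute value differences to the neighboring extrema, with the trace
# endpoints acting as outer anchors) are both at least `prominence`.
significant_extrema <- function(x, prominence) {
  ex <- local_extrema(x)
  if (nrow(ex) == 0) return(ex)
  anchors <- c(x[1], ex$value, x[length(x)])
  keep <- logical(nrow(ex))
  for (j in seq_len(nrow(ex))) {
    left <- abs(anchors[j + 1] - anchors[j])
    right <- abs(anchors[j + 2] - anchors[j + 1])
    keep[j] <- left >= prominence && right >= prominence
  }
  ex[keep, , drop = FALSE]
}
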