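#' Multichannel potential field
#'
#' A nodes x samples matrix of potentials (mV) sampled at a common
#' frequency.  Rows correspond to mesh nodes (unipolar electrograms); the
#' `role` records where the field sits in the additive measurement model
#' measured = clean + Gaussian noise + baseline wander + other noise.
#'
#' @param values Numeric matrix, nodes x samples, in mV; all finite.
#' @param fs Sampling frequency in Hz.
#' @param role One of `"measured"`, `"clean"`, `"residual"`.
#' @return Object of class `potential_field`.
#' @export
potential_field <- function(values, fs,
                            role = c("measured", "clean", "residual")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stopf("potential values must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stopf("fs must be a positive scalar (Hz)")
  structure(list(values = values, fs = fs, role = role),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential_field (%s): %d nodes x %d samples at %g Hz (%.3f s)\n",
              x$role, nrow(x$values), ncol(x$values), x$fs,
              ncol(x$values) / x$fs))
  invisible(x)
}

# Time axis of a potential field (seconds, first sample at t = 0).
field_time <- function(field) (seq_len(ncol(field$values)) - 1) / field$fs

#' Analysis time window
#'
#' Start and end instants, in seconds, of the segment under study
#' (typically one heartbeat).
#'
#' @param t_in,t_end Window bounds in seconds, `0 <= t_in < t_end`.
#' @return Object of class `time_window`.
#' @export
time_window <- function(t_in, t_end) {
  if (!(t_in >= 0 && t_end > t_in)) stopf("need 0 <= t_in < t_end")
  structure(list(t_in = t_in, t_end = t_end), class = "time_window")
}

# Sample indices covered by a window; errors if the window leaves the record.
window_indices <- function(window, fs, n_samples) {
  i1 <- floor(window$t_in * fs + 1e-9) + 1
  i2 <- floor(window$t_end * fs + 1e-9) + 1
  if (i2 > n_samples) i2 <- n_samples
  if (i1 > n_samples) stopf("window starts beyond the record")
  i1:i2
}

#' Cubic-spline baseline-wander removal
#'
#' Estimates each node's baseline as a natural cubic spline through knots
#' placed every `Tw` seconds (first/last knots clamped to the record ends)
#' and subtracts it.  The knot ordinate rule is configurable: the default
#' interpolates the signal sample at the knot instant; `"mean"` and
#' `"median"` use a window of width `Tw` centred on the knot.  The
#' decomposition is conservative: `detrended + residual` reconstructs the
#' input sample-exactly, where the residual is the removed baseline.
#'
#' @param field A [potential_field()].
#' @param Tw Knot separation in seconds; must be shorter than the record.
#' @param knot_rule `"sample"`, `"mean"` or `"median"`.
#' @return List with `detrended` (role `"clean"`) and `residual` (the
#'   baseline estimate, role `"residual"`), both [potential_field()]s.
#' @export
remove_baseline <- function(field, Tw,
                            knot_rule = c("sample", "mean", "median")) {
  knot_rule <- match.arg(knot_rule)
  dur <- ncol(field$values) / field$fs
  if (Tw <= 0) stopf("Tw must be positive")
  if (Tw >= dur) stopf("Tw (%g s) must be shorter than the record (%g s)", Tw, dur)
  t <- field_time(field)
  knots <- seq(0, dur, by = Tw)
  if (max(knots) < t[length(t)]) knots <- c(knots, t[length(t)])
  knots[length(knots)] <- t[length(t)] # clamp last knot to the record end
  baseline <- matrix(0, nrow(field$values), ncol(field$values))
  for (r in seq_len(nrow(field$values))) {
    x <- field$values[r, ]
    ords <- vapply(knots, function(tk) {
      if (knot_rule == "sample") {
        x[which.min(abs(t - tk))]
      } else {
        sel <- t >= tk - Tw / 2 & t <= tk + Tw / 2
        if (knot_rule == "mean") mean(x[sel]) else stats::median(x[sel])
      }
    }, numeric(1))
    sf <- stats::splinefun(knots, ords, method = "natural")
    baseline[r, ] <- sf(t)
  }
  list(
    detrended = potential_field(field$values - baseline, field$fs, "clean"),
    residual = potential_field(baseline, field$fs, "residual")
  )
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design of the stated order forward and
#' backward (`signal::filtfilt`), giving zero net phase and the squared
#' magnitude response of the one-pass design.  Defaults follow common
#' practice for epicardial potential conditioning: 100 Hz cutoff,
#' 9th-order design.
#'
#' @param field A [potential_field()].
#' @param fc Cutoff frequency in Hz, `fc < fs / 2`.
#' @param order Design order of the one-pass filter.
#' @return List with `filtered` (role `"clean"`) and `residual`
#'   (`input - filtered`, role `"residual"`); the decomposition is
#'   sample-exact.
#' @export
lowpass_filter <- function(field, fc = 100, order = 9) {
  if (fc <= 0 || fc >= field$fs / 2)
    stopf("fc must lie in (0, fs/2) = (0, %g)", field$fs / 2)
  if (order < 1) stopf("order must be >= 1")
  bf <- signal::butter(order, fc / (field$fs / 2), type = "low")
  n <- ncol(field$values)
  # odd-reflection padding at both ends so start-up transients decay in
  # the padding (constant signals pass exactly)
  pad <- min(n - 1, max(3 * (order + 1), round(field$fs / 4)))
  filtered <- t(apply(field$values, 1, function(x) {
    ext <- c(2 * x[1] - x[(pad + 1):2],
             x,
             2 * x[n] - x[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  }))
  list(
    filtered = potential_field(filtered, field$fs, "clean"),
    residual = potential_field(field$values - filtered, field$fs, "residual")
  )
}

#' Envelope-based beat segmentation
#'
#' Computes the across-node root-mean-square envelope of a detrended
#' field, smooths it with a moving average, and marks beats as the
#' connected regions where the envelope exceeds `threshold` times its
#' maximum, each expanded by `margin` seconds and clipped to the record.
#' Overlapping expanded regions are merged.
#'
#' @param field A [potential_field()] (detrended).
#' @param threshold Fraction of the envelope maximum (default 0.3).
#' @param margin Expansion of each region, seconds (default 0.05).
#' @param smooth Moving-average width for the envelope, seconds.
#' @return List of [time_window()]s, time-ordered and non-overlapping;
#'   empty for a flat field.
#' @export
segment_beats <- function(field, threshold = 0.3, margin = 0.05,
                          smooth = 0.05) {
  env <- sqrt(colMeans(field$values^2))
  w <- max(1, round(smooth * field$fs))
  if (w > 1) {
    kernel <- rep(1 / w, w)
    env <- stats::filter(env, kernel, sides = 2)
    env[is.na(env)] <- 0
    env <- as.numeric(env)
  }
  mx <- max(env)
  if (mx == 0) return(list())
  above <- env > threshold * mx
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  t <- field_time(field)
  dur <- ncol(field$values) / field$fs
  wins <- mapply(function(s, e) {
    c(max(0, t[s] - margin), min(dur, t[e] + margin))
  }, starts, ends, SIMPLIFY = FALSE)
  # merge overlaps after expansion
  merged <- list()
  for (wn in wins) {
    k <- length(merged)
    if (k > 0 && wn[1] <= merged[[k]][2]) {
      merged[[k]][2] <- max(merged[[k]][2], wn[2])
    } else {
      merged[[length(merged) + 1]] <- wn
    }
  }
  lapply(merged, function(wn) time_window(wn[1], wn[2]))
}
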