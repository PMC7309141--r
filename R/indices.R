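#' Peak-to-peak amplitude
#'
#' @param signal Numeric trace (mV) or a `bipolar_egm`.
#' @param window Optional [time_window()] restricting the computation
#'   (requires `fs`); by default the whole trace is used.
#' @param fs Sampling frequency, needed only with `window` on a plain
#'   trace.
#' @return Peak-to-peak voltage (max - min), mV.
#' @export
peak_to_peak <- function(signal, window = NULL, fs = NULL) {
  if (inherits(signal, "bipolar_egm")) {
    fs <- signal$fs
    signal <- signal$signal
  }
  if (!is.null(window)) {
    if (is.null(fs)) stopf("fs required to apply a window to a plain trace")
    signal <- signal[window_indices(window, fs, length(signal))]
  }
  if (length(signal) == 0) stopf("empty window")
  max(signal) - min(signal)
}

#' Per-node amplitude map
#'
#' Peak-to-peak voltage per node, either from a list of bipolar
#' electrograms ([bipolar_field()]) or from a unipolar
#' [potential_field()] over a window.
#'
#' @param x List of `bipolar_egm`s or a `potential_field`.
#' @param window Required [time_window()] when `x` is a potential field.
#' @return Object of class `amplitude_map`: `vpp` (mV per node, `NA` for
#'   excluded nodes), `source` (`"unipolar"` or the DSPO id), `window`.
#' @export
amplitude_map <- function(x, window = NULL) {
  if (inherits(x, "potential_field")) {
    if (is.null(window)) stopf("window required for a unipolar amplitude map")
    idx <- window_indices(window, x$fs, ncol(x$values))
    vpp <- apply(x$values[, idx, drop = FALSE], 1, function(v) max(v) - min(v))
    src <- "unipolar"
  } else {
    vpp <- vapply(x, function(b) {
      if (isTRUE(b$excluded)) NA_real_ else max(b$signal) - min(b$signal)
    }, numeric(1))
    src <- x[[1]]$dspo$id
    window <- x[[1]]$window
  }
  structure(list(vpp = vpp, source = src, window = window),
            class = "amplitude_map")
}

#' Voltage-based tissue classification
#'
#' Classifies tissue under each node from electrogram peak-to-peak
#' voltage, with the thresholds used in electrophysiological practice:
#' bipolar — scar below 0.5 mV, border 0.5 to 1.5 mV, healthy at or above
#' 1.5 mV; unipolar — scar below 3 mV, border 3 to 5 mV, healthy at or
#' above 5 mV.  Boundary convention: scar strictly below the low edge,
#' healthy at or above the high edge.
#'
#' @param vpp Peak-to-peak voltages (mV, >= 0) or an `amplitude_map`.
#' @param mode `"bipolar"` or `"unipolar"` (selects default thresholds).
#' @param thresholds Length-2 numeric `(low, high)` overriding the
#'   defaults.
#' @return Object of class `tissue_class_map`: `label` (factor with
#'   levels scar/border/healthy, `NA` for `NA` input), `thresholds`,
#'   `mode`.
#' @export
classify_tissue <- function(vpp, mode = c("bipolar", "unipolar"),
                            thresholds = NULL) {
  mode <- match.arg(mode)
  if (inherits(vpp, "amplitude_map")) vpp <- vpp$vpp
  if (any(vpp < 0, na.rm = TRUE)) stopf("negative peak-to-peak voltage")
  thr <- thresholds %||% if (mode == "bipolar") c(0.5, 1.5) else c(3, 5)
  lab <- ifelse(is.na(vpp), NA_character_,
                ifelse(vpp < thr[1], "scar",
                       ifelse(vpp < thr[2], "border", "healthy")))
  structure(
    list(label = factor(lab, levels = c("scar", "border", "healthy")),
         thresholds = thr, mode = mode),
    class = "tissue_class_map"
  )
}

#' Amplitude-zone histogram
#'
#' Counts nodes per amplitude zone: the first bin is everything below the
#' first edge, interior bins are half-open `[e_k, e_{k+1})`, and the last
#' bin is open above the final edge.  Counts always sum to the number of
#' (non-`NA`) nodes.
#'
#' @param vpp Peak-to-peak voltages (mV) or an `amplitude_map`.
#' @param edges Strictly increasing numeric vector of zone edges (mV).
#' @return Named integer vector of `length(edges) + 1` zone counts.
#' @export
amplitude_histogram <- function(vpp, edges) {
  if (inherits(vpp, "amplitude_map")) vpp <- vpp$vpp
  if (length(edges) < 1 || any(diff(edges) <= 0))
    stopf("edges must be strictly increasing")
  vpp <- vpp[!is.na(vpp)]
  bin <- findInterval(vpp, edges) # 0 = below first edge
  counts <- tabulate(bin + 1L, nbins = length(edges) + 1L)
  lo <- c("-Inf", format(edges, trim = TRUE))
  hi <- c(format(edges, trim = TRUE), "Inf")
  names(counts) <- paste0("[", lo, ",", hi, ")")
  counts
}

#' Notch-based fragmentation count
#'
#' Algorithmic stand-in for manual fragmentation assessment: the signal
#' is restricted to its main deflection (the largest absolute excursion)
#' plus a margin, prominence-significant local extrema are counted, the
#' two extrema of a clean biphasic deflection are discounted, and each
#' remaining direction-reversal pair counts as one notch.
#'
#' @param bipolar A `bipolar_egm` or a numeric trace.
#' @param fs Sampling frequency (taken from the `bipolar_egm` when
#'   given).
#' @param prominence Minimum swing for an extremum to count, mV (default
#'   0.05).
#' @param margin Half-width of the deflection window around the main
#'   excursion, seconds (default 0.05).
#' @return Integer notch count (0 for flat or clean biphasic signals).
#' @export
count_notches <- function(bipolar, fs = NULL, prominence = 0.05,
                          margin = 0.05) {
  if (inherits(bipolar, "bipolar_egm")) {
    fs <- bipolar$fs
    x <- bipolar$signal
  } else {
    x <- as.numeric(bipolar)
    if (is.null(fs)) stopf("fs required for a plain trace")
  }
  if (all(!is.finite(x)) || all(x == 0)) return(0L)
  peak <- which.max(abs(x))
  half <- round(margin * fs)
  sel <- max(1, peak - half):min(length(x), peak + half)
  ex <- significant_extrema(x[sel], prominence)
  max(0L, as.integer(floor((nrow(ex) - 2) / 2)))
}

#' Per-node fragmentation map
#'
#' @param begms List of `bipolar_egm`s from [bipolar_field()].
#' @param prominence,margin Passed to [count_notches()].
#' @param min_notches Notch count at or above which a node is flagged
#'   fragmented (default 1).
#' @return Object of class `fragmentation_map`: `notches` (integer per
#'   node, `NA` for excluded nodes), `fragmented` (logical).
#' @export
fragmentation_map <- function(begms, prominence = 0.05, margin = 0.05,
                              min_notches = 1) {
  notches <- vapply(begms, function(b) {
    if (isTRUE(b$excluded)) NA_integer_
    else count_notches(b, prominence = prominence, margin = margin)
  }, integer(1))
  structure(
    list(notches = notches, fragmented = notches >= min_notches,
         min_notches = min_notches, prominence = prominence,
         margin = margin),
    class = "fragmentation_map"
  )
}

#' Dice overlap coefficient between two node sets
#'
#' @param a,b Logical vectors of equal length (node membership).
#' @return `2|A & B| / (|A| + |B|)`; 1 when both sets are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a, na.rm = TRUE) + sum(b, na.rm = TRUE)
  if (denom == 0) return(1)
  2 * sum(a & b, na.rm = TRUE) / denom
}
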