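#' M-mode (time-space) representation along a node path
#'
#' Stacks the signals of an ordered line of mesh nodes into a
#' path-length x samples matrix, with the cumulative path distance (mm)
#' attached, so spatial-temporal structure along the line can be
#' visualised and correlated.
#'
#' @param field A [potential_field()].
#' @param path A `mesh_path` from [select_path()], or an integer vector of
#'   node indices (then `mesh` must be given to compute distances).
#' @param mesh Optional [tri_mesh()], required when `path` is a plain
#'   vector.
#' @return Object of class `mmode_field`: `path`, `distances`
#'   (cumulative, mm, starting at 0 and strictly increasing), `signals`,
#'   `fs`.
#' @export
extract_mmode <- function(field, path, mesh = NULL) {
  if (inherits(path, "mesh_path")) {
    nodes <- path$nodes
    dists <- path$distances
  } else {
    nodes <- as.integer(path)
    if (length(nodes) == 0) stopf("empty path")
    if (is.null(mesh)) stopf("mesh required when path is a plain node vector")
    dists <- path_distances(mesh, nodes)
  }
  if (length(nodes) == 0) stopf("empty path")
  if (any(nodes < 1) || any(nodes > nrow(field$values)))
    stopf("path node out of range")
  if (length(dists) > 1 && any(diff(dists) <= 0))
    stopf("path distances must be strictly increasing")
  structure(
    list(path = nodes, distances = dists,
         signals = field$values[nodes, , drop = FALSE], fs = field$fs),
    class = "mmode_field"
  )
}

#' @export
print.mmode_field <- function(x, ...) {
  cat(sprintf("mmode_field: %d nodes x %d samples, length %.2f mm\n",
              length(x$path), ncol(x$signals), max(x$distances)))
  invisible(x)
}

#' Two-dimensional spatial-temporal autocorrelation
#'
#' Full linear (zero-padded) autocorrelation of an S x T time-space field:
#' `R(lambda, tau) = sum_s sum_t x[s, t] * x[s + lambda, t + tau]`,
#' evaluated at all space lags `lambda = -(S-1)..(S-1)` and time lags
#' `tau = -(T-1)..(T-1)`.  Small fields are computed by direct summation
#' (exact for integer inputs); larger fields use an FFT-based evaluation of
#' the same sums.  Space lags are in path-index units (M-mode paths have
#' non-uniform physical spacing); the mean inter-node spacing is recorded
#' as metadata when available.
#'
#' @param x An `mmode_field` or a numeric matrix (rows = space, columns =
#'   time); at least 2 rows and 2 columns.
#' @param normalize If `TRUE`, divide by the value at the origin so
#'   `R(0, 0) = 1`.
#' @return Object of class `autocorr_surface`: `values`
#'   ((2S-1) x (2T-1) matrix), `tau` (time lags, seconds if the sampling
#'   frequency is known, otherwise samples), `lambda` (space lags, index
#'   units), `fs`, `mean_spacing_mm`, `normalized`.
#' @export
st_autocorrelation <- function(x, normalize = FALSE) {
  fs <- NA_real_
  spacing <- NA_real_
  if (inherits(x, "mmode_field")) {
    fs <- x$fs
    if (length(x$distances) > 1) spacing <- mean(diff(x$distances))
    x <- x$signals
  }
  x <- as.matrix(x)
  S <- nrow(x); T <- ncol(x)
  if (S < 2 || T < 2) stopf("need at least a 2 x 2 field")
  R <- if (S * T <= 4096) autocorr2d_direct(x) else autocorr2d_fft(x)
  origin <- R[S, T]
  if (normalize) {
    if (origin == 0) stopf("cannot normalize: zero energy at the origin")
    R <- R / origin
  }
  structure(
    list(values = R,
         tau = if (is.na(fs)) (-(T - 1)):(T - 1) else ((-(T - 1)):(T - 1)) / fs,
         lambda = (-(S - 1)):(S - 1),
         fs = fs, mean_spacing_mm = spacing, normalized = normalize),
    class = "autocorr_surface"
  )
}

# Direct evaluation: exact sums of products, one vectorised inner product
# per (space lag, time lag) pair.
autocorr2d_direct <- function(x) {
  S <- nrow(x); T <- ncol(x)
  R <- matrix(0, 2 * S - 1, 2 * T - 1)
  for (lam in 0:(S - 1)) {
    A <- x[1:(S - lam), , drop = FALSE]
    B <- x[(1 + lam):S, , drop = FALSE]
    for (tau in 0:(T - 1)) {
      v <- sum(A[, 1:(T - tau), drop = FALSE] *
                 B[, (1 + tau):T, drop = FALSE])
      R[S + lam, T + tau] <- v
      R[S - lam, T - tau] <- v
      if (tau > 0 && lam > 0) {
        v2 <- sum(A[, (1 + tau):T, drop = FALSE] *
                    B[, 1:(T - tau), drop = FALSE])
        R[S + lam, T - tau] <- v2
        R[S - lam, T + tau] <- v2
      } else if (tau > 0 && lam == 0) {
        R[S, T - tau] <- v
      } else if (lam > 0 && tau == 0) {
        R[S - lam, T] <- v
      }
    }
  }
  R
}

# FFT evaluation of the same linear correlation sums via zero padding.
autocorr2d_fft <- function(x) {
  S <- nrow(x); T <- ncol(x)
  P <- stats::nextn(2 * S - 1, c(2, 3, 5))
  Q <- stats::nextn(2 * T - 1, c(2, 3, 5))
  xp <- matrix(0, P, Q)
  xp[1:S, 1:T] <- x
  Rfull <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE)) / (P * Q)
  # circular lags 0..P-1 map to linear lags 0..S-1 and P-(S-1)..P-1 -> -(S-1)..-1
  idx_s <- c((P - (S - 2)):P, 1:S) # lags -(S-1)..(S-1), 1-based fft rows
  idx_t <- c((Q - (T - 2)):Q, 1:T)
  Rfull[idx_s, idx_t]
}

#' Marginal (purely temporal / purely spatial) autocorrelations
#'
#' Extracts the zero-space-lag slice (temporal autocorrelation) and the
#' zero-time-lag slice (spatial autocorrelation) of a spatial-temporal
#' autocorrelation surface — the two "walls" of its 3-D representation.
#'
#' @param surface An `autocorr_surface` from [st_autocorrelation()].
#' @return List with `temporal` (length 2T-1, over `tau`) and `spatial`
#'   (length 2S-1, over `lambda`), each a named numeric vector-bearing
#'   list with its lag axis.
#' @export
marginal_autocorrelations <- function(surface) {
  S <- (nrow(surface$values) + 1) / 2
  T <- (ncol(surface$values) + 1) / 2
  list(
    temporal = list(lags = surface$tau, values = surface$values[S, ]),
    spatial = list(lags = surface$lambda, values = surface$values[, T])
  )
}

#' Polarity alignment of a signal stack
#'
#' Bipolar electrogram polarity depends on the (arbitrary) orientation of
#' each electrode pair.  Each row is correlated with a reference row
#' (Pearson); rows with negative correlation are multiplied by -1, rows
#' with zero or undefined correlation are left unchanged.
#'
#' @param signals Numeric matrix, one signal per row.
#' @param reference_row Row index of the reference (default 1); must not
#'   be constant.
#' @return List with `aligned` (matrix) and `signs` (+1/-1 per row).
#' @export
align_polarity <- function(signals, reference_row = 1) {
  signals <- as.matrix(signals)
  ref <- signals[reference_row, ]
  if (stats::sd(ref) == 0) stopf("reference row is constant")
  signs <- apply(signals, 1, function(row) {
    if (stats::sd(row) == 0) return(1)
    r <- stats::cor(row, ref)
    if (is.na(r) || r >= 0) 1 else -1
  })
  list(aligned = signals * signs, signs = signs)
}

#' Detrending misadaptation statistics
#'
#' Summarises the temporal autocorrelation of a baseline-removal residual
#' by (a) the number of periodic peaks — prominence-significant local
#' maxima of the normalized autocorrelation at positive lags — and (b) the
#' tail mass — the mean absolute normalized autocorrelation beyond
#' `tail_start` seconds.  A knot separation that is too short relative to
#' the beat period leaks beat content into the baseline and shows up as
#' periodic peaks; one that is too long leaves slow trends and inflates
#' the tail mass.
#'
#' @param temporal A temporal marginal from [marginal_autocorrelations()]
#'   (list with `lags` in seconds and `values`).
#' @param prominence Minimum swing (relative to `R(0) = 1`) for a peak to
#'   count (default 0.05).
#' @param tail_start Tail region start, seconds (default 1.5).
#' @return List with `peak_count` and `tail_mass`.
#' @export
misadaptation_stats <- function(temporal, prominence = 0.05,
                                tail_start = 1.5) {
  lags <- temporal$lags
  r <- temporal$values / temporal$values[which(lags == 0)]
  pos <- r[lags > 0]
  ex <- significant_extrema(pos, prominence)
  peaks <- if (nrow(ex) == 0) 0L else sum(ex$kind == 1L)
  tail_sel <- lags > tail_start
  tail_mass <- if (any(tail_sel)) mean(abs(r[tail_sel])) else NA_real_
  list(peak_count = as.integer(peaks), tail_mass = tail_mass)
}
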