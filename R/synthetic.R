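#' Synthetic scenario configuration
#'
#' Describes a synthetic epicardial recording: an icosphere mesh, a
#' wavefront propagating from an origin node at physiological conduction
#' speed (0.3-0.5 m/s), biphasic unipolar deflections per beat, an
#' optional low-amplitude fragmented scar patch, and additive noise
#' (white Gaussian + band-limited baseline wander + optional powerline).
#'
#' Default amplitudes follow the voltage criteria used in
#' electrophysiology: healthy unipolar peak-to-peak 8 mV (above the 5 mV
#' healthy threshold) and a scar amplitude scale of 0.03, i.e. scar
#' unipolar peak-to-peak 0.24 mV, below the 0.7 mV seen over dense scar.
#' The full-scale default mirrors clinical ECGI records: 812 nodes,
#' 2048 Hz, 9.7 s, ~10 beats; [reduced_infarct_config()] (252 nodes,
#' 3 s, 3 beats) is sized for desk-scale validation.
#'
#' @param subdivisions Icosphere subdivision frequency (9 gives 812
#'   nodes; 5 gives 252).
#' @param radius_mm Sphere radius, mm.
#' @param origin Wavefront origin node index.
#' @param speed Conduction speed, m/s (valid range 0.3-0.5).
#' @param fs Sampling frequency, Hz.
#' @param duration Record length, s.
#' @param beat_times Activation onset of each beat at the origin, s.
#' @param healthy_amp Healthy unipolar peak-to-peak amplitude, mV.
#' @param template_width Deflection width parameter (Gaussian sigma), s.
#' @param rs_ratio Positive/negative lobe asymmetry of the deflection.
#' @param scar_center Scar patch centre: node index, or `NULL` for no
#'   scar, or `"inferior"` for the node nearest the -z pole.
#' @param scar_radius_mm Scar geodesic radius, mm.
#' @param scar_scale Scar amplitude scale (times `healthy_amp`); the
#'   product must stay below 0.7 mV.
#' @param scar_components Sub-deflections superposed in scar templates
#'   (fragmentation).
#' @param gaussian_sd White noise standard deviation, mV.
#' @param baseline_amp Baseline wander amplitude, mV.
#' @param baseline_max_freq Upper frequency of the wander band, Hz.
#' @param powerline_amp 50 Hz interference amplitude, mV (default 0).
#' @param seed RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(subdivisions = 9, radius_mm = 30, origin = 1L,
                            speed = 0.4, fs = 2048, duration = 9.7,
                            beat_times = seq(0.3, 9.3, by = 1),
                            healthy_amp = 8, template_width = 0.008,
                            rs_ratio = 1.5,
                            scar_center = "inferior", scar_radius_mm = 47,
                            scar_scale = 0.03, scar_components = 3,
                            gaussian_sd = 0.02, baseline_amp = 0.3,
                            baseline_max_freq = 0.4, powerline_amp = 0,
                            seed = 1L) {
  if (speed <= 0) stopf("conduction speed must be positive")
  # template spectral content extends to roughly 3 / (2 pi width) Hz
  bw <- 3 / (2 * pi * template_width)
  if (fs <= 2 * bw)
    stopf("fs = %g Hz undersamples the deflection (bandwidth ~%.0f Hz)", fs, bw)
  if (!is.null(scar_center) && healthy_amp * scar_scale >= 0.7)
    stopf("scar unipolar amplitude %.2f mV must stay below 0.7 mV",
          healthy_amp * scar_scale)
  if (any(beat_times < 0) || any(beat_times > duration))
    stopf("beat times must lie within the record")
  structure(
    list(subdivisions = subdivisions, radius_mm = radius_mm,
         origin = as.integer(origin), speed = speed, fs = fs,
         duration = duration, beat_times = beat_times,
         healthy_amp = healthy_amp, template_width = template_width,
         rs_ratio = rs_ratio, scar_center = scar_center,
         scar_radius_mm = scar_radius_mm, scar_scale = scar_scale,
         scar_components = scar_components, gaussian_sd = gaussian_sd,
         baseline_amp = baseline_amp,
         baseline_max_freq = baseline_max_freq,
         powerline_amp = powerline_amp, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Reduced infarct scenario
#'
#' Desk-scale default: 252 nodes, 3 s at 2048 Hz, 3 beats, wide inferior
#' scar patch.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
reduced_infarct_config <- function(seed = 1L, ...) {
  args <- list(subdivisions = 5, duration = 3,
               beat_times = c(0.3, 1.3, 2.3), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scenario_config, args)
}

#' Activation times of a propagating wavefront
#'
#' Activation time of each node = shortest edge-path distance from the
#' origin divided by the conduction speed.  Disconnected nodes get
#' `Inf`.
#'
#' @param mesh A [tri_mesh()].
#' @param origin Origin node index.
#' @param speed Conduction speed, m/s.
#' @return Numeric vector of activation times (s) per node.
#' @export
simulate_wavefront <- function(mesh, origin, speed) {
  if (speed <= 0) stopf("speed must be positive")
  d_mm <- path_distance_from(mesh, origin)
  d_mm / (speed * 1000)
}

#' Biphasic unipolar electrogram template
#'
#' RS-like deflection modelled as a (negated-argument) derivative of a
#' Gaussian centred at the activation time, with optional lobe asymmetry
#' and, for `components > 1`, jittered sub-deflections superposed to
#' emulate fragmentation.  The trace is rescaled so its peak-to-peak
#' amplitude equals `amplitude` exactly.
#'
#' @param t_axis Time axis, s.
#' @param t_act Activation time, s.
#' @param amplitude Peak-to-peak amplitude, mV.
#' @param width Gaussian sigma, s.
#' @param components Number of superposed sub-deflections (>= 1).
#' @param rs_ratio Positive/negative lobe ratio (1 = symmetric).
#' @param seed Seed for the sub-deflection jitter (required when
#'   `components > 1` for reproducibility; default 1).
#' @return Numeric trace over `t_axis`, mV.
#' @export
unipolar_template <- function(t_axis, t_act, amplitude, width = 0.008,
                              components = 1, rs_ratio = 1.5, seed = 1L) {
  if (width <= 0) stopf("width must be positive")
  if (components < 1) stopf("components must be >= 1")
  lobe <- function(tc, w) {
    u <- (t_axis - tc) / w
    g <- -u * exp(-u^2 / 2)
    # asymmetric lobes: scale the positive (R) lobe by rs_ratio
    ifelse(g > 0, g * rs_ratio, g)
  }
  x <- lobe(t_act, width)
  if (components > 1) {
    offs <- with_seed(seed, {
      # sharp sub-deflections on alternating sides of the main deflection
      list(dt = stats::runif(components - 1, 1.5, 3.5) * width *
             (-1)^seq_len(components - 1),
           amp = stats::runif(components - 1, 0.5, 0.8),
           w = stats::runif(components - 1, 0.25, 0.4) * width)
    })
    for (j in seq_len(components - 1)) {
      x <- x + offs$amp[j] * lobe(t_act + offs$dt[j], offs$w[j])
    }
  }
  vpp <- max(x) - min(x)
  if (vpp == 0) return(x)
  x * (amplitude / vpp)
}

#' Add measurement noise to a clean field
#'
#' Implements the additive measurement model measured = clean + N + B +
#' R: `N` is i.i.d. Gaussian per sample; `B` is a per-node random-phase
#' sum of five sinusoids drawn below `baseline_max_freq` (respiratory /
#' motion wander); `R` is an optional fixed-frequency 50 Hz interference
#' with random phase per node.  All components are returned separately
#' as ground truth.
#'
#' @param clean A [potential_field()] (role `"clean"`).
#' @param config A [scenario_config()] (noise levels and seed).
#' @return List with `measured` (a `potential_field`) and `components`
#'   (list of matrices `N`, `B`, `R`).
#' @export
add_noise <- function(clean, config) {
  nr <- nrow(clean$values); nc <- ncol(clean$values)
  t <- field_time(clean)
  with_seed(config$seed + 1L, {
    N <- if (config$gaussian_sd > 0) {
      matrix(stats::rnorm(nr * nc, sd = config$gaussian_sd), nr, nc)
    } else matrix(0, nr, nc)
    B <- matrix(0, nr, nc)
    if (config$baseline_amp > 0) {
      n_sin <- 5
      for (r in seq_len(nr)) {
        f <- stats::runif(n_sin, 0.05, config$baseline_max_freq)
        ph <- stats::runif(n_sin, 0, 2 * pi)
        a <- stats::runif(n_sin, 0.5, 1)
        b <- colSums(a * sin(outer(2 * pi * f, t) + ph))
        B[r, ] <- b / max(abs(b)) * config$baseline_amp
      }
    }
    R <- matrix(0, nr, nc)
    if (config$powerline_amp > 0) {
      for (r in seq_len(nr)) {
        R[r, ] <- config$powerline_amp *
          sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      }
    }
    list(
      measured = potential_field(clean$values + N + B + R, clean$fs,
                                 "measured"),
      components = list(N = N, B = B, R = R)
    )
  })
}

#' Generate a complete synthetic scenario
#'
#' Builds the mesh, propagates a wavefront from the origin for each
#' beat, places a biphasic deflection at each node's activation time
#' (scar-patch nodes get the scaled amplitude and multi-component
#' fragmented templates), adds noise, and returns full ground truth.
#'
#' @param config A [scenario_config()].
#' @return List with `mesh`, `measured` (a `potential_field`), `clean`
#'   (noise-free field) and `truth`: `activation` (nodes x beats matrix,
#'   s), `label` (factor scar/healthy per node), `scar_nodes` (logical),
#'   `noise` (component matrices), `config`.
#' @export
generate_scenario <- function(config) {
  mesh <- icosphere(config$subdivisions, config$radius_mm)
  M <- mesh$n_vertices
  if (config$origin < 1 || config$origin > M) stopf("origin out of range")
  onset <- simulate_wavefront(mesh, config$origin, config$speed)
  if (any(!is.finite(onset))) stopf("mesh has disconnected nodes")

  scar <- rep(FALSE, M)
  if (!is.null(config$scar_center)) {
    ctr <- if (identical(config$scar_center, "inferior")) {
      which.min(mesh$vertices[, 3])
    } else as.integer(config$scar_center)
    # geodesic (great-circle) distance on the idealised sphere
    ctr_dir <- mesh$vertices[ctr, ] / sqrt(sum(mesh$vertices[ctr, ]^2))
    dirs <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
    ang <- acos(pmin(1, pmax(-1, drop(dirs %*% ctr_dir))))
    scar <- ang * config$radius_mm <= config$scar_radius_mm
  }

  t_axis <- seq(0, config$duration - 1 / config$fs, by = 1 / config$fs)
  values <- matrix(0, M, length(t_axis))
  n_beats <- length(config$beat_times)
  activation <- matrix(NA_real_, M, n_beats)
  for (n in seq_len(M)) {
    amp <- if (scar[n]) config$healthy_amp * config$scar_scale
           else config$healthy_amp
    comp <- if (scar[n]) config$scar_components else 1
    trace <- numeric(length(t_axis))
    for (b in seq_len(n_beats)) {
      t_act <- config$beat_times[b] + onset[n]
      activation[n, b] <- t_act
      trace <- trace + unipolar_template(
        t_axis, t_act, amp, width = config$template_width,
        components = comp, rs_ratio = config$rs_ratio,
        seed = config$seed + n # per-node jitter, reproducible
      )
    }
    values[n, ] <- trace
  }
  clean <- potential_field(values, config$fs, "clean")
  noisy <- add_noise(clean, config)
  list(
    mesh = mesh,
    measured = noisy$measured,
    clean = clean,
    truth = list(
      activation = activation,
      label = factor(ifelse(scar, "scar", "healthy"),
                     levels = c("scar", "border", "healthy")),
      scar_nodes = scar,
      noise = noisy$components,
      config = config
    )
  )
}
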