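test_that("wavefront activation times follow path distance over speed", {
  ch <- chain_mesh()
  act <- simulate_wavefront(ch, 1, 0.5) # 1 mm edges at 0.5 m/s
  expect_equal(act[1], 0)
  expect_equal(act[1:4], c(0, 0.002, 0.004, 0.006)) # 2 ms per mm

  act2 <- simulate_wavefront(ch, 1, 1.0)
  expect_equal(act2[1:4], act[1:4] / 2) # doubling speed halves times

  # monotone in path distance on a sphere
  mesh <- icosphere(3, 30)
  d <- ecgidsp:::path_distance_from(mesh, 1)
  a <- simulate_wavefront(mesh, 1, 0.4)
  expect_equal(a, d / 400)
  expect_true(all(a[order(d)] == sort(a)))

  disc <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(9, 9, 9)),
                   rbind(c(1, 2, 3)))
  expect_true(is.infinite(simulate_wavefront(disc, 1, 0.4)[4]))
})

test_that("unipolar template is a calibrated biphasic deflection", {
  fs <- 2048
  t <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  x <- unipolar_template(t, 0.25, 2)
  expect_equal(max(x) - min(x), 2, tolerance = 1e-6)
  expect_gt(max(x), 0)
  expect_lt(min(x), 0)
  # deterministic given the seed
  expect_identical(unipolar_template(t, 0.25, 2, components = 3, seed = 9),
                   unipolar_template(t, 0.25, 2, components = 3, seed = 9))
})

test_that("noise components follow the additive measurement model", {
  scen <- small_scenario()
  cfg <- scen$truth$config
  nz <- scen$truth$noise
  expect_equal(scen$clean$values + nz$N + nz$B + nz$R,
               scen$measured$values)

  silent <- scenario_config(subdivisions = 2, duration = 1, fs = 512,
                            beat_times = 0.3, scar_center = NULL,
                            gaussian_sd = 0, baseline_amp = 0,
                            powerline_amp = 0, seed = 3)
  s2 <- generate_scenario(silent)
  expect_equal(s2$measured$values, s2$clean$values) # zero levels: exact

  s3 <- generate_scenario(silent)
  expect_identical(s2$measured$values, s3$measured$values) # seeded repeat
})

test_that("baseline wander is band-limited below 1 Hz", {
  cfg <- scenario_config(subdivisions = 2, duration = 10, fs = 128,
                         beat_times = 0.5, scar_center = NULL,
                         gaussian_sd = 0, baseline_amp = 0.3, seed = 6)
  scen <- generate_scenario(cfg)
  B <- scen$truth$noise$B
  for (r in c(1, 20)) {
    sp <- stats::spec.pgram(stats::ts(B[r, ], frequency = 128),
                            plot = FALSE, taper = 0)
    above <- sum(sp$spec[sp$freq > 1]) / sum(sp$spec)
    expect_lt(above, 0.01)
  }
})

test_that("scar patch obeys the unipolar amplitude bound", {
  cfg <- reduced_infarct_config(seed = 4)
  scen <- generate_scenario(cfg)
  expect_true(any(scen$truth$scar_nodes))
  scar_vpp <- apply(scen$clean$values[scen$truth$scar_nodes, , drop = FALSE],
                    1, function(x) max(x) - min(x))
  expect_true(all(scar_vpp < 0.7))
  expect_error(scenario_config(scar_scale = 0.2), "0.7 mV")
})

test_that("healthy scenario classifies nearly all nodes healthy", {
  cfg <- scenario_config(subdivisions = 3, duration = 2, fs = 512,
                         beat_times = 0.3, scar_center = NULL,
                         gaussian_sd = 0, baseline_amp = 0, seed = 8)
  scen <- generate_scenario(cfg)
  win <- segment_beats(scen$clean)[[1]]
  vpp <- amplitude_map(scen$clean, window = win)
  lab <- classify_tissue(vpp, mode = "unipolar")$label
  expect_gte(mean(lab == "healthy"), 0.95)
})

test_that("conduction speed is recoverable from ground-truth isochrones", {
  scen <- small_scenario()
  cfg <- scen$truth$config
  d <- ecgidsp:::path_distance_from(scen$mesh, cfg$origin)
  fit <- stats::lm(scen$truth$activation[, 1] - cfg$beat_times[1] ~ d)
  speed_hat <- 1 / (stats::coef(fit)[["d"]] * 1000)
  expect_lt(abs(speed_hat - cfg$speed) / cfg$speed, 0.05)
})

test_that("scenario dimensions and ground truth match the configuration", {
  scen <- small_scenario()
  cfg <- scen$truth$config
  expect_equal(scen$mesh$n_vertices, 92) # icosphere f = 3
  expect_equal(ncol(scen$measured$values), round(cfg$duration * cfg$fs))
  expect_equal(nrow(scen$measured$values), scen$mesh$n_vertices)
  expect_equal(scen$truth$activation[cfg$origin, 1], cfg$beat_times[1])
  expect_true(all(levels(scen$truth$label) ==
                    c("scar", "border", "healthy")))
})
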