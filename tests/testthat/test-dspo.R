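# Star fixture: hexagonal center with controlled neighbor amplitudes and
# distances, for enumerating DSPO choices by hand.
star_fixture <- function() {
  # center 1; neighbors 2..4 at distances 4, 6, 8 mm in a fan plus two
  # filler vertices to close triangles
  mesh <- tri_mesh(
    rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0), c(-8, 0, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4))
  )
  fs <- 100
  n <- 50
  vals <- matrix(0, 4, n)
  vals[1, ] <- 0.5 * sin(seq(0, 2 * pi, length.out = n))
  vals[2, 10] <- 0.2 # peak |v| 0.2 mV at 4 mm
  vals[3, 20] <- -1.0 # peak |v| 1.0 mV at 6 mm
  vals[4, 30] <- 3.0 # peak |v| 3.0 mV at 8 mm
  list(mesh = mesh, field = potential_field(vals, fs),
       window = time_window(0, (n - 1) / fs))
}

test_that("each DSPO picks the documented neighbor on the star fixture", {
  fx <- star_fixture()
  nb <- neighbor_geometry(fx$mesh, 1)
  pick <- function(id) select_reference(fx$field, nb, dspo_spec(id), fx$window)
  expect_equal(pick("theta_V")$node, 4L) # max peak |v| = 3.0 mV
  expect_equal(pick("theta_v")$node, 2L) # min peak |v| = 0.2 mV
  expect_equal(pick("theta_d")$node, 2L) # min distance = 4 mm
  expect_equal(pick("theta_D")$node, 4L) # max distance = 8 mm
  expect_equal(pick("theta_m")$kind, "virtual-mean")
})

test_that("ties break toward the lowest node index and theta_r is seeded", {
  mesh <- hex_fan()
  vals <- matrix(rep(sin(seq(0, 2 * pi, length.out = 40)), each = 7), 7)
  pf <- potential_field(vals, 100)
  nb <- neighbor_geometry(mesh, 1)
  win <- time_window(0, 0.39)
  expect_equal(select_reference(pf, nb, dspo_spec("theta_V"), win)$node, 2L)
  expect_equal(select_reference(pf, nb, dspo_spec("theta_v"), win)$node, 2L)

  r1 <- select_reference(pf, nb, dspo_spec("theta_r", seed = 99), win)$node
  r2 <- select_reference(pf, nb, dspo_spec("theta_r", seed = 99), win)$node
  expect_identical(r1, r2)
  expect_true(r1 %in% nb$neighbors)
})

test_that("DSPO selections match exhaustive enumeration on random fields", {
  set.seed(30)
  meshes <- list(icosphere(1, 10), icosphere(2, 10))
  fs <- 100
  ids <- c("theta_V", "theta_v", "theta_D", "theta_d", "theta_V_alpha")
  n_trials <- 200
  for (trial in seq_len(n_trials)) {
    mesh <- meshes[[1 + trial %% 2]]
    pf <- potential_field(matrix(rnorm(mesh$n_vertices * 30),
                                 mesh$n_vertices), fs)
    i <- sample.int(mesh$n_vertices, 1)
    nb <- neighbor_geometry(mesh, i)
    win <- time_window(0.1, 0.29)
    for (id in ids) {
      alpha <- if (id == "theta_V_alpha") 5L else 0L
      got <- select_reference(pf, nb, dspo_spec(id, alpha = alpha), win)$node
      expect_identical(got, oracle_reference(pf, mesh, i, id, win, alpha))
    }
  }
})

test_that("bipolar EGM subtracts the shifted reference trace", {
  mesh <- two_triangles()
  fs <- 1000
  vals <- matrix(0, 4, 300)
  vals[1, 100] <- 1 # exploratory pulse at sample 100
  vals[2, 110] <- 1 # neighbor pulse at sample 110
  pf <- potential_field(vals, fs)
  nb <- neighbor_geometry(mesh, 1)
  win <- time_window(0.06, 0.25)
  idx <- 61:251

  b <- bipolar_egm(pf, 1, nb, dspo_spec("theta_V_alpha", alpha = 40), win)
  expect_equal(b$reference, 2L)
  expect_equal(b$signal, vals[1, idx] - vals[2, idx - 40]) # array-shift oracle

  # self-cancellation: identical traces, alpha = 0
  same <- potential_field(rbind(vals[2, ], vals[2, ], vals[2, ], vals[2, ]), fs)
  b0 <- bipolar_egm(same, 1, nb, dspo_spec("theta_V"), win)
  expect_true(all(b0$signal == 0))

  # no zero padding: a shift beyond the record start errors
  expect_error(
    bipolar_egm(pf, 1, nb, dspo_spec("theta_V_alpha", alpha = 100),
                time_window(0, 0.25)),
    "leaves the record"
  )
})

test_that("theta_V_alpha with alpha = 0 reduces to theta_V", {
  scen <- small_scenario()
  nbs <- build_neighborhoods(scen$mesh)
  win <- segment_beats(scen$clean)[[1]]
  for (i in c(1, 10, 41, 80)) {
    bV <- bipolar_egm(scen$clean, i, nbs[[i]], dspo_spec("theta_V"), win)
    bVa <- bipolar_egm(scen$clean, i, nbs[[i]],
                       dspo_spec("theta_V_alpha", alpha = 0), win)
    expect_equal(bVa$signal, bV$signal)
    expect_identical(bVa$reference, bV$reference)
  }
})

test_that("ftd implements first difference and delayed self-reference", {
  fs <- 100
  ramp <- matrix(seq(0, 2.99, by = 0.01), 1) # slope 0.01 per sample
  pf <- potential_field(ramp, fs)
  win <- time_window(0.5, 2.5)
  b1 <- ftd(pf, 1, 1, win)
  expect_true(all(abs(b1$signal - 0.01) < 1e-12))
  expect_equal(b1$exploratory, b1$reference)

  zero <- potential_field(matrix(0, 1, 300), fs)
  expect_true(all(ftd(zero, 1, 40, win)$signal == 0))

  pulse <- matrix(0, 1, 300); pulse[1, 120] <- 2
  pfp <- potential_field(pulse, fs)
  idx <- 51:251
  expect_equal(ftd(pfp, 1, 40, win)$signal,
               pulse[1, idx] - pulse[1, idx - 40])
  expect_error(ftd(pfp, 1, 60, time_window(0.3, 2)), "leaves the record")
  expect_error(dspo_spec("ftd", alpha = 0), "shift")
})

test_that("bipolar_field equals a per-node loop and scales linearly", {
  scen <- small_scenario()
  nbs <- build_neighborhoods(scen$mesh)
  win <- segment_beats(scen$clean)[[1]]
  spec <- dspo_spec("theta_V_alpha", alpha = 20)
  bf <- bipolar_field(scen$clean, scen$mesh, spec, win, neighborhoods = nbs)
  expect_length(bf, scen$mesh$n_vertices)
  for (i in c(3, 30, 77)) {
    expect_equal(bf[[i]]$signal,
                 bipolar_egm(scen$clean, i, nbs[[i]], spec, win)$signal)
  }

  scaled <- potential_field(3 * scen$clean$values, scen$clean$fs)
  bf3 <- bipolar_field(scaled, scen$mesh, spec, win, neighborhoods = nbs)
  expect_equal(bf3[[30]]$signal, 3 * bf[[30]]$signal)

  flat <- potential_field(matrix(rep(scen$clean$values[1, ],
                                     each = scen$mesh$n_vertices),
                                 scen$mesh$n_vertices), scen$clean$fs)
  bflat <- bipolar_field(flat, scen$mesh, dspo_spec("theta_V"), win,
                         neighborhoods = nbs)
  expect_true(all(vapply(bflat, function(b) all(b$signal == 0), logical(1))))
})

test_that("theta_d/theta_D choices survive rigid mesh transforms", {
  set.seed(31)
  base <- icosphere(2, 10)
  # jitter the vertices so neighbor distances are all distinct (the exact
  # icosphere has tied distances, making the arg-extrema ill-defined)
  mesh <- tri_mesh(base$vertices + matrix(rnorm(3 * base$n_vertices, sd = 0.3),
                                          base$n_vertices),
                   base$triangles)
  pf <- potential_field(matrix(rnorm(mesh$n_vertices * 20),
                               mesh$n_vertices), 100)
  th <- 1.1
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  moved <- tri_mesh(mesh$vertices %*% t(Rx) +
                      matrix(c(-2, 8, 1), mesh$n_vertices, 3, byrow = TRUE),
                    mesh$triangles)
  win <- time_window(0, 0.19)
  for (i in c(2, 15, 33)) {
    for (id in c("theta_d", "theta_D")) {
      expect_identical(
        select_reference(pf, neighbor_geometry(mesh, i), dspo_spec(id), win)$node,
        select_reference(pf, neighbor_geometry(moved, i), dspo_spec(id), win)$node
      )
    }
  }
})

test_that("bipolar amplitude is largest along the propagation direction", {
  # planar wave along +x over a hexagonal fan: the neighbor pair aligned
  # with propagation sees the largest potential difference, the pair
  # perpendicular to it the smallest
  mesh <- hex_fan(radius = 5)
  fs <- 1000
  t <- seq(0, 0.3 - 1 / fs, by = 1 / fs)
  speed <- 0.4
  vals <- t(apply(mesh$vertices, 1, function(v)
    unipolar_template(t, 0.15 + v[1] / (speed * 1000), 8)))
  pf <- potential_field(vals, fs)
  win <- time_window(0, 0.299)
  vpp_vs <- vapply(2:7, function(j)
    peak_to_peak(pf$values[1, ] - pf$values[j, ]), numeric(1))
  along <- vpp_vs[c(1, 4)] # neighbors at 0 and pi (propagation axis)
  perp <- vpp_vs[c(2, 3, 5, 6)] # oblique/perpendicular neighbors
  expect_true(min(along) > max(perp))
})

test_that("delay conversions are exact arithmetic", {
  expect_equal(delay_seconds(40, 2048), 40 / 2048)
  expect_equal(delay_distance(0.3, delay_seconds(40, 2048)),
               0.3 * 40 / 2048)
  expect_equal(delay_seconds(0, 2048), 0)
})
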