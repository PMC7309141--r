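test_that("one-ring neighborhoods follow triangle-edge adjacency", {
  nb1 <- build_neighborhoods(single_triangle())
  expect_equal(nb1[[1]]$neighbors, c(2L, 3L))

  nb2 <- build_neighborhoods(two_triangles())
  expect_equal(lengths(lapply(nb2, `[[`, "neighbors")), c(3L, 3L, 2L, 2L))

  # regular icosahedron: every vertex has degree 5
  ico <- icosphere(1)
  degs <- lengths(lapply(build_neighborhoods(ico), `[[`, "neighbors"))
  expect_true(all(degs == 5L))
})

test_that("neighborhood relation is symmetric on every fixture mesh", {
  for (mesh in list(single_triangle(), two_triangles(), chain_mesh(),
                    hex_fan(), icosphere(2))) {
    nbs <- build_neighborhoods(mesh)
    for (i in seq_along(nbs)) {
      for (j in nbs[[i]]$neighbors) {
        expect_true(i %in% nbs[[j]]$neighbors)
      }
    }
  }
})

test_that("an isolated vertex gets an empty, flagged neighborhood", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                   rbind(c(1, 2, 3)))
  nb <- neighbor_geometry(mesh, 4)
  expect_length(nb$neighbors, 0)
  pf <- potential_field(matrix(rnorm(4 * 20), 4), 100)
  expect_error(
    select_reference(pf, nb, dspo_spec("theta_V"), time_window(0, 0.1)),
    "no neighbors"
  )
})

test_that("neighbor geometry gives Euclidean distances and tangent angles", {
  eq <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                 rbind(c(1, 2, 3)))
  nb <- neighbor_geometry(eq, 1)
  expect_equal(nb$distances, c(1, 1))

  # unit square split along the diagonal: corner 1 sees the far corner at sqrt(2)
  sq <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  nb1 <- neighbor_geometry(sq, 1)
  expect_equal(nb1$distances[nb1$neighbors == 3], sqrt(2))

  # hexagonal fan: consecutive angular gaps are all pi/3
  nbh <- neighbor_geometry(hex_fan(), 1)
  gaps <- diff(sort(c(nbh$angles, 2 * pi)))
  expect_equal(gaps, rep(pi / 3, 6))
  expect_true(all(nbh$angles >= 0 & nbh$angles < 2 * pi))
  expect_equal(nbh$angles[1], 0) # lowest-index neighbor defines the origin
})

test_that("degenerate geometry is rejected", {
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 2))),
               "degenerate")
  coincident <- tri_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                         rbind(c(1, 2, 3)))
  expect_error(neighbor_geometry(coincident, 1), "degenerate mesh")
  expect_error(tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 4))), "out of range")
})

test_that("select_path returns shortest edge-paths with cumulative distances", {
  ch <- chain_mesh()
  p <- select_path(ch, 1, 4)
  expect_equal(p$nodes, 1:4)
  expect_equal(p$distances, 0:3)

  same <- select_path(ch, 2, 2)
  expect_equal(same$nodes, 2)
  expect_equal(same$distances, 0)

  disconnected <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(9, 9, 0), c(10, 9, 0), c(9, 10, 0)),
                           rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(select_path(disconnected, 1, 5), "not connected")
})

test_that("select_path cost matches a brute-force Dijkstra oracle", {
  set.seed(3)
  for (mesh in list(icosphere(1, 10), icosphere(2, 10), chain_mesh())) {
    for (rep in 1:5) {
      ends <- sample.int(mesh$n_vertices, 2)
      p <- select_path(mesh, ends[1], ends[2])
      expect_equal(max(p$distances), oracle_dijkstra(mesh, ends[1], ends[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("neighbor distances are invariant under rigid transforms", {
  set.seed(4)
  mesh <- icosphere(2, 10)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- tri_mesh(mesh$vertices %*% t(Rz) +
                      matrix(c(5, -3, 2), mesh$n_vertices, 3, byrow = TRUE),
                    mesh$triangles)
  for (i in c(1, 7, 30)) {
    expect_equal(neighbor_geometry(moved, i)$distances,
                 neighbor_geometry(mesh, i)$distances, tolerance = 1e-9)
  }
})
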