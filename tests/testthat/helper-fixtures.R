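# Fixture meshes and independent brute-force oracles used across tests.

single_triangle <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# two triangles sharing edge (1,2) on 4 vertices
two_triangles <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
           rbind(c(1, 2, 3), c(1, 2, 4)))
}

# chain 1-2-3-4 triangulated with off-axis apex vertices 5, 6
chain_mesh <- function() {
  tri_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
          c(0.5, 5, 0), c(2.5, 5, 0)),
    rbind(c(1, 2, 5), c(2, 3, 5), c(2, 3, 6), c(3, 4, 6))
  )
}

# planar hexagonal fan: center vertex 1 + 6 surrounding vertices
hex_fan <- function(radius = 1) {
  ring <- t(sapply(0:5, function(k)
    radius * c(cos(k * pi / 3), sin(k * pi / 3), 0)))
  tri_mesh(rbind(c(0, 0, 0), ring),
           cbind(1, 2:7, c(3:7, 2)))
}

# small potential field with a given number of nodes
random_field <- function(n_nodes, n_samples, fs = 100) {
  potential_field(matrix(rnorm(n_nodes * n_samples), n_nodes), fs)
}

# --- independent oracles -------------------------------------------------

# Dijkstra shortest path, plain R reimplementation over the edge list
oracle_dijkstra <- function(mesh, from, to) {
  e <- ecgidsp:::mesh_edges(mesh)
  n <- mesh$n_vertices
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u]) || u == to) break
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (k in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][k, 1]
        dist[v] <- min(dist[v], dist[u] + adj[[u]][k, 2])
      }
    }
  }
  dist[to]
}

# quadruple-loop 2-D linear autocorrelation
oracle_autocorr2d <- function(x) {
  S <- nrow(x); T <- ncol(x)
  R <- matrix(0, 2 * S - 1, 2 * T - 1)
  for (lam in (-(S - 1)):(S - 1)) {
    for (tau in (-(T - 1)):(T - 1)) {
      acc <- 0
      for (s in 1:S) for (t in 1:T) {
        s2 <- s + lam; t2 <- t + tau
        if (s2 >= 1 && s2 <= S && t2 >= 1 && t2 <= T) {
          acc <- acc + x[s, t] * x[s2, t2]
        }
      }
      R[lam + S, tau + T] <- acc
    }
  }
  R
}

# exhaustive-enumeration DSPO reference choice (amplitude/distance ops)
oracle_reference <- function(field, mesh, i, id, window, alpha = 0L) {
  nb <- sort(ecgidsp:::mesh_edges(mesh)[, 1:2][
    ecgidsp:::mesh_edges(mesh)[, 1] == i |
      ecgidsp:::mesh_edges(mesh)[, 2] == i, ])
  nb <- setdiff(unique(as.integer(nb)), i)
  idx <- ecgidsp:::window_indices(window, field$fs, ncol(field$values))
  if (id %in% c("theta_V", "theta_v", "theta_V_alpha")) {
    shift <- if (id == "theta_V_alpha") alpha else 0L
    best <- NA_integer_; best_m <- NA_real_
    for (j in nb) {
      m <- max(abs(field$values[j, idx - shift]))
      if (is.na(best_m) ||
          (id == "theta_v" && m < best_m) ||
          (id != "theta_v" && m > best_m)) {
        best <- j; best_m <- m
      }
    }
    return(best)
  }
  d <- sqrt(rowSums((mesh$vertices[nb, , drop = FALSE] -
                       matrix(mesh$vertices[i, ], length(nb), 3,
                              byrow = TRUE))^2))
  if (id == "theta_D") nb[which.max(d)] else nb[which.min(d)]
}

# tiny scenario shared by slow-ish tests; memoised per test run
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scenario(
        scenario_config(subdivisions = 3, duration = 2, fs = 512,
                        beat_times = 0.3, scar_center = NULL, seed = 11)
      )
    }
    cache
  }
})
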