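#' Triangulated surface mesh
#'
#' Container for a triangulated surface: vertex coordinates in millimetres
#' and triangles as 1-based vertex-index triples.  The triangle edge set
#' defines the one-ring connectivity used to pick bipolar reference
#' electrodes among the nearest mesh neighbors of each node.
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param triangles Integer matrix, k x 3, 1-based vertex indices; every
#'   triangle must reference three distinct vertices.
#' @return An object of class `tri_mesh` with elements `vertices`,
#'   `triangles` and `n_vertices`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' m$n_vertices
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stopf("vertices must be an n x 3 matrix")
  if (any(!is.finite(vertices))) stopf("vertex coordinates must be finite")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (nrow(triangles) > 0) {
    if (ncol(triangles) != 3) stopf("triangles must be a k x 3 matrix")
    if (any(triangles < 1L) || any(triangles > nrow(vertices)))
      stopf("triangle index out of range [1, %d]", nrow(vertices))
    degen <- apply(triangles, 1, function(tr) length(unique(tr)) < 3)
    if (any(degen))
      stopf("degenerate triangle (repeated vertex) at row %d", which(degen)[1])
  }
  structure(
    list(vertices = vertices, triangles = triangles,
         n_vertices = nrow(vertices)),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles\n",
              x$n_vertices, nrow(x$triangles)))
  invisible(x)
}

# Unique undirected edge list (two-column matrix, i < j) of a tri_mesh.
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(matrix(integer(), ncol = 2))
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Area-weighted average normal of the triangles incident to vertex i.
vertex_normal <- function(mesh, i) {
  tr <- mesh$triangles
  inc <- which(tr[, 1] == i | tr[, 2] == i | tr[, 3] == i)
  if (length(inc) == 0) return(c(0, 0, 0))
  n <- c(0, 0, 0)
  for (f in inc) {
    a <- mesh$vertices[tr[f, 1], ]
    b <- mesh$vertices[tr[f, 2], ]
    cc <- mesh$vertices[tr[f, 3], ]
    n <- n + cross3(b - a, cc - a) / 2 # triangle normal scaled by area
  }
  len <- sqrt(sum(n^2))
  if (len == 0) return(c(0, 0, 0))
  n / len
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' One-ring neighborhood with geometry
#'
#' Returns the set of vertices sharing a triangle edge with node `i`,
#' together with the Euclidean distance (mm) to each neighbor and its
#' azimuthal angle in the tangent plane at `i`.  The tangent-plane normal
#' is the area-weighted average of the incident triangle normals; angles
#' are measured in `[0, 2*pi)` from the projection of the lowest-index
#' neighbor, so the origin is deterministic and mesh-intrinsic.
#'
#' @param mesh A [tri_mesh()].
#' @param i Vertex index (1-based).
#' @return An object of class `neighborhood`: `center`, `neighbors`
#'   (sorted ascending), `distances` (mm), `angles` (radians).
#' @export
neighbor_geometry <- function(mesh, i) {
  if (i < 1 || i > mesh$n_vertices) stopf("node %d out of range", i)
  e <- mesh_edges(mesh)
  nb <- sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])))
  if (length(nb) == 0) {
    return(structure(list(center = i, neighbors = integer(),
                          distances = numeric(), angles = numeric()),
                     class = "neighborhood"))
  }
  ctr <- mesh$vertices[i, ]
  offs <- mesh$vertices[nb, , drop = FALSE] -
    matrix(ctr, length(nb), 3, byrow = TRUE)
  d <- sqrt(rowSums(offs^2))
  if (any(d == 0))
    stopf("degenerate mesh: neighbor %d coincides with node %d",
          nb[which(d == 0)[1]], i)
  nrm <- vertex_normal(mesh, i)
  proj <- offs - outer(drop(offs %*% nrm), nrm) # tangent-plane projections
  ref <- proj[1, ] # lowest-index neighbor defines angle zero
  ang <- vapply(seq_len(nrow(proj)), function(j) {
    a <- atan2(sum(cross3(ref, proj[j, ]) * nrm), sum(ref * proj[j, ]))
    if (a < 0) a <- a + 2 * pi
    a
  }, numeric(1))
  structure(
    list(center = i, neighbors = nb, distances = d, angles = ang),
    class = "neighborhood"
  )
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("neighborhood of node %d: %d neighbors\n",
              x$center, length(x$neighbors)))
  invisible(x)
}

#' One-ring neighborhoods of every vertex
#'
#' @param mesh A [tri_mesh()].
#' @return List of [neighbor_geometry()] results, one per vertex.  Vertices
#'   with no incident triangle get an empty neighborhood; they are excluded
#'   from DSPO processing downstream.
#' @export
build_neighborhoods <- function(mesh) {
  lapply(seq_len(mesh$n_vertices), function(i) neighbor_geometry(mesh, i))
}

#' Shortest edge-path between two mesh nodes
#'
#' Dijkstra shortest path over the triangle edge graph with Euclidean edge
#' lengths, used to pick reproducible M-mode lines across the surface.
#'
#' @param mesh A [tri_mesh()].
#' @param from,to Vertex indices.
#' @return An object of class `mesh_path`: `nodes` (ordered, first = `from`,
#'   last = `to`), `distances` (cumulative path length, mm, starting at 0).
#' @export
select_path <- function(mesh, from, to) {
  if (from < 1 || from > mesh$n_vertices || to < 1 || to > mesh$n_vertices)
    stopf("path endpoints out of range")
  if (from == to) {
    return(structure(list(nodes = from, distances = 0), class = "mesh_path"))
  }
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, mesh$n_vertices - igraph::vcount(g)))
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from, to, weights = w, output = "vpath")
  )
  nodes <- as.integer(sp$vpath[[1]])
  if (length(nodes) < 2) stopf("nodes %d and %d are not connected", from, to)
  structure(
    list(nodes = nodes, distances = path_distances(mesh, nodes)),
    class = "mesh_path"
  )
}

# Cumulative Euclidean distances along an ordered node list.
path_distances <- function(mesh, nodes) {
  if (length(nodes) == 1) return(0)
  seg <- sqrt(rowSums((mesh$vertices[nodes[-1], , drop = FALSE] -
                         mesh$vertices[nodes[-length(nodes)], , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' @export
print.mesh_path <- function(x, ...) {
  cat(sprintf("mesh_path: %d nodes, length %.2f mm\n",
              length(x$nodes), max(x$distances)))
  invisible(x)
}

#' Pairwise graph distances from one node
#'
#' Shortest edge-path distance (mm) from `origin` to every vertex; `Inf`
#' for vertices in a different connected component.
#'
#' @param mesh A [tri_mesh()].
#' @param origin Vertex index.
#' @return Numeric vector of length `n_vertices`.
#' @export
path_distance_from <- function(mesh, origin) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, mesh$n_vertices - igraph::vcount(g)))
  drop(igraph::distances(g, v = origin, weights = w))
}
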