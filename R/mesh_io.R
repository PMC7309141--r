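# Mesh file formats: OFF, ASCII PLY (triangles only) and a small JSON
# dialect {"vertices": [[x,y,z],...], "triangles": [[a,b,c],...]}.
# On disk all three use 0-based vertex indices (the native convention of
# OFF/PLY); the R API is 1-based and the readers/writers convert.

#' Read a triangle mesh
#'
#' @param path File path; format inferred from the extension (`.off`,
#'   `.ply`, `.json`) unless given explicitly.
#' @param format One of `"off"`, `"ply"`, `"json"` or `"auto"`.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", json = "json",
                     stopf("cannot infer mesh format from extension '%s'", ext))
  }
  switch(format,
    off = read_mesh_off(path),
    ply = read_mesh_ply(path),
    json = {
      j <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (is.null(j$vertices) || is.null(j$triangles))
        stopf("JSON mesh needs 'vertices' and 'triangles'")
      tri_mesh(j$vertices, matrix(as.integer(j$triangles), ncol = 3) + 1L)
    }
  )
}

read_mesh_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0 || ln[1] != "OFF") stopf("not an OFF file: %s", path)
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(s, "\\s+")[[1]][1:3])))
  faces <- lapply(ln[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(s, "\\s+")[[1]]))
  bad <- which(vapply(faces, function(f) f[1] != 3L, logical(1)))
  if (length(bad) > 0)
    stopf("OFF face %d is not a triangle", bad[1])
  tri <- do.call(rbind, lapply(faces, function(f) f[2:4])) + 1L
  tri_mesh(vtx, tri)
}

read_mesh_ply <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0 || trimws(ln[1]) != "ply") stopf("not a PLY file: %s", path)
  hdr_end <- which(trimws(ln) == "end_header")[1]
  if (is.na(hdr_end)) stopf("PLY header not terminated")
  hdr <- ln[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stopf("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  body <- trimws(ln[(hdr_end + 1):length(ln)])
  body <- body[nzchar(body)]
  vtx <- do.call(rbind, lapply(body[1:nv], function(s)
    as.numeric(strsplit(s, "\\s+")[[1]][1:3])))
  faces <- lapply(body[(nv + 1):(nv + nf)], function(s)
    as.integer(strsplit(s, "\\s+")[[1]]))
  bad <- which(vapply(faces, function(f) f[1] != 3L, logical(1)))
  if (length(bad) > 0) stopf("PLY face %d is not a triangle", bad[1])
  tri <- do.call(rbind, lapply(faces, function(f) f[2:4])) + 1L
  tri_mesh(vtx, tri)
}

#' Write a mesh as ASCII OFF
#'
#' @param mesh A [tri_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", mesh$n_vertices, nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(format(v, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  if (nrow(mesh$triangles) > 0)
    writeLines(apply(mesh$triangles - 1L, 1, function(f)
      paste(c(3L, f), collapse = " ")), con)
  invisible(path)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: near-uniform vertex
#' spacing with `10 * f^2 + 2` vertices at subdivision frequency `f`
#' (12, 42, 162, 252 at f = 5, 812 at f = 9, ...).  Deterministic; used by
#' the synthetic scenario generator as an idealised closed epicardial
#' surface.
#'
#' @param subdivisions Subdivision frequency (each icosahedron edge is
#'   split into `subdivisions` segments); 1 gives the raw icosahedron.
#' @param radius Sphere radius in mm.
#' @return A [tri_mesh()].
#' @export
icosphere <- function(subdivisions = 1, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # each face is split into subdivisions^2 subtriangles on a barycentric
  # grid; shared grid points are identified combinatorially (corner /
  # edge / interior keys), never by coordinate hashing
  if (subdivisions > 1) {
    n <- subdivisions
    verts <- new.env(parent = emptyenv())
    coords <- list()
    idx_of <- function(key, p) {
      i <- verts[[key]]
      if (is.null(i)) {
        coords[[length(coords) + 1]] <<- p / sqrt(sum(p^2))
        i <- length(coords)
        verts[[key]] <- i
      }
      i
    }
    grid_point <- function(face_id, a, b, c, i, j) {
      w <- c(n - i - j, i, j) # barycentric weights on corners (a, b, c)
      corners <- c(a, b, c)
      nz <- which(w > 0)
      if (length(nz) == 1) {
        return(idx_of(sprintf("v%d", corners[nz]), v[corners[nz], ]))
      }
      if (length(nz) == 2) {
        p1 <- corners[nz[1]]; p2 <- corners[nz[2]]; k <- w[nz[2]]
        if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp; k <- n - k }
        # canonical coordinate from the ordered endpoints
        p <- v[p1, ] * ((n - k) / n) + v[p2, ] * (k / n)
        return(idx_of(sprintf("e%d_%d_%d", p1, p2, k), p))
      }
      p <- v[a, ] * (w[1] / n) + v[b, ] * (w[2] / n) + v[c, ] * (w[3] / n)
      idx_of(sprintf("f%d_%d_%d", face_id, i, j), p)
    }
    faces <- list()
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      grid <- matrix(0L, n + 1, n + 1)
      for (i in 0:n) for (j in 0:(n - i)) {
        grid[i + 1, j + 1] <- grid_point(t, a, b, c, i, j)
      }
      for (i in 0:(n - 1)) for (j in 0:(n - 1 - i)) {
        faces[[length(faces) + 1]] <-
          c(grid[i + 1, j + 1], grid[i + 2, j + 1], grid[i + 1, j + 2])
        if (j < n - 1 - i) {
          faces[[length(faces) + 1]] <-
            c(grid[i + 2, j + 1], grid[i + 2, j + 2], grid[i + 1, j + 2])
        }
      }
    }
    v <- do.call(rbind, coords)
    f <- do.call(rbind, faces)
  }
  tri_mesh(v * radius, f)
}
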