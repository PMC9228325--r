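#' Triangulated surface meshes
#'
#' A `mesh3t` object stores a triangulated surface as an `n x 3` matrix of
#' vertex coordinates (metres) and an `m x 3` integer matrix of 1-based
#' vertex indices.  All morphometric operations in the package act on this
#' class.  Watertight meshes (every edge shared by exactly two faces) are a
#' precondition for signed-volume computation.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (m).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param validate check index bounds and drop unreferenced vertices.
#' @return an object of class `mesh3t`.
#' @export
mesh3t <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate && nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "mesh3t")
}

#' @export
print.mesh3t <- function(x, ...) {
  cat(sprintf("mesh3t: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [m]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# undirected edge table: one row per face edge, columns (vmin, vmax)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_key <- function(e, nv) (e[, 1] - 1) * as.double(nv) + (e[, 2] - 1)

#' Mesh integrity checks
#'
#' `is_watertight()` tests that every undirected edge is shared by exactly
#' two faces.  `is_oriented()` additionally requires the two incident faces
#' to traverse the edge in opposite directions (consistent orientation).
#'
#' @param mesh a [mesh3t()] object.
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  k <- edge_key(mesh_edges(mesh), nrow(mesh$vertices))
  all(tabulate(match(k, unique(k))) == 2L)
}

#' @rdname is_watertight
#' @export
is_oriented <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  nv <- nrow(mesh$vertices)
  # directed edges must be unique and each must have its reverse present
  de <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  kf <- (de[, 1] - 1) * as.double(nv) + (de[, 2] - 1)
  kr <- (de[, 2] - 1) * as.double(nv) + (de[, 1] - 1)
  !anyDuplicated(kf) && all(kf %in% kr)
}

# fraction of edges on a boundary (shared by exactly one face)
boundary_edge_fraction <- function(mesh) {
  k <- edge_key(mesh_edges(mesh), nrow(mesh$vertices))
  tab <- tabulate(match(k, unique(k)))
  sum(tab == 1L) / length(tab)
}

#' Mesh volume by the divergence theorem
#'
#' Sums signed tetrahedron volumes of each face against the origin.  The
#' result is origin-independent for a closed surface; a positive value
#' corresponds to outward orientation.  Non-watertight input is an error
#' (never a silent partial volume).
#'
#' @param mesh a watertight, consistently oriented [mesh3t()].
#' @param signed return the signed value instead of requiring positivity.
#' @return volume in m^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  if (!is_watertight(mesh)) stop("mesh_volume requires a watertight mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
             a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
             a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  if (signed) vol else {
    if (vol < 0) stop("mesh is inward-oriented; flip faces first")
    vol
  }
}

#' Mesh surface area
#'
#' @param mesh a [mesh3t()] object (need not be closed).
#' @return total triangle area in m^2.
#' @export
mesh_surface_area <- function(mesh) {
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Rigid and affine transforms
#'
#' @param mesh a [mesh3t()] object.
#' @param offset length-3 translation (m).
#' @param R 3x3 rotation matrix, or for `rotate_mesh_z` an angle in radians.
#' @param s scalar scale factor.
#' @return the transformed mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}

#' @rdname translate_mesh
#' @export
rotate_mesh <- function(mesh, R) {
  mesh$vertices <- mesh$vertices %*% t(R)
  mesh
}

#' @rdname translate_mesh
#' @export
rotate_mesh_z <- function(mesh, R) {
  th <- R
  rotate_mesh(mesh, matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                           3, 3, byrow = TRUE))
}

#' @rdname translate_mesh
#' @export
scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Fix global orientation to outward
#'
#' Flips all faces when the signed volume is negative, so that a
#' consistently oriented closed mesh encloses positive volume.
#'
#' @param mesh a watertight [mesh3t()] with consistent face winding.
#' @return the outward-oriented mesh.
#' @export
orient_outward <- function(mesh) {
  vol <- mesh_volume(mesh, signed = TRUE)
  if (vol < 0) flip_faces(mesh) else mesh
}

#' Connected components of a mesh
#'
#' Faces are connected when they share an edge.  Returns a list of meshes,
#' largest surface area first.
#'
#' @param mesh a [mesh3t()] object.
#' @return list of `mesh3t` objects.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (!nf) return(list())
  nv <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  k <- edge_key(e, nv)
  fid <- rep(seq_len(nf), 3L)
  ord <- order(k)
  k <- k[ord]
  fid <- fid[ord]
  # adjacent face pairs share identical edge keys
  grp <- cumsum(c(TRUE, k[-1] != k[-length(k)]))
  g <- igraph::make_graph(edges = integer(0), n = nf, directed = FALSE)
  runs <- split(fid, grp)
  pairs <- do.call(cbind, lapply(runs[lengths(runs) > 1], function(r) {
    rbind(r[1], r[-1])
  }))
  if (!is.null(pairs)) g <- igraph::add_edges(g, as.vector(pairs))
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_len(nf), comp), function(idx) {
    sub <- f[idx, , drop = FALSE]
    used <- sort(unique(as.vector(sub)))
    remap <- match(sub, used)
    mesh3t(mesh$vertices[used, , drop = FALSE],
           matrix(remap, ncol = 3), validate = FALSE)
  })
  out[order(vapply(out, mesh_surface_area, 0), decreasing = TRUE)]
}

# drop components contributing less than `min_frac` of the total area
clean_components <- function(mesh, min_frac = 0.01) {
  comps <- mesh_components(mesh)
  if (length(comps) <= 1) return(mesh)
  areas <- vapply(comps, mesh_surface_area, 0)
  keep <- comps[areas >= min_frac * sum(areas)]
  merge_meshes(keep)
}

merge_meshes <- function(meshes) {
  offs <- cumsum(c(0, vapply(meshes, function(m) nrow(m$vertices), 0)))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  F <- do.call(rbind, mapply(function(m, o) m$faces + as.integer(o),
                             meshes, offs[-length(offs)], SIMPLIFY = FALSE))
  mesh3t(V, F, validate = FALSE)
}

#' Parametric test solids
#'
#' Exact triangulations of canonical solids, used as closed-form oracles:
#' a UV sphere, a capped cylinder with elliptical cross-section and an
#' axis-aligned box.  `res` is the number of angular subdivisions.
#'
#' @param r,a,b radii (m); for `mesh_cylinder` `a`, `b` are the lateral
#'   semi-axes (circular when equal).
#' @param len cylinder length along the x axis (m).
#' @param size box edge lengths, recycled to length 3 (m).
#' @param res angular resolution (segments).
#' @param center length-3 centre position (m).
#' @return a watertight, outward-oriented [mesh3t()].
#' @export
mesh_sphere <- function(r = 1, res = 64, center = c(0, 0, 0)) {
  nth <- res             # around z
  nph <- max(3L, res %/% 2L) # pole to pole
  ph <- seq(0, pi, length.out = nph + 1)[2:nph] # exclude poles
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  g <- expand.grid(th = th, ph = ph)
  V <- cbind(r * sin(g$ph) * cos(g$th), r * sin(g$ph) * sin(g$th),
             r * cos(g$ph))
  top <- nrow(V) + 1L
  bot <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, r), c(0, 0, -r))
  idx <- function(i, p) (p - 1L) * nth + ((i - 1L) %% nth) + 1L
  F <- list()
  # pole fans (top pole connects ring p=1; ph increases away from +z)
  i <- seq_len(nth)
  F[[1]] <- cbind(top, idx(i, 1L), idx(i + 1L, 1L))
  F[[2]] <- cbind(bot, idx(i + 1L, nph - 1L), idx(i, nph - 1L))
  for (p in seq_len(nph - 2L)) {
    F[[length(F) + 1L]] <- cbind(idx(i, p), idx(i, p + 1L), idx(i + 1L, p))
    F[[length(F) + 1L]] <- cbind(idx(i + 1L, p), idx(i, p + 1L), idx(i + 1L, p + 1L))
  }
  m <- mesh3t(sweep(V, 2, center, "+"), do.call(rbind, F))
  orient_outward(m)
}

#' @rdname mesh_sphere
#' @export
mesh_cylinder <- function(r = 1, len = 2, res = 64, a = r, b = r,
                          center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = res + 1)[-(res + 1)]
  x0 <- -len / 2
  x1 <- len / 2
  ring0 <- cbind(x0, a * cos(th), b * sin(th))
  ring1 <- cbind(x1, a * cos(th), b * sin(th))
  V <- rbind(ring0, ring1, c(x0, 0, 0), c(x1, 0, 0))
  c0 <- 2L * res + 1L
  c1 <- 2L * res + 2L
  i <- seq_len(res)
  nxt <- c(seq_len(res)[-1], 1L)
  F <- rbind(
    cbind(i, nxt, res + i),              # side
    cbind(nxt, res + nxt, res + i),
    cbind(c0, nxt, i),                   # cap x0
    cbind(c1, res + i, res + nxt))       # cap x1
  m <- mesh3t(sweep(V, 2, center, "+"), F)
  orient_outward(m)
}

#' @rdname mesh_sphere
#' @export
mesh_box <- function(size = 1, center = c(0, 0, 0)) {
  s <- rep(size, length.out = 3) / 2
  g <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  V <- sweep(g %*% diag(s), 2, center, "+")
  # 12 triangles, outward
  F <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo
             c(5, 6, 7), c(6, 8, 7),   # z = hi
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  orient_outward(mesh3t(V, F))
}
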