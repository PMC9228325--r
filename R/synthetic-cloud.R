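#' Point clouds with optional oriented normals
#'
#' @param points numeric matrix, one row per point (m).
#' @param normals optional matrix of unit normals, same dimensions.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must have 3 columns")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(points)))
      stop("normals must match points in dimension")
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit vectors")
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else " with normals"))
  invisible(x)
}

#' Sample a surface point cloud from a mesh
#'
#' Emulates a scan of the surface: points are drawn uniformly by triangle
#' area, displaced along the face normal by Gaussian noise, and carry the
#' face normal.  Deterministic given the seed.
#'
#' @param mesh a [mesh3t()] object with at least one face.
#' @param n_points number of points (>= 100).
#' @param noise_sd standard deviation of the normal displacement (m).
#' @param seed integer RNG seed.
#' @return a [point_cloud()] with normals.
#' @export
sample_point_cloud <- function(mesh, n_points, noise_sd = 0, seed = 1) {
  if (!nrow(mesh$faces)) stop("cannot sample an empty mesh")
  if (n_points < 100) stop("n_points must be at least 100")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  areas <- face_areas(mesh)
  fn <- face_normals(mesh)
  with_seed(seed, {
    fi <- sample.int(length(areas), n_points, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n_points))
    r2 <- runif(n_points)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    c <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    P <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
    N <- fn[fi, , drop = FALSE]
    if (noise_sd > 0) P <- P + rnorm(n_points, sd = noise_sd) * N
    point_cloud(P, N)
  })
}

#' Inject a "skirt" artifact between the legs
#'
#' Reproduces the reconstruction failure seen on sparsely sampled legs: a
#' membrane webbing each fore/hind leg pair, rising from the ground to a
#' fraction `severity` of the leg zone.  The mesh is resampled through a
#' signed-distance field unioned with the membrane solids, so the output
#' is again watertight; its volume and surface area strictly exceed the
#' input's for positive severity.
#'
#' @param mesh a watertight [mesh3t()] with a detectable leg region.
#' @param severity fraction in \[0, 1\]; 0 returns the input unchanged.
#' @param seed integer seed (adds a small reproducible jitter to the
#'   membrane extent).
#' @return a watertight [mesh3t()].
#' @export
inject_skirt <- function(mesh, severity, seed = 1) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (severity == 0) return(mesh)
  if (!is_watertight(mesh)) stop("inject_skirt requires a watertight mesh")
  frame <- fit_body_frame(mesh)
  wh <- withers_height(mesh, frame)
  belly <- belly_height(mesh, frame)
  zone <- min(belly, frame$stations$leg_zone_frac * wh)
  z0 <- frame$ground
  legs <- height_slice(mesh, frame, z0 + 0.5 * zone)
  if (length(legs) < 2) stop("no leg region detected (need >= 2 leg sections)")

  # cluster leg sections into fore and hind pairs by axial position
  ax <- vapply(legs, function(p) mean(p[, 1]), 0)
  lat <- vapply(legs, function(p) mean(p[, 2]), 0)
  rad <- vapply(legs, function(p) sqrt(attr(p, "area") / pi), 0)
  pair_id <- if (length(legs) > 2 && diff(range(ax)) > 4 * max(rad))
    (ax > mean(range(ax))) + 1L else rep(1L, length(legs))

  jit <- with_seed(seed, 1 + 0.01 * runif(1))
  R3 <- rbind(frame$axis, frame$lat, frame$up)
  boxes <- NULL
  for (pid in unique(pair_id)) {
    sel <- pair_id == pid
    r <- mean(rad[sel])
    # slice coordinates are already absolute frame coordinates (the slice
    # plane origin has no axial or lateral component)
    xc <- mean(ax[sel])
    ylo <- min(lat[sel])
    yhi <- max(lat[sel])
    ztop <- z0 + 0.01 * zone + severity * 0.98 * zone * jit
    boxes <- rbind(boxes, c(2, xc - 1.2 * r, xc + 1.2 * r, ylo, yhi,
                            z0 + 0.004 * zone, min(ztop, z0 + zone),
                            0, 0, 0, 0, 0, 0))
  }
  # resample in frame coordinates (membranes are axis-aligned boxes there)
  Vr <- mesh$vertices %*% t(R3)
  el <- sqrt(rowSums((Vr[mesh$faces[, 1], , drop = FALSE] -
                      Vr[mesh$faces[, 2], , drop = FALSE])^2))
  h <- 1.25 * median(el)
  raw <- cpp_mesh_remesh(Vr, mesh$faces - 1L, boxes, h)
  out <- mesh3t(raw$vertices %*% R3, raw$faces + 1L, validate = FALSE)
  if (!is_watertight(out)) stop("skirt resampling produced an open surface")
  orient_outward(out)
}
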