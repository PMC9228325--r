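#' Fit a body frame to a standing animal mesh
#'
#' The body axis is the first principal direction of the vertices projected
#' onto the ground plane; up is +z (animals stand on the device floor).
#' The muzzle end is identified as the end with the smaller lateral spread
#' (head and neck are narrower than the hindquarters), and stations are
#' expressed as fractions of body length from the front.
#'
#' @param mesh a [mesh3t()] object.
#' @param stations landmark table from [anatomy_stations()].
#' @return an object of class `body_frame`: origin (3d, on the ground under
#'   the muzzle), `axis` and `up` unit vectors, `lat` = up x axis,
#'   `body_length` (m), `ground` (z of the ground plane) and the stations.
#' @export
fit_body_frame <- function(mesh, stations = anatomy_stations()) {
  V <- mesh$vertices
  if (nrow(V) < 10) stop("too few vertices to fit a body frame")
  xy <- V[, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  a2 <- eg$vectors[, 1]
  p1 <- as.vector(xy %*% a2)
  p2 <- as.vector(xy %*% eg$vectors[, 2])
  ext <- c(diff(range(p1)), diff(range(p2)))
  if (ext[1] / max(ext[2], 1e-12) < 1.1)
    stop("body axis is ambiguous: vertex distribution is near-isotropic")

  # front = narrower end (head/neck), using lateral spread of the end slabs
  q <- quantile(p1, c(0.15, 0.85))
  spread_lo <- mean(abs(p2[p1 <= q[1]] - mean(p2[p1 <= q[1]])))
  spread_hi <- mean(abs(p2[p1 >= q[2]] - mean(p2[p1 >= q[2]])))
  if (spread_lo > spread_hi) {
    a2 <- -a2
    p1 <- -p1
  }
  axis <- c(a2, 0)
  up <- c(0, 0, 1)
  lat <- c(up[2] * axis[3] - up[3] * axis[2],
           up[3] * axis[1] - up[1] * axis[3],
           up[1] * axis[2] - up[2] * axis[1])
  ground <- min(V[, 3])
  front <- min(p1)
  origin <- c(ctr + (front - sum(ctr * a2)) * a2, ground)
  structure(list(origin = origin, axis = axis, up = up, lat = lat,
                 body_length = diff(range(p1)), ground = ground,
                 stations = stations),
            class = "body_frame")
}

#' @export
print.body_frame <- function(x, ...) {
  cat(sprintf("body_frame: length %.3f m, axis (%.3f, %.3f, %.3f)\n",
              x$body_length, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# axial coordinate of vertices (m from the front)
axial_coord <- function(mesh, frame) {
  as.vector(sweep(mesh$vertices, 2, frame$origin) %*% frame$axis)
}

# intersection of the mesh with an arbitrary plane; polygons in (e1, e2)
# plane coordinates.  Chains crossing edges into loops; open chains (from
# non-watertight meshes) are closed implicitly.
section_polygons <- function(mesh, p0, normal, e1, e2, min_area = 1e-6) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.vector(sweep(V, 2, p0) %*% normal)
  d[d == 0] <- 1e-12
  sgn <- d > 0
  cross_face <- (sgn[F[, 1]] + sgn[F[, 2]] + sgn[F[, 3]]) %in% c(1L, 2L)
  if (!any(cross_face)) return(list())
  Fc <- F[cross_face, , drop = FALSE]
  nv <- nrow(V)
  # per face, its two crossing edges
  ek <- function(i, j) (pmin(i, j) - 1) * as.double(nv) + (pmax(i, j) - 1)
  e12 <- sgn[Fc[, 1]] != sgn[Fc[, 2]]
  e23 <- sgn[Fc[, 2]] != sgn[Fc[, 3]]
  e31 <- sgn[Fc[, 3]] != sgn[Fc[, 1]]
  keys <- cbind(ifelse(e12, ek(Fc[, 1], Fc[, 2]), ifelse(e23, ek(Fc[, 2], Fc[, 3]), NA)),
                ifelse(e31, ek(Fc[, 3], Fc[, 1]), ifelse(e23, ek(Fc[, 2], Fc[, 3]), NA)))
  ukeys <- unique(as.vector(keys))
  kid <- matrix(match(as.vector(keys), ukeys), ncol = 2)
  # intersection point per unique edge; key = (min-1)*nv + (max-1)
  ii <- (ukeys %/% nv) + 1
  jj <- (ukeys %% nv) + 1
  tt <- d[ii] / (d[ii] - d[jj])
  P <- V[ii, , drop = FALSE] + tt * (V[jj, , drop = FALSE] - V[ii, , drop = FALSE])
  py <- as.vector(sweep(P, 2, p0) %*% e1)
  pz <- as.vector(sweep(P, 2, p0) %*% e2)

  # walk loops: nodes are unique edges, links are faces
  nfc <- nrow(kid)
  adj <- vector("list", length(ukeys))
  for (f in seq_len(nfc)) {
    adj[[kid[f, 1]]] <- c(adj[[kid[f, 1]]], f)
    adj[[kid[f, 2]]] <- c(adj[[kid[f, 2]]], f)
  }
  used <- logical(nfc)
  walk <- function(f, node) {
    loop <- integer(0)
    repeat {
      used[f] <<- TRUE
      loop <- c(loop, node)
      nxt <- kid[f, 1] + kid[f, 2] - node # the other edge of this face
      cand <- setdiff(adj[[nxt]], f)
      node <- nxt
      if (!length(cand) || used[cand[1]]) {
        loop <- c(loop, nxt)
        break
      }
      f <- cand[1]
    }
    loop
  }
  polys <- list()
  for (f0 in seq_len(nfc)) {
    if (used[f0]) next
    loop <- walk(f0, kid[f0, 1])
    if (loop[length(loop)] == loop[1]) {
      loop <- loop[-length(loop)] # closed: drop repeated endpoint
    } else {
      back <- walk(f0, kid[f0, 2]) # open chain: extend the other way
      loop <- c(rev(back[-(1:2)]), loop) # back repeats this face's two edges
    }
    poly <- cbind(py[loop], pz[loop])
    n <- nrow(poly)
    if (n < 3) next
    area <- abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
                    poly[c(2:n, 1), 1] * poly[, 2])) / 2
    if (area < min_area) next
    attr(poly, "area") <- area
    attr(poly, "perimeter") <- sum(sqrt(rowSums((poly[c(2:n, 1), ] - poly)^2)))
    polys[[length(polys) + 1]] <- poly
  }
  polys
}

#' Planar cross-section of a body mesh
#'
#' Intersects the mesh with the plane normal to the body axis at a
#' fractional station, returning closed polygons in plane coordinates
#' (first column lateral, second vertical).  Degenerate polygons with area
#' below 1e-6 m^2 are discarded.
#'
#' @param mesh a [mesh3t()] object.
#' @param frame a [fit_body_frame()] result.
#' @param station fractional position along the body axis in \[0, 1\].
#' @return list of polygon matrices with `area` and `perimeter` attributes.
#' @export
cross_section <- function(mesh, frame, station) {
  if (station < 0 || station > 1) stop("station must lie in [0, 1]")
  p0 <- frame$origin + station * frame$body_length * frame$axis
  polys <- section_polygons(mesh, p0, frame$axis, frame$lat, frame$up)
  if (!length(polys)) stop(sprintf("empty cross-section at station %.3f", station))
  polys
}

# horizontal slice at absolute height z (polygons in (axial, lateral))
height_slice <- function(mesh, frame, z) {
  p0 <- c(0, 0, z)
  section_polygons(mesh, p0, frame$up, frame$axis, frame$lat,
                   min_area = 1e-5)
}

#' Heart girth: taut-tape circumference at the heart-girth plane
#'
#' The girth is the perimeter of the convex hull of the cross-section at
#' the heart-girth station, emulating how a tape is pulled taut over
#' concavities rather than following the surface.
#'
#' @inheritParams cross_section
#' @return girth in m.
#' @export
girth <- function(mesh, frame) {
  polys <- cross_section(mesh, frame, frame$stations$heart_girth)
  pts <- do.call(rbind, polys)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  sum(sqrt(rowSums((hp[c(2:nrow(hp), 1), , drop = FALSE] - hp)^2)))
}

#' Withers height
#'
#' Maximum height of the surface above the ground plane (minimum z of the
#' mesh) within an axial window around the heart-girth station.
#'
#' @inheritParams cross_section
#' @return height in m.
#' @export
withers_height <- function(mesh, frame) {
  ax <- axial_coord(mesh, frame)
  st <- frame$stations$heart_girth
  w <- frame$stations$window
  sel <- ax >= (st - w) * frame$body_length & ax <= (st + w) * frame$body_length
  if (!any(sel)) stop("no surface in the withers window")
  max(mesh$vertices[sel, 3]) - frame$ground
}

#' Chest depth
#'
#' Vertical extent of the torso polygon (the largest-area polygon) at the
#' heart-girth station.
#'
#' @inheritParams cross_section
#' @return depth in m.
#' @export
chest_depth <- function(mesh, frame) {
  polys <- cross_section(mesh, frame, frame$stations$heart_girth)
  main <- polys[[which.max(vapply(polys, attr, 0, "area"))]]
  diff(range(main[, 2]))
}

#' Hip and buttock width
#'
#' Lateral extent of the largest polygon at the hip (`landmark = "hip"`,
#' trait HW) or buttock (`landmark = "buttock"`, trait KW) station.
#'
#' @inheritParams cross_section
#' @param landmark `"hip"` or `"buttock"`.
#' @return width in m.
#' @export
body_width <- function(mesh, frame, landmark = c("hip", "buttock")) {
  landmark <- match.arg(landmark)
  polys <- cross_section(mesh, frame, frame$stations[[landmark]])
  main <- polys[[which.max(vapply(polys, attr, 0, "area"))]]
  diff(range(main[, 1]))
}

#' Measure all traits of a body mesh
#'
#' Fits the body frame and measures heart girth, withers height, chest
#' depth, hip width, buttock width, surface area and volume, plus the
#' 1-4 quality score.  Individual trait failures are recorded as `NA`
#' rather than aborting (a partially digitised animal can still yield
#' valid linear traits); volume requires a watertight mesh.
#'
#' @param mesh a [mesh3t()] object.
#' @param animal_id identifier stored in the record.
#' @param age age in days stored in the record.
#' @param stations landmark table from [anatomy_stations()].
#' @return one-row data.frame (a trait record): `animal_id`, `age`, `hg`,
#'   `wh`, `cd`, `hw`, `kw` (m), `bsa` (m^2), `volume` (m^3), `quality`.
#' @export
measure_all <- function(mesh, animal_id = "animal", age = NA_real_,
                        stations = anatomy_stations()) {
  rec <- data.frame(animal_id = animal_id, age = age, hg = NA_real_,
                    wh = NA_real_, cd = NA_real_, hw = NA_real_,
                    kw = NA_real_, bsa = NA_real_, volume = NA_real_,
                    quality = 1L, stringsAsFactors = FALSE)
  qr <- score_quality(mesh, stations)
  rec$quality <- qr$score
  frame <- tryCatch(fit_body_frame(mesh, stations), error = function(e) NULL)
  if (is.null(frame)) return(rec)
  grab <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rec$hg <- grab(girth(mesh, frame))
  rec$wh <- grab(withers_height(mesh, frame))
  rec$cd <- grab(chest_depth(mesh, frame))
  rec$hw <- grab(body_width(mesh, frame, "hip"))
  rec$kw <- grab(body_width(mesh, frame, "buttock"))
  rec$bsa <- grab(mesh_surface_area(mesh))
  if (qr$watertight) rec$volume <- grab(mesh_volume(orient_outward(mesh)))
  rec
}
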