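#' Parametric quadruped body shape
#'
#' Describes a synthetic standing heifer assembled from analytic solids:
#' a superellipsoidal torso (profile exponent `torso_taper` along the body
#' axis, superelliptical cross-section with exponent `section_exponent`),
#' four vertical capsule legs with hemispherical feet, a capsule neck and
#' an ellipsoidal head.  Coordinates: x = body axis (muzzle at x = 0,
#' increasing towards the tail), y = lateral, z = up, ground at z = 0.
#' All lengths in metres.
#'
#' Every trait of the assembled solid (volume, surface area, heart girth,
#' withers height, chest depth, hip and buttock width) has a closed-form or
#' high-resolution numerical ground truth, so meshes built from a shape can
#' be used as measurement oracles.
#'
#' Appendages may be omitted by setting their radius to zero (used by the
#' degenerate test shapes); all retained dimensions must be positive.
#'
#' @param torso_length,torso_height_radius,torso_width_radius torso
#'   semi-axis lengths: full length `torso_length` along x, vertical
#'   semi-axis (height radius) and lateral semi-axis (width radius) (m).
#' @param torso_taper profile exponent n of the torso superellipsoid; 2 is
#'   an ellipsoid, larger is boxier along the axis.
#' @param section_exponent cross-section superellipse exponent m; 2 gives
#'   elliptical sections.
#' @param torso_center_z height of the torso axis above ground (m).
#' @param leg_length exposed leg length (ground to torso underline) (m).
#' @param leg_radius,leg_stance_x,leg_stance_y leg capsule radius, axial
#'   positions of the fore and hind pairs (length-2 vector, absolute x),
#'   and lateral offset of each leg from the midline (m).
#' @param neck_length exposed gap between head and torso along x (m).
#' @param neck_radius capsule radius of the neck (m).
#' @param head_length,head_radius full length and lateral radius of the
#'   ellipsoidal head (m).
#' @return an object of class `heifer_shape`.
#' @export
heifer_shape <- function(torso_length,
                         torso_height_radius,
                         torso_width_radius,
                         torso_taper = 2.5,
                         section_exponent = 2.8,
                         torso_center_z = torso_height_radius + leg_length,
                         leg_length = 0.45,
                         leg_radius = 0.08,
                         leg_stance_x = NULL,
                         leg_stance_y = 1.5 * leg_radius,
                         neck_length = 0.05,
                         neck_radius = 0.12,
                         head_length = 0.3,
                         head_radius = 0.1) {
  s <- list(torso_length = torso_length,
            torso_height_radius = torso_height_radius,
            torso_width_radius = torso_width_radius,
            torso_taper = torso_taper,
            section_exponent = section_exponent,
            torso_center_z = torso_center_z,
            leg_length = leg_length,
            leg_radius = leg_radius,
            leg_stance_x = leg_stance_x,
            leg_stance_y = leg_stance_y,
            neck_length = neck_length,
            neck_radius = neck_radius,
            head_length = head_length,
            head_radius = head_radius)
  class(s) <- "heifer_shape"
  validate_shape(s)
}

validate_shape <- function(s) {
  core <- c("torso_length", "torso_height_radius", "torso_width_radius",
            "torso_taper", "section_exponent")
  for (f in core)
    if (!is.numeric(s[[f]]) || s[[f]] <= 0)
      stop(sprintf("shape field '%s' must be positive", f))
  if (s$torso_taper <= 1) stop("torso_taper must exceed 1")
  has_legs <- s$leg_radius > 0
  has_head <- s$head_radius > 0
  has_neck <- s$neck_radius > 0
  if (has_legs) {
    if (s$leg_length < 0) stop("leg_length must be non-negative")
    if (s$leg_radius >= s$torso_width_radius)
      stop("leg_radius must be smaller than torso_width_radius")
    if (is.null(s$leg_stance_x))
      s$leg_stance_x <- body_front_length(s) +
        c(0.24, 0.81) * s$torso_length
    if (length(s$leg_stance_x) != 2L)
      stop("leg_stance_x must give fore and hind positions")
    x0 <- body_front_length(s)
    if (any(s$leg_stance_x < x0) ||
        any(s$leg_stance_x > x0 + s$torso_length))
      stop("leg stance positions must lie under the torso")
  }
  if (has_head && !has_neck)
    stop("a head requires a neck to attach it to the torso")
  s$has_legs <- has_legs
  s$has_head <- has_head
  s$has_neck <- has_neck
  s
}

#' @export
print.heifer_shape <- function(x, ...) {
  cat("heifer_shape\n")
  cat(sprintf("  torso %.3f x %.3f x %.3f m (taper %.2f, section %.2f), axis z %.3f\n",
              x$torso_length, 2 * x$torso_width_radius,
              2 * x$torso_height_radius, x$torso_taper, x$section_exponent,
              x$torso_center_z))
  if (x$has_legs)
    cat(sprintf("  legs r %.3f at x %.2f/%.2f, y +/-%.2f\n", x$leg_radius,
                x$leg_stance_x[1], x$leg_stance_x[2], x$leg_stance_y))
  if (x$has_head)
    cat(sprintf("  head %.2f x %.2f, neck r %.3f\n", x$head_length,
                2 * x$head_radius, x$neck_radius))
  invisible(x)
}

# length of the head + neck section in front of the torso
body_front_length <- function(s) {
  if (s$head_radius > 0) s$head_length + s$neck_length else 0
}

# total body length (muzzle to tail)
body_length <- function(s) body_front_length(s) + s$torso_length

head_center_z <- function(s) s$torso_center_z + 0.55 * s$torso_height_radius

# primitive table rows for the C++ kernels
shape_primitives <- function(s) {
  a <- s$torso_length / 2
  xc <- body_front_length(s) + a
  rows <- list(torso = c(0, xc, 0, s$torso_center_z, a, s$torso_width_radius,
                         s$torso_height_radius, s$torso_taper,
                         s$section_exponent, 0, 0, 0, 0))
  if (s$has_legs) {
    for (i in 1:2) for (sgn in c(-1, 1)) {
      nm <- sprintf("leg_%s_%s", c("fore", "hind")[i],
                    if (sgn < 0) "left" else "right")
      rows[[nm]] <- c(1, s$leg_stance_x[i], sgn * s$leg_stance_y, s$leg_radius,
                      s$leg_stance_x[i], sgn * s$leg_stance_y,
                      s$torso_center_z, s$leg_radius, 0, 0, 0, 0, 0)
    }
  }
  if (s$has_neck) {
    p0x <- if (s$has_head) 0.55 * s$head_length else body_front_length(s)
    p0z <- if (s$has_head) head_center_z(s) else s$torso_center_z
    p1x <- body_front_length(s) + 0.07 * s$torso_length
    rows$neck <- c(1, p0x, 0, p0z, p1x, 0, s$torso_center_z, s$neck_radius,
                   0, 0, 0, 0, 0)
  }
  if (s$has_head) {
    rows$head <- c(0, s$head_length / 2, 0, head_center_z(s),
                   s$head_length / 2, s$head_radius, s$head_radius, 2, 2,
                   0, 0, 0, 0)
  }
  M <- do.call(rbind, rows)
  rownames(M) <- names(rows)
  M
}

# ---------------------------------------------------------- superellipsoids

# profile scale factor s(u) = (1 - |u|^n)^(1/n), u in [-1, 1]
se_profile <- function(u, n) {
  u <- pmin(1, abs(u))
  (1 - u^n)^(1 / n)
}

# integral of s(u)^2 over [0, 1]
se_I <- function(n) beta(1 / n, 2 / n + 1) / n

# area factor of the superellipse x = p cos^(2/m), y = q sin^(2/m):
# area = 4 p q gamma(1+1/m)^2 / gamma(1+2/m)
se_section_area <- function(p, q, m) 4 * p * q * gamma(1 + 1 / m)^2 / gamma(1 + 2 / m)

# perimeter of the superellipse with semi-axes p (y) and q (z)
se_perimeter <- function(p, q, m) {
  th <- seq(0, pi / 2, length.out = 20001)
  y <- p * cos(th)^(2 / m)
  z <- q * sin(th)^(2 / m)
  4 * sum(sqrt(diff(y)^2 + diff(z)^2))
}

# ------------------------------------------------------- anatomy stations

#' Landmark stations along the body axis
#'
#' Measurement planes are placed at fixed fractions of body length from the
#' muzzle: the heart-girth plane just behind the forelegs, the hip and the
#' buttock (pin-bone) planes on the hindquarters.  The withers height is
#' taken as the maximum height over an axial window around the heart-girth
#' station.  These defaults are used everywhere a `stations` argument is
#' accepted.
#'
#' @param heart_girth,hip,buttock fractional positions in \[0, 1\].
#' @param window half-width of the withers window (fraction of body length).
#' @param leg_zone_frac leg zone upper bound as a fraction of withers height.
#' @return a named list of stations.
#' @export
anatomy_stations <- function(heart_girth = 0.30, hip = 0.78, buttock = 0.92,
                             window = 0.05, leg_zone_frac = 0.55) {
  if (!(heart_girth < hip && hip < buttock))
    stop("stations must be ordered heart_girth < hip < buttock")
  st <- list(heart_girth = heart_girth, hip = hip, buttock = buttock,
             window = window, leg_zone_frac = leg_zone_frac)
  if (any(unlist(st[1:3]) < 0) || any(unlist(st[1:3]) > 1))
    stop("stations must lie in [0, 1]")
  st
}

# ------------------------------------------------------------ ground truth

#' Closed-form ground truth of a parametric shape
#'
#' Linear traits, heart girth and withers height come from closed forms of
#' the torso superellipsoid.  Volume is the sum of closed-form primitive
#' volumes minus voxel-counted pairwise overlaps (voxel pitch proportional
#' to torso length, so truth scales exactly under similarity transforms).
#' Surface area is computed by parametric quadrature of each primitive
#' surface, discarding patches hidden inside another primitive.
#'
#' @param shape a [heifer_shape()].
#' @param stations landmark table from [anatomy_stations()].
#' @return list with elements `volume` (m^3), `bsa` (m^2), `hg`, `wh`,
#'   `cd`, `hw`, `kw` (m), and `bw` (kg, volume times the reference body
#'   density of 900 kg/m^3).
#' @export
shape_ground_truth <- function(shape, stations = anatomy_stations()) {
  s <- validate_shape(shape)
  a <- s$torso_length / 2
  xc <- body_front_length(s) + a
  BL <- body_length(s)
  n <- s$torso_taper
  m <- s$section_exponent
  b <- s$torso_width_radius
  cc <- s$torso_height_radius
  zc <- s$torso_center_z

  u_at <- function(frac) (frac * BL - xc) / a
  s_hg <- se_profile(u_at(stations$heart_girth), n)
  s_hip <- se_profile(u_at(stations$hip), n)
  s_kw <- se_profile(u_at(stations$buttock), n)
  # withers: max torso height over the axial window
  uw <- u_at(stations$heart_girth + c(-1, 1) * stations$window)
  u_best <- if (uw[1] <= 0 && uw[2] >= 0) 0 else uw[which.min(abs(uw))]
  wh <- zc + cc * se_profile(u_best, n)

  hg <- se_perimeter(b * s_hg, cc * s_hg, m)
  cd <- 2 * cc * s_hg
  hw <- 2 * b * s_hip
  kw <- 2 * b * s_kw

  # ---- volume: closed forms minus voxel overlap of appendages
  prims <- shape_primitives(s)
  v_torso <- se_section_area(b, cc, m) * a * 2 * se_I(n)
  vol <- v_torso
  hvox <- s$torso_length / 400
  app <- setdiff(rownames(prims), "torso")
  placed <- prims["torso", , drop = FALSE]
  for (nm in app) {
    row <- prims[nm, , drop = FALSE]
    v_cf <- if (row[1, 1] == 1) {
      L <- sqrt(sum((row[1, 5:7] - row[1, 2:4])^2))
      r <- row[1, 8]
      pi * r^2 * L + 4 / 3 * pi * r^3
    } else {
      4 / 3 * pi * row[1, 5] * row[1, 6] * row[1, 7]
    }
    vol <- vol + v_cf - cpp_overlap_volume(row, placed, hvox)
    placed <- rbind(placed, row)
  }

  bsa <- shape_surface_area(s, prims)

  gt <- list(volume = vol, bsa = bsa, hg = hg, wh = wh, cd = cd, hw = hw,
             kw = kw, bw = vol * 900)
  stopifnot(gt$volume > 0, gt$bsa > 0, gt$hg > 2 * gt$cd, gt$cd < gt$wh)
  gt
}

# quadrature surface area of the union (total minus hidden patches)
shape_surface_area <- function(s, prims = shape_primitives(s)) {
  total <- 0
  nms <- rownames(prims)
  for (i in seq_along(nms)) {
    others <- prims[-i, , drop = FALSE]
    patches <- prim_patches(prims[i, ], nms[i])
    for (p in patches) {
      vis <- if (nrow(others)) cpp_prim_field(others, p$centers) >= 0 else TRUE
      total <- total + sum(p$areas[vis])
    }
  }
  total
}

# parametric surface patches of one primitive: list of (centers, areas)
prim_patches <- function(row, name) {
  type <- row[1]
  if (type == 0) {
    nu <- if (name == "torso") 600L else 200L
    nv <- nu
    cx <- row[2]; cy <- row[3]; cz <- row[4]
    a <- row[5]; b <- row[6]; cc <- row[7]; n <- row[8]; m <- row[9]
    ph <- seq(0, pi, length.out = nu + 1)
    th <- seq(0, 2 * pi, length.out = nv + 1)
    tph <- sign(cos(ph)) * abs(cos(ph))^(2 / n)
    sph <- abs(sin(ph))^(2 / n)
    sy <- sign(cos(th)) * abs(cos(th))^(2 / m)
    sz <- sign(sin(th)) * abs(sin(th))^(2 / m)
    X <- cx + a * matrix(tph, nu + 1, nv + 1)
    Y <- cy + b * outer(sph, sy)
    Z <- cz + cc * outer(sph, sz)
    list(grid_patch(X, Y, Z))
  } else {
    p0 <- row[2:4]; p1 <- row[5:7]; r <- row[8]
    axis <- p1 - p0
    L <- sqrt(sum(axis^2))
    axis <- axis / L
    e1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    th <- seq(0, 2 * pi, length.out = 241)
    ring <- function(center, rad) {
      list(X = center[1] + rad * (cos(th) * e1[1] + sin(th) * e2[1]),
           Y = center[2] + rad * (cos(th) * e1[2] + sin(th) * e2[2]),
           Z = center[3] + rad * (cos(th) * e1[3] + sin(th) * e2[3]))
    }
    # cylinder
    tt <- seq(0, 1, length.out = 121)
    cylX <- outer(tt, rep(1, 241))
    base <- ring(c(0, 0, 0), r)
    X <- outer(p0[1] + tt * L * axis[1], rep(1, 241)) + outer(rep(1, 121), base$X)
    Y <- outer(p0[2] + tt * L * axis[2], rep(1, 241)) + outer(rep(1, 121), base$Y)
    Z <- outer(p0[3] + tt * L * axis[3], rep(1, 241)) + outer(rep(1, 121), base$Z)
    out <- list(grid_patch(X, Y, Z))
    # hemispherical caps
    for (endi in 1:2) {
      cen <- if (endi == 1) p0 else p1
      dir <- if (endi == 1) -1 else 1
      al <- seq(0, pi / 2, length.out = 61)
      Xc <- Yc <- Zc <- matrix(0, 61, 241)
      for (k in seq_along(al)) {
        rr <- ring(cen + dir * axis * r * sin(al[k]), r * cos(al[k]))
        Xc[k, ] <- rr$X
        Yc[k, ] <- rr$Y
        Zc[k, ] <- rr$Z
      }
      out[[endi + 1]] <- grid_patch(Xc, Yc, Zc)
    }
    out
  }
}

# triangle-pair areas and centers over a parametric grid
grid_patch <- function(X, Y, Z) {
  nu <- nrow(X) - 1
  nv <- ncol(X) - 1
  i <- seq_len(nu)
  j <- seq_len(nv)
  P00 <- cbind(as.vector(X[i, j]), as.vector(Y[i, j]), as.vector(Z[i, j]))
  P10 <- cbind(as.vector(X[i + 1, j]), as.vector(Y[i + 1, j]), as.vector(Z[i + 1, j]))
  P01 <- cbind(as.vector(X[i, j + 1]), as.vector(Y[i, j + 1]), as.vector(Z[i, j + 1]))
  P11 <- cbind(as.vector(X[i + 1, j + 1]), as.vector(Y[i + 1, j + 1]), as.vector(Z[i + 1, j + 1]))
  tri <- function(A, B, C) {
    u <- B - A
    w <- C - A
    0.5 * sqrt((u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
               (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
               (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2)
  }
  list(centers = (P00 + P10 + P01 + P11) / 4,
       areas = tri(P00, P10, P11) + tri(P00, P11, P01))
}

# ------------------------------------------------------------- mesh builder

#' Build a watertight mesh of a parametric heifer
#'
#' Extracts the union surface of the shape's primitives by marching
#' tetrahedra on a uniform grid.  `resolution` is interpreted as the number
#' of angular subdivisions of the thinnest primitive: the grid pitch is
#' `2 pi r_min / resolution`, so resolution 64 resolves the smallest limb
#' with about 64 segments around its circumference.
#'
#' @param shape a [heifer_shape()].
#' @param resolution angular resolution (>= 8).
#' @param stations landmark table used for the ground-truth traits.
#' @param ground_truth also compute [shape_ground_truth()] (skippable when
#'   only the mesh is needed).
#' @return list with `mesh` (a watertight, outward-oriented [mesh3t()]) and
#'   `truth` (the [shape_ground_truth()] list, or `NULL`).
#' @export
build_heifer_mesh <- function(shape, resolution = 128,
                              stations = anatomy_stations(),
                              ground_truth = TRUE) {
  s <- validate_shape(shape)
  if (resolution < 8) stop("resolution must be at least 8")
  prims <- shape_primitives(s)
  radii <- c(if (s$has_legs) s$leg_radius,
             if (s$has_neck) s$neck_radius,
             if (s$has_head) s$head_radius,
             min(s$torso_width_radius, s$torso_height_radius))
  h <- 2 * pi * min(radii) / resolution
  raw <- cpp_mesh_from_prims(prims, h)
  mesh <- mesh3t(raw$vertices, raw$faces + 1L, validate = FALSE)
  if (!is_watertight(mesh)) {
    # diagnose which pair failed to merge
    comps <- mesh_components(mesh)
    stop(sprintf(
      "assembled surface is not watertight (%d components); primitives fail to overlap",
      length(comps)))
  }
  mesh <- orient_outward(mesh)
  list(mesh = mesh,
       truth = if (ground_truth) shape_ground_truth(s, stations))
}

# ------------------------------------------------------------- presets

# stage means of the study population (ages in days; traits in SI units)
heifer_stage_table <- function() {
  data.frame(
    stage = c("month02", "month04", "month06", "month08", "month12",
              "month15", "month20"),
    age = c(62.0, 136.4, 171.0, 246.8, 369.2, 455.8, 604.8),
    bw = c(84.5, 173.6, 227.5, 228.0, 366.8, 393.8, 543.4),
    bsa = c(2.73, 3.84, 4.16, 4.45, 5.21, 5.48, 6.37),
    volume = c(0.12, 0.25, 0.28, 0.28, 0.43, 0.49, 0.61),
    wh = c(0.9030, 1.1188, 1.1671, 1.1591, 1.3353, 1.4051, 1.4311),
    cd = c(0.4238, 0.5431, 0.5850, 0.5889, 0.7181, 0.7431, 0.7861),
    hg = c(1.1223, 1.4066, 1.5173, 1.5185, 1.8812, 2.0181, 2.0855),
    kw = c(0.2055, 0.2834, 0.2995, 0.3431, 0.4032, 0.4246, 0.5086),
    stringsAsFactors = FALSE)
}

preset_cache <- new.env(parent = emptyenv())

#' Growth-stage shape presets
#'
#' Returns a [heifer_shape()] calibrated so that its ground-truth withers
#' height, chest depth, heart girth, buttock width and volume reproduce the
#' stage means of the study population (stages month02, month04, month06,
#' month08, month12, month15, month20).  `"sphere"` returns a degenerate
#' shape (torso only, an exact sphere of radius 0.5 m) used by the
#' closed-form oracle tests.
#'
#' @param stage preset name.
#' @return a `heifer_shape`.
#' @export
shape_preset <- function(stage = "month12") {
  if (stage == "sphere") return(sphere_shape(0.5))
  tab <- heifer_stage_table()
  row <- tab[tab$stage == stage, ]
  if (!nrow(row)) stop(sprintf("unknown shape preset '%s'", stage))
  key <- paste0("preset_", stage)
  if (!is.null(preset_cache[[key]])) return(preset_cache[[key]])
  sh <- calibrate_shape(wh = row$wh, cd = row$cd, hg = row$hg, kw = row$kw,
                        volume = row$volume)
  preset_cache[[key]] <- sh
  sh
}

#' @rdname shape_preset
#' @param r sphere radius (m).
#' @export
sphere_shape <- function(r = 0.5) {
  heifer_shape(torso_length = 2 * r, torso_height_radius = r,
               torso_width_radius = r, torso_taper = 2, section_exponent = 2,
               torso_center_z = 1.5 * r, leg_length = 0, leg_radius = 0,
               neck_radius = 0, head_radius = 0)
}

# Solve shape parameters from target traits.  Fixed design ratios: torso
# spans [0.18, 1] of body length; head 0.16 and neck gap 0.02 of body
# length; section exponent 2.8; leg/neck/head radii proportional to chest
# depth.  Free parameters solved: taper n (from buttock width), torso
# width radius (from heart girth), torso height radius (from chest depth),
# torso axis height (from withers height) and body length (from volume).
calibrate_shape <- function(wh, cd, hg, kw, volume,
                            stations = anatomy_stations(), m = 2.8) {
  torso_f0 <- 0.18
  af <- (1 - torso_f0) / 2          # torso semi-length as fraction of BL
  xcf <- torso_f0 + af              # torso centre as fraction of BL
  u_hg <- (stations$heart_girth - xcf) / af
  u_kw <- (stations$buttock - xcf) / af
  u_win <- (stations$heart_girth + stations$window - xcf) / af
  leg_r <- 0.13 * cd
  neck_r <- 0.12 * cd
  head_r <- 0.16 * cd

  solve_bc <- function(n, m) {
    s_hg <- se_profile(u_hg, n)
    cc <- cd / (2 * s_hg)
    bs <- uniroot(function(p) se_perimeter(p, cd / 2, m) - hg,
                  c(0.02 * cd, 4 * cd), tol = 1e-10)$root
    list(b = bs / s_hg, cc = cc, s_hg = s_hg)
  }
  kw_gap <- function(n, m) 2 * solve_bc(n, m)$b * se_profile(u_kw, n) - kw
  # boxy sections are preferred (they reproduce the high surface-to-volume
  # ratio of real animals); relax towards elliptical until the buttock
  # width target is bracketed in the taper exponent
  n <- NA
  for (mm in seq(m, 1.5, by = -0.1)) {
    if (kw_gap(1.12, mm) < 0 && kw_gap(10, mm) > 0) {
      n <- uniroot(function(n) kw_gap(n, mm), c(1.12, 10), tol = 1e-9)$root
      m <- mm
      break
    }
  }
  if (is.na(n)) stop("calibration failed: buttock width target unreachable")
  g <- solve_bc(n, m)
  zc <- wh - g$cc * se_profile(u_win, n)
  belly <- zc - g$cc
  if (belly <= 2.5 * leg_r)
    stop("calibration failed: torso underline too close to the ground")

  mk <- function(BL) {
    heifer_shape(torso_length = (1 - torso_f0) * BL,
                 torso_height_radius = g$cc, torso_width_radius = g$b,
                 torso_taper = n, section_exponent = m, torso_center_z = zc,
                 leg_length = belly, leg_radius = leg_r,
                 leg_stance_x = (torso_f0 + c(0.24, 0.81) * (1 - torso_f0)) * BL,
                 leg_stance_y = 1.5 * leg_r,
                 neck_length = 0.02 * BL, neck_radius = neck_r,
                 head_length = 0.16 * BL, head_radius = head_r)
  }
  # approximate volume (overlaps ignored) is monotone in body length
  vol_of <- function(BL) {
    sh <- mk(BL)
    se_section_area(g$b, g$cc, m) * sh$torso_length / 2 * 2 * se_I(n) +
      4 * (pi * leg_r^2 * (belly - leg_r) + 2 / 3 * pi * leg_r^3) +
      pi * neck_r^2 * 0.22 * BL +
      4 / 3 * pi * (0.08 * BL) * head_r^2
  }
  BL <- uniroot(function(BL) vol_of(BL) - volume,
                c(0.8 * hg / 2, 4 * hg), tol = 1e-10)$root
  mk(BL)
}
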