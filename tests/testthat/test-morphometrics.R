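test_that("body frame recovers the axis, also under rotation", {
  mesh <- month12_small()$mesh
  fr <- fit_body_frame(mesh)
  expect_lt(acos(min(1, abs(sum(fr$axis * c(1, 0, 0))))) * 180 / pi, 1)
  # muzzle end found: origin near x = 0, not at the tail
  expect_lt(abs(fr$origin[1]), 0.05 * fr$body_length)

  th <- 30 * pi / 180
  m2 <- rotate_mesh_z(mesh, th)
  fr2 <- fit_body_frame(m2)
  truth <- c(cos(th), sin(th), 0)
  expect_lt(acos(min(1, abs(sum(fr2$axis * truth)))) * 180 / pi, 1)
  expect_equal(fr2$body_length, fr$body_length, tolerance = 1e-6)

  expect_error(fit_body_frame(mesh_sphere(1, 48)), "ambiguous")
})

test_that("cross-sections reproduce closed-form slices", {
  cyl <- mesh_cylinder(r = 0.4, len = 2, res = 192)
  fr <- fit_body_frame(cyl)
  polys <- cross_section(cyl, fr, 0.5)
  expect_length(polys, 1)
  expect_lt(abs(attr(polys[[1]], "area") - pi * 0.4^2) / (pi * 0.4^2), 0.01)
  # a plane through the leg region of the default shape cuts >= 2 sections
  mesh <- month12_small()$mesh
  frb <- fit_body_frame(mesh)
  legs <- heifer3d:::height_slice(mesh, frb, frb$ground +
                                    0.5 * heifer3d:::belly_height(mesh, frb))
  expect_gte(length(legs), 2)
  expect_error(cross_section(mesh, frb, 2), "station")
})

test_that("girth matches tape-measure closed forms", {
  cyl <- mesh_cylinder(r = 0.4, len = 2, res = 192)
  fr <- fit_body_frame(cyl)
  expect_lt(abs(girth(cyl, fr) - 2 * pi * 0.4) / (2 * pi * 0.4), 0.01)

  ell <- mesh_cylinder(len = 2, res = 256, a = 0.35, b = 0.25)
  fre <- fit_body_frame(ell)
  expect_lt(abs(girth(ell, fre) - ramanujan_perimeter(0.35, 0.25)) /
              ramanujan_perimeter(0.35, 0.25), 0.01)

  # taut tape: hull perimeter never exceeds the surface perimeter
  mesh <- month12_small()$mesh
  frb <- fit_body_frame(mesh)
  polys <- cross_section(mesh, frb, frb$stations$heart_girth)
  expect_lte(girth(mesh, frb),
             sum(vapply(polys, attr, 0, "perimeter")) + 1e-9)
})

test_that("heights and widths follow their definitions", {
  ell <- mesh_cylinder(len = 2, res = 192, a = 0.2, b = 0.29,
                       center = c(0, 0, 1))
  fr <- fit_body_frame(ell)
  expect_lt(abs(chest_depth(ell, fr) - 0.58) / 0.58, 0.01)
  expect_lt(abs(body_width(ell, fr, "hip") - 0.4) / 0.4, 0.01)
  # withers height is ground-referenced: raising the mesh changes nothing
  mesh <- month12_small()$mesh
  frb <- fit_body_frame(mesh)
  wh <- withers_height(mesh, frb)
  up <- translate_mesh(mesh, c(0, 0, 0.5))
  expect_equal(withers_height(up, fit_body_frame(up)), wh, tolerance = 1e-9)
  expect_lt(chest_depth(mesh, frb), wh)
  # left-right mirror symmetry of widths
  mir <- mesh3t(mesh$vertices %*% diag(c(1, -1, 1)),
                mesh$faces[, c(1, 3, 2)], validate = FALSE)
  expect_equal(body_width(mir, fit_body_frame(mir), "hip"),
               body_width(mesh, frb, "hip"), tolerance = 1e-6)
})

test_that("measure_all round-trips the generator ground truth", {
  bm <- month12_build(64)
  rec <- measure_all(bm$mesh, "m12", 369)
  for (tr in c("hg", "wh", "cd", "hw", "kw", "bsa", "volume"))
    expect_lt(abs(rec[[tr]] - bm$truth[[tr]]) / bm$truth[[tr]], 0.03,
              label = sprintf("%s relative error", tr))
  expect_identical(rec$quality, 4L)
})

test_that("measurements are stable under mesh refinement", {
  sh <- shape_preset("month12")
  m128 <- month12_build(128)
  m256 <- build_heifer_mesh(sh, 256, ground_truth = FALSE)
  grab <- function(bm) {
    fr <- fit_body_frame(bm$mesh)
    c(volume = mesh_volume(bm$mesh), bsa = mesh_surface_area(bm$mesh),
      hg = girth(bm$mesh, fr), wh = withers_height(bm$mesh, fr),
      cd = chest_depth(bm$mesh, fr))
  }
  a <- grab(m128)
  b <- grab(m256)
  expect_true(all(abs(b / a - 1) < 0.01))
})

test_that("traits are invariant under rigid transforms after frame refit", {
  bm <- month12_small()
  m2 <- translate_mesh(rotate_mesh_z(bm$mesh, 0.6), c(1.5, -2, 0.3))
  r1 <- measure_all(bm$mesh)
  r2 <- measure_all(m2)
  for (tr in c("hg", "wh", "cd", "hw", "kw", "bsa", "volume"))
    expect_lt(abs(r2[[tr]] - r1[[tr]]) / r1[[tr]], 0.005, label = tr)
})

test_that("measure_all fails soft on defective meshes", {
  mesh <- month12_small()$mesh
  cropped <- drop_faces_below(mesh, 0.25) # legs partially removed, open
  rec <- measure_all(cropped)
  expect_false(is.na(rec$wh))   # linear trait still measurable
  expect_true(is.na(rec$volume)) # not watertight -> no volume
  expect_lte(rec$quality, 2L)
})
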