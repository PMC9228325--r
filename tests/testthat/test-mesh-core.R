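test_that("volume and surface area match closed forms on canonical solids", {
  cube <- mesh_box(1)
  expect_equal(mesh_volume(cube), 1.0)
  expect_equal(mesh_surface_area(cube), 6.0)

  sp <- mesh_sphere(1, res = 96)
  expect_lt(abs(mesh_volume(sp) - 4 / 3 * pi) / (4 / 3 * pi), 0.005)
  expect_lt(abs(mesh_surface_area(sp) - 4 * pi) / (4 * pi), 0.005)

  cyl <- mesh_cylinder(r = 0.4, len = 1.5, res = 128)
  v <- pi * 0.4^2 * 1.5
  a <- 2 * pi * 0.4 * 1.5 + 2 * pi * 0.4^2
  expect_lt(abs(mesh_volume(cyl) - v) / v, 0.005)
  expect_lt(abs(mesh_surface_area(cyl) - a) / a, 0.005)
})

test_that("volume is origin-independent and area is additive", {
  sp <- mesh_sphere(0.7, res = 48)
  moved <- translate_mesh(sp, c(5, -3, 11))
  expect_equal(mesh_volume(moved), mesh_volume(sp), tolerance = 1e-10)

  two <- heifer3d:::merge_meshes(list(sp, translate_mesh(sp, c(3, 0, 0))))
  expect_equal(mesh_surface_area(two), 2 * mesh_surface_area(sp))
  expect_equal(length(mesh_components(two)), 2L)
})

test_that("watertightness and orientation are diagnosed", {
  cube <- mesh_box(1)
  expect_true(is_watertight(cube))
  expect_true(is_oriented(cube))

  open_cube <- mesh3t(cube$vertices, cube$faces[-1, ], validate = FALSE)
  expect_false(is_watertight(open_cube))
  expect_error(mesh_volume(open_cube), "watertight")

  flipped <- heifer3d:::flip_faces(cube)
  expect_error(mesh_volume(flipped), "inward")
  expect_equal(mesh_volume(orient_outward(flipped)), 1.0)
})

test_that("rigid transforms leave volume and area invariant", {
  bm <- month12_small()
  R <- rotation_xyz(0.4, -0.8, 1.2)
  m2 <- translate_mesh(rotate_mesh(bm$mesh, R), c(2, -1, 3))
  expect_equal(mesh_volume(m2), mesh_volume(bm$mesh), tolerance = 1e-9)
  expect_equal(mesh_surface_area(m2), mesh_surface_area(bm$mesh),
               tolerance = 1e-9)
})
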