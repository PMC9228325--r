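test_that("normal estimation matches analytic normals on a sphere", {
  sp <- mesh_sphere(1, res = 96)
  pc <- sample_point_cloud(sp, 10000, 0, seed = 4)
  est <- estimate_normals(point_cloud(pc$points), 16)
  radial <- est$points / sqrt(rowSums(est$points^2))
  ang <- acos(pmin(1, abs(rowSums(est$normals * radial)))) * 180 / pi
  expect_gt(mean(ang < 5), 0.99)
  # orientation is globally consistent and points outward
  expect_gt(mean(rowSums(est$normals * radial) > 0), 0.99)
})

test_that("planar clouds give parallel normals; sentinel passes through", {
  g <- as.matrix(expand.grid(x = seq(0, 1, by = 0.02),
                             y = seq(0, 1, by = 0.02)))
  pl <- point_cloud(cbind(g, 0.5 + 0.3 * g[, 1])) # tilted plane
  est <- estimate_normals(pl, 12)
  ref <- est$normals[1, ]
  ang <- acos(pmin(1, abs(est$normals %*% ref))) * 180 / pi
  expect_lt(max(ang), 1)

  withn <- point_cloud(g3 <- cbind(g, 0), cbind(0 * g, 1))
  expect_identical(estimate_normals(withn, 0), withn)
  expect_error(estimate_normals(point_cloud(cbind(g, 0)), 0), "no normals")
  expect_error(estimate_normals(point_cloud(matrix(0, 3, 3)), 16), "fewer")
})

test_that("implicit reconstruction recovers closed-form and source volumes", {
  sp <- mesh_sphere(0.5, res = 128)
  pc <- sample_point_cloud(sp, 50000, 0, seed = 2)
  rec <- reconstruct_surface(pc)
  v <- 4 / 3 * pi * 0.5^3
  expect_true(is_watertight(rec))
  expect_gt(mesh_volume(rec), 0)
  expect_lt(abs(mesh_volume(rec) - v) / v, 0.02)
  expect_error(reconstruct_surface(point_cloud(pc$points)), "normals")
})

test_that("two separated spheres reconstruct as two closed components", {
  m <- heifer3d:::merge_meshes(list(mesh_sphere(0.5, 64),
                                    mesh_sphere(0.45, 64, center = c(2, 0, 0))))
  pc <- sample_point_cloud(m, 40000, 0, seed = 8)
  rec <- reconstruct_surface(pc)
  comps <- mesh_components(rec)
  expect_length(comps, 2)
  expect_true(all(vapply(comps, is_watertight, TRUE)))
})

test_that("reconstruction error shrinks as point count grows", {
  mesh <- month12_small()$mesh
  err <- vapply(c(10000, 100000), function(n) {
    pc <- sample_point_cloud(mesh, n, 0.002, seed = 21)
    rec <- reconstruct_surface(estimate_normals(point_cloud(pc$points), 16))
    d <- heifer3d:::cpp_points_mesh_distance(rec$vertices, mesh$vertices,
                                             mesh$faces - 1L)
    mean(d)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("hole filling restores closed surfaces", {
  cube <- mesh_box(2)
  expect_identical(make_watertight(cube), cube)

  open_cube <- mesh3t(cube$vertices, cube$faces[-(1:2), ], validate = FALSE)
  closed <- make_watertight(open_cube)
  expect_true(is_watertight(closed))
  expect_equal(mesh_volume(closed), 8, tolerance = 1e-9)

  sp <- mesh_sphere(1, res = 48)
  keep <- heifer3d:::with_seed(9, sample(nrow(sp$faces),
                                         round(0.95 * nrow(sp$faces))))
  holey <- mesh3t(sp$vertices, sp$faces[keep, ], validate = FALSE)
  fixed <- make_watertight(holey)
  expect_true(is_watertight(fixed))
  expect_lt(abs(mesh_volume(fixed) - mesh_volume(sp)) / mesh_volume(sp), 0.01)

  # a flat fan disk: the rim is half of all edges, far beyond honest filling
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  disk <- mesh3t(rbind(c(0, 0, 0), cbind(cos(th), sin(th), 0)),
                 cbind(1L, 2:33, c(3:33, 2L)), validate = FALSE)
  expect_error(make_watertight(disk), "boundary loop")
})
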