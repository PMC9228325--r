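test_that("growth curve honours its boundary behaviour and calibration", {
  gp <- growth_params()
  expect_equal(growth_state_at_age(gp, 0)$bw, gp$birth_bw)
  expect_lt(abs(growth_state_at_age(gp, 1e6)$bw - gp$asymptote_bw), 1e-6)
  # one-year-old body weight brackets the study population mean
  bw12 <- growth_state_at_age(gp, 369)$bw
  expect_gt(bw12, 320)
  expect_lt(bw12, 414)
  # strictly increasing in age for BW and all traits
  ages <- seq(0, 700, by = 14)
  states <- lapply(ages, growth_state_at_age, params = gp)
  for (tr in c("bw", "volume", "bsa", "hg", "wh", "cd", "hw", "kw"))
    expect_true(all(diff(vapply(states, `[[`, 0, tr)) > 0), info = tr)
  expect_error(growth_state_at_age(gp, -1), "age")
  expect_error(growth_params(birth_bw = 50, asymptote_bw = 40), "asymptote")
})

test_that("degenerate sphere shape reproduces closed forms", {
  r <- 0.5
  sh <- sphere_shape(r)
  for (res in c(64, 256)) {
    bm <- build_heifer_mesh(sh, res)
    tol <- if (res >= 256) 0.001 else 0.01
    expect_lt(abs(mesh_volume(bm$mesh) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
              tol)
    expect_lt(abs(mesh_surface_area(bm$mesh) - 4 * pi * r^2) / (4 * pi * r^2),
              tol)
    expect_true(is_watertight(bm$mesh))
    expect_true(is_oriented(bm$mesh))
  }
  # ground truth agrees with the closed form exactly
  gt <- shape_ground_truth(sh)
  expect_equal(gt$volume, 4 / 3 * pi * r^3, tolerance = 1e-6)
  expect_equal(gt$bsa, 4 * pi * r^2, tolerance = 1e-4)
})

test_that("ground truth obeys exact similarity scaling", {
  s1 <- shape_preset("month06")
  s2 <- heifer3d:::scale_shape(s1, 2)
  g1 <- shape_ground_truth(s1)
  g2 <- shape_ground_truth(s2)
  expect_equal(g2$volume, 8 * g1$volume, tolerance = 1e-9)
  expect_equal(g2$bsa, 4 * g1$bsa, tolerance = 1e-9)
  for (tr in c("hg", "wh", "cd", "hw", "kw"))
    expect_equal(g2[[tr]], 2 * g1[[tr]], tolerance = 1e-9, info = tr)
})

test_that("preset ground truths satisfy the trait invariants", {
  for (st in heifer3d:::heifer_stage_table()$stage) {
    gt <- shape_ground_truth(shape_preset(st))
    expect_gt(gt$volume, 0)
    expect_gt(gt$bsa, 0)
    expect_gt(gt$hg, 2 * gt$cd)
    expect_lt(gt$cd, gt$wh)
    expect_gt(gt$bw, 0)
  }
})

test_that("point sampling is on-surface, uniform and deterministic", {
  sp <- mesh_sphere(1, res = 64)
  pc <- sample_point_cloud(sp, 2000, noise_sd = 0, seed = 5)
  d <- heifer3d:::cpp_points_mesh_distance(pc$points, sp$vertices,
                                           sp$faces - 1L)
  expect_lt(max(d), 1e-9)
  pc2 <- sample_point_cloud(sp, 2000, noise_sd = 0, seed = 5)
  expect_identical(pc$points, pc2$points)
  pc3 <- sample_point_cloud(sp, 2000, noise_sd = 0, seed = 6)
  expect_false(identical(pc$points, pc3$points))
  # radial Monte-Carlo oracle: mean radius ~ 1 within 3 sd / sqrt(n)
  pcn <- sample_point_cloud(sp, 10000, noise_sd = 0.05, seed = 1)
  rad <- sqrt(rowSums(pcn$points^2))
  expect_lt(abs(mean(rad) - 1), 3 * 0.05 / sqrt(10000) + 3e-3)
  expect_error(sample_point_cloud(sp, 10), "at least 100")
})

test_that("herd simulation matches its configuration", {
  gp <- growth_params()
  # zero noise, zero spread: records equal the growth curve exactly
  gp0 <- gp
  gp0$noise_sd[] <- 0
  herd0 <- simulate_herd(gp0, 1, c(100, 200, 300), seed = 3,
                         cv = c(asymptote = 0, rate = 0))
  st <- growth_state_at_age(gp, c(100, 200, 300))
  expect_equal(herd0$traits$hg, st$hg, tolerance = 1e-12)
  expect_equal(herd0$weights$bw, st$bw, tolerance = 1e-12)

  # monthly visits: each animal weighed at least 20 times
  herd <- simulate_herd(gp, 5, seq(35, 620, by = 28), seed = 1)
  counts <- table(herd$weights$animal_id)
  expect_true(all(counts >= 20))
  expect_identical(nrow(herd$traits), nrow(herd$weights))

  # between-animal spread propagates to BW sd at one year (delta oracle)
  herd100 <- simulate_herd(gp, 100, 369, seed = 11)
  sd_obs <- sd(herd100$weights$bw)
  sd_cfg <- heifer3d:::herd_bw_sd(gp, 369)
  expect_lt(abs(sd_obs - sd_cfg) / sd_cfg, 0.30)

  # reproducibility
  herd_b <- simulate_herd(gp, 5, seq(35, 620, by = 28), seed = 1)
  expect_identical(herd$traits, herd_b$traits)
})

test_that("skirt injection inflates the solid and is detected downstream", {
  mesh <- month12_small()$mesh
  v0 <- mesh_volume(mesh)
  a0 <- mesh_surface_area(mesh)
  expect_identical(inject_skirt(mesh, 0, seed = 1), mesh)
  for (sev in c(0.5, 1)) {
    sk <- inject_skirt(mesh, sev, seed = 2)
    expect_true(is_watertight(sk))
    expect_gt(mesh_volume(sk), v0)
    expect_gt(mesh_surface_area(sk), a0)
  }
  sk1 <- .fixtures[["skirt_full"]] <- inject_skirt(mesh, 1, seed = 2)
  q <- score_quality(sk1)
  expect_lte(q$score, 2L)
  # no legs -> error
  ball <- build_heifer_mesh(sphere_shape(0.5), 48)$mesh
  expect_error(inject_skirt(ball, 0.5), "leg|axis")
})
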