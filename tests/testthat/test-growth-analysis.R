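test_that("interpolation is exact at knots, linear between, bounded", {
  w <- data.frame(animal_id = "a", age = c(100, 200, 300),
                  bw = c(100, 200, 260))
  expect_equal(interpolate_bw(w, 200)$bw, 200)
  expect_false(interpolate_bw(w, 200)$interpolated)
  out <- interpolate_bw(w, 150)
  expect_equal(out$bw, 150)
  expect_true(out$interpolated)
  expect_error(interpolate_bw(w, 90), "extrapolation")
  expect_error(interpolate_bw(w, 310), "extrapolation")
  expect_error(interpolate_bw(w[1, ], 100), "two records")
  # monotone between monotone knots
  grid <- interpolate_bw(w, seq(100, 300, by = 10))
  expect_true(all(diff(grid$bw) >= 0))
})

test_that("daily gain follows the printed-means arithmetic", {
  w <- data.frame(animal_id = "a", age = c(100, 200), bw = c(100, 200))
  expect_equal(average_daily_gain(w, c(100, 200)), 1.0)
  wc <- data.frame(animal_id = "a", age = c(0, 500), bw = c(80, 80))
  expect_equal(average_daily_gain(wc, c(100, 400)), 0)
  # stage means, 2 -> 12 months: (366.8 - 84.5) / (369.2 - 62.0)
  tab <- heifer3d:::heifer_stage_table()
  w3 <- data.frame(animal_id = "a", age = tab$age, bw = tab$bw)
  adg <- average_daily_gain(w3, c(62.0, 369.2))
  expect_equal(round(adg, 3), round((366.8 - 84.5) / (369.2 - 62.0), 3))
  expect_error(average_daily_gain(w, c(100, 100)), "distinct")
})

test_that("stage summaries reproduce a noiseless herd exactly", {
  gp <- growth_params()
  gp$noise_sd[] <- 0
  herd <- simulate_herd(gp, 3, c(136.4, 246.8, 369.2), seed = 2,
                        cv = c(asymptote = 0, rate = 0))
  sm <- suppressWarnings(stage_summary(herd$traits, herd$weights))
  st <- growth_state_at_age(gp, 369.2)
  r12 <- sm[sm$stage == "month12", ]
  expect_equal(r12$hg_mean, st$hg, tolerance = 1e-9)
  expect_equal(r12$volume_mean, st$volume, tolerance = 1e-9)
  expect_equal(r12$bw_mean, st$bw, tolerance = 1e-9)
  expect_equal(r12$hg_sd, 0)
  expect_identical(r12$n, 3L)
  # singleton stage reports NA sd; empty stage warns and is omitted
  one <- simulate_herd(gp, 1, 62, seed = 3, cv = c(asymptote = 0, rate = 0))
  one$weights <- rbind(one$weights,
                       data.frame(animal_id = "H001", age = 63, bw = 85,
                                  interpolated = FALSE))
  expect_warning(
    sm1 <- stage_summary(one$traits, one$weights,
                         stages = list(month02 = c(47, 77),
                                       month04 = c(121, 151))),
    "no visits")
  expect_true(is.na(sm1$hg_sd[1]))
})

test_that("quality gating excludes poor scans from bsa/volume only", {
  gp <- growth_params()
  gp$noise_sd[] <- 0
  herd <- simulate_herd(gp, 2, 369.2, seed = 4,
                        cv = c(asymptote = 0, rate = 0))
  herd$traits$quality <- c(2L, 4L)
  herd$traits$volume[1] <- 99 # would wreck the mean if not gated
  sm <- suppressWarnings(stage_summary(herd$traits, herd$weights))
  st <- growth_state_at_age(gp, 369.2)
  expect_equal(sm$volume_mean, st$volume, tolerance = 1e-9)
  expect_equal(sm$hg_mean, st$hg, tolerance = 1e-9) # linear traits kept
})

test_that("growth ratios reproduce the printed stage-mean arithmetic", {
  tab <- heifer3d:::heifer_stage_table()
  sm <- data.frame(stage = tab$stage, volume_mean = tab$volume,
                   bsa_mean = tab$bsa, bw_mean = tab$bw)
  expect_equal(round(growth_ratio(sm, "volume", "month02", "month20"), 1), 5.1)
  expect_equal(round(growth_ratio(sm, "bsa", "month02", "month20"), 1), 2.3)
  expect_equal(growth_ratio(sm, "bsa", "month12", "month12"), 1.0)
  expect_error(growth_ratio(sm, "volume", "month02", "month99"), "stage")
  expect_error(growth_ratio(sm, "nope", "month02", "month20"), "trait")
})

test_that("surface-to-volume decay recovers the isometric exponent", {
  s <- seq(1, 1.8, length.out = 24)
  tr <- data.frame(animal_id = "a", age = seq_along(s), bsa = 4.2 * s^2,
                   volume = 0.35 * s^3, bw = 315 * s^3, quality = 4L)
  sv <- surface_to_volume_curve(tr)
  expect_equal(sv$b, 1 / 3, tolerance = 1e-6)
  # fitted ratio decreases in BW when b > 0
  bw <- seq(100, 600, length.out = 50)
  expect_true(all(diff(predict(sv, bw)) < 0))
  # ratios from the stage means decrease with BW
  tab <- heifer3d:::heifer_stage_table()
  expect_equal(round(tab$bsa[1] / tab$volume[1], 2), 22.75)
  expect_equal(round(tab$bsa[7] / tab$volume[7], 2), 10.44)
  expect_lt(tab$bsa[7] / tab$volume[7], tab$bsa[1] / tab$volume[1])
})

test_that("degenerate and alternative decay fits behave", {
  tr <- data.frame(animal_id = "a", age = 1:10, bsa = 4, volume = 0.4,
                   bw = seq(200, 400, length.out = 10), quality = 4L)
  expect_warning(sv0 <- surface_to_volume_curve(tr), "not decrease")
  expect_equal(sv0$b, 0, tolerance = 1e-9)
  s <- seq(1, 1.8, length.out = 24)
  tr2 <- data.frame(animal_id = "a", age = seq_along(s), bsa = 4.2 * s^2,
                    volume = 0.35 * s^3, bw = 315 * s^3, quality = 4L)
  sve <- surface_to_volume_curve(tr2, model = "exponential")
  expect_gt(sve$b, 0)
  expect_error(surface_to_volume_curve(tr2[1:2, ]), "3 valid")
})

test_that("bw is interpolated from weighing records when absent", {
  gp <- growth_params()
  herd <- simulate_herd(gp, 3, seq(62, 605, by = 35), seed = 6)
  sv <- surface_to_volume_curve(herd$traits, herd$weights)
  expect_gt(sv$b, 0.1)
  expect_lt(sv$b, 0.6)
})
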