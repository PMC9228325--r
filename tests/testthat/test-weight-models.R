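test_that("built-in equations evaluate and serialize exactly", {
  m <- builtin_models()
  expect_length(m, 8)
  # direct arithmetic on the printed coefficients
  expect_equal(predict_bw(m$eq5, list(volume = 0.43)), 827.5 * 0.43 + 45.8)
  expect_equal(predict_bw(m$eq8, list(volume = 0.43)), 922.3 * 0.43 - 34.4)
  expect_equal(predict_bw(m$eq5, list(volume = 0)), 45.8)
  expect_equal(predict_bw(m$eq3, list(bsa = 5.21)), 102.3 * 5.21 - 30.3)
  expect_equal(predict_bw(m$eq6, list(bsa = 5.21)), 118.2 * 5.21 - 259.3)
  expect_error(predict_bw(m$eq5, list(bsa = 5)), "volume")
  expect_error(predict_bw(m$eq5, list(volume = NA_real_)), "volume")

  # serialization round-trips the printed decimal strings bit-exactly
  tf <- tempfile(fileext = ".txt")
  write_models(m, tf)
  m2 <- read_models(tf)
  expect_identical(lapply(m, unclass), lapply(m2, unclass))
  expect_identical(m2$eq8$terms[["volume"]], "922.3")
})

test_that("allometric surface-area laws and their inversion agree", {
  expect_equal(elting_bsa(600, "adult"), 0.0839 * 600^0.67)
  expect_equal(round(elting_bsa(600, "adult"), 2), 6.10)
  expect_equal(round(elting_bsa(84.5, "heifer"), 2), 1.76)
  expect_equal(elting_bsa(1, "adult"), 0.0839)
  expect_equal(elting_bsa(1, "heifer"), 0.147)
  expect_equal(bw_from_bsa_elting(elting_bsa(600, "adult"), "adult"), 600,
               tolerance = 1e-9)
  # arithmetic oracle: (4.16 / 0.147)^(1 / 0.56)
  expect_equal(bw_from_bsa_elting(4.16, "heifer"),
               (4.16 / 0.147)^(1 / 0.56), tolerance = 1e-12)
  expect_equal(bw_from_bsa_elting(0.0839, "adult"), 1, tolerance = 1e-9)
  expect_error(elting_bsa(-1), "positive")
  expect_error(bw_from_bsa_elting(0), "positive")
})

test_that("prediction is affine in each predictor", {
  m <- builtin_models()$eq4
  base <- list(volume = 0.4, bsa = 5, kw = 0.4, hw = 0.5, hg = 1.8, wh = 1.3)
  zero <- lapply(base, function(x) 0)
  p0 <- predict_bw(m, zero)
  for (p in names(base)) {
    one <- zero
    one[[p]] <- 1
    slope <- predict_bw(m, one) - p0
    two <- zero
    two[[p]] <- 2.5
    expect_equal(predict_bw(m, two) - p0, 2.5 * slope, tolerance = 1e-9)
  }
})

test_that("refitting recovers generating coefficients", {
  # noiseless: exact recovery
  tr <- herd_with_bw(31, noise = 0)
  f0 <- suppressWarnings(fit_weight_model(tr, "volume"))
  expect_equal(unname(coef(f0)), c(-34.4, 922.3), tolerance = 1e-6)

  # 10 kg noise, n = 69: slope within 3 standard errors, R^2 high
  tr <- herd_with_bw(32)
  f <- fit_weight_model(tr, "volume")
  se <- summary(f)$coefficients["volume", "Std. Error"]
  expect_lt(abs(coef(f)[["volume"]] - 922.3), 3 * se)
  expect_gt(f$r2, 0.9)
  expect_identical(f$n, 69L)
  expect_true(all(f$p_values >= 0 & f$p_values <= 1))
})

test_that("through-origin fits use the uncentered R^2 convention", {
  tr <- herd_with_bw(33, coefs = c(volume = 900), intercept = 0, noise = 8)
  f <- fit_weight_model(tr, "volume", through_origin = TRUE)
  expect_identical(unname(coef(f)["(Intercept)"]), 0)
  yhat <- predict(f, tr)
  r2_uncentered <- 1 - sum((tr$bw - yhat)^2) / sum(tr$bw^2)
  expect_equal(f$r2, r2_uncentered, tolerance = 1e-9)
  # slope recovery as good as the free fit on zero-intercept data
  ff <- fit_weight_model(tr, "volume")
  expect_lt(abs(coef(f)[["volume"]] - 900),
            abs(coef(ff)[["volume"]] - 900) + 25)
})

test_that("backward elimination prunes spurious predictors", {
  tr <- herd_with_bw(34, coefs = c(volume = 900, hw = 120), intercept = 20)
  f <- fit_weight_model(tr, c("volume", "bsa", "kw", "hg", "wh", "hw"),
                        prune_alpha = 0.05)
  expect_true("volume" %in% names(f$model$terms))
  expect_true(all(f$p_values <= 0.05))
  expect_true(length(f$dropped) >= 1)
  expect_identical(setdiff(names(f$model$terms),
                           c("volume", "bsa", "kw", "hg", "wh", "hw")),
                   character(0))
})

test_that("rank-deficient designs are refused with the culprits named", {
  tr <- herd_with_bw(35)
  tr$vol2 <- tr$volume * 2
  expect_error(fit_weight_model(tr, c("volume", "vol2")), "collinear")
  expect_error(fit_weight_model(tr[1:2, ], "volume"), "observations")
})

test_that("estimate comparison reproduces printed-arithmetic examples", {
  cmp <- compare_estimates(551, 561)
  expect_equal(round(cmp$mean_pct, 1), 1.8)
  cmp2 <- compare_estimates(c(100, 200), c(110, 210))
  expect_equal(cmp2$mean_pct, 7.5)
  expect_equal(cmp2$bias, 10)
  ident <- compare_estimates(c(300, 400), c(300, 400))
  expect_equal(ident$mean_pct, 0)
  expect_equal(ident$rmse, 0)
  byage <- compare_estimates(c(100, 200), c(110, 210), ages = c(6, 20))
  expect_equal(byage$by_age$mean_pct, c(10, 5))
  expect_error(compare_estimates(c(-1, 2), c(1, 2)), "positive")
  expect_error(compare_estimates(1:3, 1:2), "length")
})

test_that("OLS refits are unbiased over Monte-Carlo repetitions", {
  slopes <- vapply(1:200, function(r) {
    tr <- herd_with_bw(4000 + r, n = 40)
    coef(fit_weight_model(tr, "volume"))[["volume"]]
  }, 0)
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 922.3), 3 * se_mean + 1)
})
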