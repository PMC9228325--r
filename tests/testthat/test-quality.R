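test_that("clean meshes score 4 with no skirt", {
  mesh <- month12_small()$mesh
  fr <- fit_body_frame(mesh)
  sk <- detect_skirt(mesh, fr)
  expect_false(sk$detected)
  expect_equal(sk$severity, 0)
  expect_true(all(sk$components_by_height == 4))
  expect_identical(detect_missing(mesh, fr), character(0))
  q <- score_quality(mesh)
  expect_identical(q$score, 4L)
  expect_true(q$watertight)
})

test_that("injected skirts are flagged with severity matching the injection", {
  mesh <- month12_small()$mesh
  sk1 <- .fixtures[["skirt_full"]] %||% inject_skirt(mesh, 1, seed = 2)
  d1 <- detect_skirt(sk1, fit_body_frame(sk1))
  expect_true(d1$detected)
  expect_gte(d1$severity, 0.8)
  expect_identical(detect_skirt(mesh, fit_body_frame(mesh))$detected, FALSE)
})

test_that("missing regions are reported by name", {
  headless <- build_heifer_mesh(headless_shape(), 48,
                                ground_truth = FALSE)$mesh
  fr <- fit_body_frame(headless)
  expect_true("head" %in% detect_missing(headless, fr))

  mesh <- month12_small()$mesh
  legless <- drop_faces_below(mesh, 0.5)
  expect_true("leg" %in% detect_missing(legless, fit_body_frame(legless)))
})

test_that("scores degrade monotonically as defects accumulate", {
  mesh <- month12_small()$mesh
  q0 <- score_quality(mesh)$score                      # pristine
  skirted <- .fixtures[["skirt_full"]] %||% inject_skirt(mesh, 1, seed = 2)
  q1 <- score_quality(skirted)$score                   # one major defect
  # skirt + missing head
  headless <- build_heifer_mesh(headless_shape(), 48,
                                ground_truth = FALSE)$mesh
  hs <- inject_skirt(headless, 1, seed = 3)
  q2 <- score_quality(hs)$score                        # two defects
  expect_identical(q0, 4L)
  expect_identical(q1, 2L)
  expect_identical(q2, 1L)
  expect_true(q0 >= q1 && q1 >= q2)
})

test_that("report invariants hold on varied inputs", {
  meshes <- list(month12_small()$mesh,
                 drop_faces_below(month12_small()$mesh, 0.5),
                 mesh_sphere(1, 32))
  for (m in meshes) {
    q <- score_quality(m)
    if (q$score == 4L) {
      expect_true(q$watertight)
      expect_length(q$missing_region, 0)
      expect_false(q$skirt_detected)
    }
    if (q$score == 1L)
      expect_true(!q$watertight || length(q$missing_region) > 0 ||
                  isTRUE(q$skirt_severity > 0.4))
  }
})
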