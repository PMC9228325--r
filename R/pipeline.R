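#' Shape at an arbitrary age
#'
#' Linearly interpolates every dimension of the calibrated stage presets
#' in age (clamped to the preset range), giving a continuous family of
#' growing body shapes.
#'
#' @param age age in days.
#' @return a [heifer_shape()].
#' @export
shape_at_age <- function(age) {
  tab <- heifer_stage_table()
  ages <- tab$age
  age <- min(max(age, min(ages)), max(ages))
  i <- findInterval(age, ages, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(tab) - 1L)
  s0 <- shape_preset(tab$stage[i])
  s1 <- shape_preset(tab$stage[i + 1])
  t <- (age - ages[i]) / (ages[i + 1] - ages[i])
  out <- s0
  for (f in names(s0)) {
    if (is.numeric(s0[[f]])) out[[f]] <- (1 - t) * s0[[f]] + t * s1[[f]]
  }
  validate_shape(out)
}

# uniform similarity scaling of all shape lengths
scale_shape <- function(shape, s) {
  len_fields <- c("torso_length", "torso_height_radius", "torso_width_radius",
                  "torso_center_z", "leg_length", "leg_radius",
                  "leg_stance_x", "leg_stance_y", "neck_length",
                  "neck_radius", "head_length", "head_radius")
  for (f in len_fields) shape[[f]] <- shape[[f]] * s
  validate_shape(shape)
}

#' Default pipeline configuration
#'
#' @param ... overrides of the default fields.
#' @return configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 42L,
    n_animals = 2L,
    visit_ages = c(136, 250, 369),
    resolution = 48,
    defect_prob = list(skirt = 0, missing_head = 0),
    reconstruct = FALSE,
    recon_points = 60000,
    recon_noise = 0.002,
    model = "eq8",
    cv = c(asymptote = 0.08, rate = 0.05),
    out_dir = NULL)
  ovr <- list(...)
  for (nm in names(ovr)) {
    if (!nm %in% names(cfg)) stop("unknown pipeline config field: ", nm)
    if (nm == "defect_prob") {
      for (k in names(ovr[[nm]])) cfg$defect_prob[[k]] <- ovr[[nm]][[k]]
    } else cfg[[nm]] <- ovr[[nm]]
  }
  if (any(unlist(cfg$defect_prob) < 0) || any(unlist(cfg$defect_prob) > 1))
    stop("defect probabilities must lie in [0, 1]")
  if (!cfg$model %in% names(builtin_models()))
    stop("unknown prediction model: ", cfg$model)
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a herd, builds a body mesh per animal-visit (optionally
#' corrupted with scan defects and/or re-acquired through the point-cloud
#' reconstruction path), measures all traits, scores quality, predicts
#' body weight, summarises growth stages and fits the surface-to-volume
#' curve.  All artifacts (meshes, traits.csv, weights.csv, qc/*.json,
#' bw_predicted.csv, summary.csv, curve.json and a hash manifest) are
#' written to the run directory.  Fully deterministic given the seed.
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @return the run directory, invisibly; its `manifest.json` lists every
#'   output with an md5 hash.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- do.call(pipeline_config,
                                              yaml::read_yaml(config))
  cfg <- do.call(pipeline_config, config[setdiff(names(config), NULL)])
  dir <- cfg$out_dir %||% tempfile("heifer3d_run_")
  for (sub in c("", "meshes", "qc"))
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)

  growth <- growth_params()
  herd <- simulate_herd(growth, cfg$n_animals, cfg$visit_ages,
                        seed = cfg$seed, cv = cfg$cv)
  weights <- herd$weights

  traits <- list()
  ids <- unique(weights$animal_id)
  for (ai in seq_along(ids)) {
    for (vi in seq_along(cfg$visit_ages)) {
      age <- cfg$visit_ages[vi]
      vseed <- cfg$seed + 1000L * ai + vi
      bw_i <- weights$bw[weights$animal_id == ids[ai] & weights$age == age]
      sh <- shape_at_age(age)
      base_bw <- growth_state_at_age(growth, age)$bw
      sh <- scale_shape(sh, (max(bw_i, 1) / base_bw)^(1 / 3))
      defect <- with_seed(vseed, runif(2))
      if (defect[2] < cfg$defect_prob$missing_head) {
        front <- sh$head_length + sh$neck_length
        sh$head_radius <- 0
        sh$neck_radius <- 0
        sh$leg_stance_x <- sh$leg_stance_x - front
        sh <- validate_shape(sh)
      }
      built <- build_heifer_mesh(sh, cfg$resolution, ground_truth = FALSE)
      mesh <- built$mesh
      if (defect[1] < cfg$defect_prob$skirt)
        mesh <- inject_skirt(mesh, with_seed(vseed + 1L, runif(1, 0.5, 1)),
                             seed = vseed)
      if (cfg$reconstruct) {
        pc <- sample_point_cloud(mesh, cfg$recon_points, cfg$recon_noise,
                                 seed = vseed + 2L)
        mesh <- reconstruct_surface(estimate_normals(point_cloud(pc$points)))
      }
      tag <- sprintf("%s_d%03d", ids[ai], age)
      write_mesh(mesh, file.path(dir, "meshes", paste0(tag, ".ply")))
      rec <- measure_all(mesh, ids[ai], age)
      qr <- score_quality(mesh)
      jsonlite::write_json(
        list(mesh = paste0(tag, ".ply"), score = qr$score,
             watertight = qr$watertight, skirt_detected = qr$skirt_detected,
             skirt_severity = qr$skirt_severity,
             missing_region = qr$missing_region,
             leg_components_by_station =
               as.list(qr$leg_components_by_station)),
        file.path(dir, "qc", paste0(tag, ".json")), auto_unbox = TRUE)
      traits[[tag]] <- rec
    }
  }
  traits <- do.call(rbind, traits)
  rownames(traits) <- NULL
  write_traits(traits, file.path(dir, "traits.csv"))
  utils::write.csv(
    data.frame(animal_id = weights$animal_id, age_days = weights$age,
               bw_kg = weights$bw),
    file.path(dir, "weights.csv"), row.names = FALSE)

  # body-weight prediction on usable records
  model <- builtin_models()[[cfg$model]]
  usable <- traits[!is.na(traits$quality) & traits$quality >= 3, ,
                   drop = FALSE]
  pred <- lapply(seq_len(nrow(usable)), function(i) {
    est <- tryCatch(predict_bw(model, usable[i, ]), error = function(e) NA)
    meas <- tryCatch(
      interpolate_bw(weights[weights$animal_id == usable$animal_id[i], ],
                     usable$age[i])$bw, error = function(e) NA)
    data.frame(animal_id = usable$animal_id[i], age_days = usable$age[i],
               bw_measured_kg = meas, bw_estimated_kg = est)
  })
  pred <- do.call(rbind, pred)
  utils::write.csv(pred, file.path(dir, "bw_predicted.csv"), row.names = FALSE)

  sm <- suppressWarnings(stage_summary(traits, weights))
  utils::write.csv(sm, file.path(dir, "summary.csv"), row.names = FALSE)

  curve <- tryCatch({
    sv <- surface_to_volume_curve(traits, weights)
    list(model = sv$model, a = sv$a, b = sv$b, n = nrow(sv$data))
  }, error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(curve, file.path(dir, "curve.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    package_version = as.character(utils::packageVersion("heifer3d")),
    files = lapply(setNames(nm = files), function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
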