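#' Detect the "skirt" reconstruction artifact
#'
#' When leg point coverage is sparse, surface reconstruction webs the space
#' between legs with a spurious membrane, inflating volume and surface
#' area.  The leg zone (from the ground up to the torso underline, capped
#' at a fraction of withers height) is sliced at 10 evenly spaced heights;
#' a clean quadruped shows four separate leg sections per slice, so any
#' slice with fewer connected sections is counted as webbed.  Severity is
#' the webbed fraction of slices and the artifact is flagged when severity
#' exceeds `flag_threshold`.
#'
#' @param mesh a [mesh3t()] object.
#' @param frame a [fit_body_frame()] result.
#' @param n_slices number of heights sampled in the leg zone.
#' @param expected_legs leg sections expected per slice (4 for a quadruped).
#' @param flag_threshold severity above which the flag is raised.
#' @return list with `detected`, `severity` and `components_by_height`
#'   (named integer vector of section counts).
#' @export
detect_skirt <- function(mesh, frame, n_slices = 10, expected_legs = 4,
                         flag_threshold = 0.2) {
  wh <- withers_height(mesh, frame)
  belly <- belly_height(mesh, frame)
  zone_top <- min(belly, frame$stations$leg_zone_frac * wh) # above ground
  if (zone_top < 0.05 * wh) stop("no leg zone detected")
  hts <- frame$ground + (seq_len(n_slices) - 0.5) / n_slices *
    zone_top * 0.96 + 0.02 * zone_top
  counts <- vapply(hts, function(z) length(height_slice(mesh, frame, z)), 0L)
  if (all(counts == 0)) stop("no leg region detected below the torso")
  names(counts) <- sprintf("%.3f", hts - frame$ground)
  webbed <- counts < expected_legs
  severity <- mean(webbed)
  list(detected = severity > flag_threshold, severity = severity,
       components_by_height = counts)
}

# height of the torso underline above ground, from the mid-body section
belly_height <- function(mesh, frame) {
  # section up-coordinates are measured from the origin, which sits on the
  # ground plane, so this is already a height above ground
  polys <- cross_section(mesh, frame, 0.5)
  main <- polys[[which.max(vapply(polys, attr, 0, "area"))]]
  min(main[, 2])
}

#' Detect missing body regions
#'
#' Compares the digitised surface against quadruped anatomy: a head/neck
#' section should overhang in front of the forelegs by a substantial
#' fraction of body length, legs should be present below the torso
#' underline, and the trunk should yield a mid-body cross-section.
#'
#' @param mesh a [mesh3t()] object.
#' @param frame a [fit_body_frame()] result.
#' @param head_overhang_min minimum fraction of body length in front of the
#'   foremost leg pillar for the head to be considered present.
#' @return character vector drawn from `c("head", "leg", "torso")`; empty
#'   when nothing is missing.
#' @export
detect_missing <- function(mesh, frame, head_overhang_min = 0.30) {
  missing <- character(0)
  torso_ok <- tryCatch({
    cross_section(mesh, frame, 0.5)
    TRUE
  }, error = function(e) FALSE)
  if (!torso_ok) missing <- c(missing, "torso")

  wh <- tryCatch(withers_height(mesh, frame), error = function(e) NA_real_)
  belly <- tryCatch(belly_height(mesh, frame), error = function(e) NA_real_)
  zone_top <- min(belly, frame$stations$leg_zone_frac * wh, na.rm = TRUE)
  legs <- if (is.finite(zone_top) && zone_top > 0.02) {
    z <- frame$ground + 0.5 * zone_top
    height_slice(mesh, frame, z)
  } else list()
  if (!length(legs)) {
    missing <- c(missing, "leg")
  } else {
    # axial centroid of the foremost leg pillar
    ax <- vapply(legs, function(p) mean(p[, 1]), 0)
    if (min(ax) / frame$body_length < head_overhang_min)
      missing <- c(missing, "head")
  }
  missing
}

#' Score scan quality on the 1-4 scale
#'
#' Operationalises the visual usability scale applied to each image:
#' 4 = sufficient (watertight, no skirt, nothing missing); 3 = some
#' defects (skirt severity at most 0.4 but otherwise intact); 2 =
#' partially usable (exactly one major defect: not watertight, a missing
#' region, or skirt severity above 0.4 - linear traits may still be
#' measurable); 1 = not usable (two or more major defects, or no
#' recognisable body frame).
#'
#' @param mesh a [mesh3t()] object.
#' @param stations landmark table from [anatomy_stations()].
#' @return list of class `quality_report`: `score`, `skirt_detected`,
#'   `skirt_severity`, `missing_region`, `watertight`,
#'   `leg_components_by_station`.
#' @export
score_quality <- function(mesh, stations = anatomy_stations()) {
  watertight <- is_watertight(mesh)
  frame <- tryCatch(fit_body_frame(mesh, stations), error = function(e) NULL)
  if (is.null(frame)) {
    return(structure(list(score = 1L, skirt_detected = FALSE,
                          skirt_severity = NA_real_,
                          missing_region = "torso", watertight = watertight,
                          leg_components_by_station = integer(0)),
                     class = "quality_report"))
  }
  missing <- tryCatch(detect_missing(mesh, frame),
                      error = function(e) "torso")
  skirt <- tryCatch(detect_skirt(mesh, frame), error = function(e)
    list(detected = FALSE, severity = 0, components_by_height = integer(0)))
  major <- sum(!watertight, length(missing) > 0, skirt$severity > 0.4)
  score <- if (major >= 2) 1L else if (major == 1) 2L
           else if (skirt$severity > 0) 3L else 4L
  structure(list(score = score, skirt_detected = skirt$detected,
                 skirt_severity = skirt$severity, missing_region = missing,
                 watertight = watertight,
                 leg_components_by_station = skirt$components_by_height),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: score %d (watertight: %s)\n", x$score,
              x$watertight))
  if (length(x$missing_region))
    cat("  missing:", paste(x$missing_region, collapse = ", "), "\n")
  if (!is.na(x$skirt_severity) && x$skirt_severity > 0)
    cat(sprintf("  skirt severity %.2f%s\n", x$skirt_severity,
                if (x$skirt_detected) " (flagged)" else ""))
  invisible(x)
}
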