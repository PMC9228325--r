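#' Interpolate body weight between weighing dates
#'
#' Linear interpolation in age, per animal, exact at the recorded knots.
#' Extrapolation outside an animal's recorded age range is an error,
#' mirroring a design in which weights are only compared within the
#' recorded span.
#'
#' @param records data.frame with columns `animal_id`, `age` (days) and
#'   `bw` (kg); at least two records per animal.
#' @param target_ages ages (days) at which weights are required.
#' @return data.frame `animal_id`, `age`, `bw`, `interpolated` (TRUE for
#'   ages that are not recorded knots).
#' @export
interpolate_bw <- function(records, target_ages) {
  records <- as.data.frame(records)
  out <- lapply(split(records, records$animal_id), function(r) {
    if (nrow(r) < 2) stop("need at least two records per animal")
    if (anyDuplicated(r$age)) stop("duplicate ages for animal ", r$animal_id[1])
    r <- r[order(r$age), ]
    if (any(target_ages < min(r$age) - 1e-9) ||
        any(target_ages > max(r$age) + 1e-9))
      stop(sprintf("extrapolation requested for animal %s (range %g-%g d)",
                   r$animal_id[1], min(r$age), max(r$age)))
    bw <- approx(r$age, r$bw, xout = target_ages, rule = 1)$y
    data.frame(animal_id = r$animal_id[1], age = target_ages, bw = bw,
               interpolated = !(target_ages %in% r$age),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average daily gain over an age window
#'
#' @param records weighing records as in [interpolate_bw()] (one animal).
#' @param window length-2 vector `c(start, end)` in days, inside the
#'   recorded range.
#' @return gain in kg/day.
#' @export
average_daily_gain <- function(records, window) {
  if (length(window) != 2 || diff(window) == 0)
    stop("window must be two distinct ages")
  ends <- interpolate_bw(records, sort(window))
  diff(ends$bw) / abs(diff(window)) * sign(diff(window))^0
}

#' Stage summaries of a longitudinal trait table
#'
#' For each growth stage (an age window), computes the mean and sample
#' standard deviation (n - 1 denominator) of body weight and each trait
#' over the visits falling in the window.  Surface area and volume are
#' gated on quality score >= 3; linear traits are kept whenever present.
#' Body weight at each visit is interpolated from the weighing records.
#' The standard deviation is reported as `NA` for singleton stages;
#' stages with no visits are omitted with a warning.
#'
#' @param traits trait records (columns as produced by [measure_all()] or
#'   [simulate_herd()]).
#' @param weights weighing records (`animal_id`, `age`, `bw`).
#' @param stages named list of `c(lo, hi)` age windows in days; defaults
#'   to the seven growth stages of the study, each +/- 15 days around the
#'   stage mean age.
#' @return data.frame with one row per stage: `stage`, `n`, `mean_age`,
#'   then `<trait>_mean` and `<trait>_sd` for bw, bsa, volume, hg, wh,
#'   cd, hw, kw.
#' @export
stage_summary <- function(traits, weights,
                          stages = default_stage_windows()) {
  traits <- as.data.frame(traits)
  trcols <- c("bsa", "volume", "hg", "wh", "cd", "hw", "kw")
  rows <- list()
  for (lab in names(stages)) {
    win <- stages[[lab]]
    sel <- traits$age >= win[1] & traits$age <= win[2]
    if (!any(sel)) {
      warning("stage ", lab, " has no visits; omitted")
      next
    }
    tt <- traits[sel, , drop = FALSE]
    if ("quality" %in% names(tt)) {
      gate <- !is.na(tt$quality) & tt$quality >= 3
      tt$bsa[!gate] <- NA
      tt$volume[!gate] <- NA
    }
    bw <- rep(NA_real_, nrow(tt))
    for (i in seq_len(nrow(tt))) {
      w <- weights[weights$animal_id == tt$animal_id[i], , drop = FALSE]
      bw[i] <- tryCatch(interpolate_bw(w, tt$age[i])$bw,
                        error = function(e) NA_real_)
    }
    msd <- function(v) {
      v <- v[!is.na(v)]
      c(mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_)
    }
    row <- data.frame(stage = lab, n = nrow(tt), mean_age = mean(tt$age),
                      stringsAsFactors = FALSE)
    vals <- c(list(bw = bw), as.list(tt[, intersect(trcols, names(tt)),
                                        drop = FALSE]))
    for (v in names(vals)) {
      ms <- msd(vals[[v]])
      row[[paste0(v, "_mean")]] <- ms[["mean"]]
      row[[paste0(v, "_sd")]] <- ms[["sd"]]
    }
    rows[[lab]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname stage_summary
#' @export
default_stage_windows <- function() {
  tab <- heifer_stage_table()
  setNames(lapply(tab$age, function(a) c(a - 15, a + 15)), tab$stage)
}

#' Growth ratio between two stages
#'
#' Ratio of stage means of one trait, e.g. how many times larger the
#' volume at 20 months is than at 2 months.
#'
#' @param summaries a [stage_summary()] data.frame.
#' @param trait one of bw, bsa, volume, hg, wh, cd, hw, kw.
#' @param from_stage,to_stage stage labels.
#' @return the ratio `mean(to) / mean(from)` (report at 1 decimal place).
#' @export
growth_ratio <- function(summaries, trait, from_stage, to_stage) {
  col <- paste0(trait, "_mean")
  if (!col %in% names(summaries)) stop("unknown trait ", trait)
  f <- summaries[[col]][summaries$stage == from_stage]
  t <- summaries[[col]][summaries$stage == to_stage]
  if (!length(f) || !length(t)) stop("stage not present in summaries")
  if (is.na(f) || f == 0) stop("zero or missing denominator stage mean")
  t / f
}

#' Surface-to-volume dynamics
#'
#' Computes the per-record surface-to-volume ratio (BSA / volume, 1/m) and
#' fits its decay against body weight: a power law
#' `ratio = a BW^(-b)` by least squares on the log-log scale (the default;
#' isometric growth predicts b = 1/3), or an exponential decay
#' `ratio = a exp(-b BW)` on the semi-log scale.
#'
#' @param traits trait records with `bsa`, `volume` (and `quality`,
#'   gated at score >= 3).
#' @param weights weighing records used to attach a body weight to each
#'   visit (interpolated in age); alternatively `traits` may already
#'   carry a `bw` column.
#' @param model `"power"` or `"exponential"`.
#' @return object of class `sv_fit`: `a`, `b`, `model`, `data` (bw,
#'   ratio), and the underlying `lm` fit.  A non-decreasing fit (b <= 0)
#'   raises a warning, not an error.
#' @export
surface_to_volume_curve <- function(traits, weights = NULL,
                                    model = c("power", "exponential")) {
  model <- match.arg(model)
  traits <- as.data.frame(traits)
  if (!("bw" %in% names(traits))) {
    if (is.null(weights)) stop("supply weighing records or a bw column")
    bw <- rep(NA_real_, nrow(traits))
    for (i in seq_len(nrow(traits))) {
      w <- weights[weights$animal_id == traits$animal_id[i], , drop = FALSE]
      bw[i] <- tryCatch(interpolate_bw(w, traits$age[i])$bw,
                        error = function(e) NA_real_)
    }
    traits$bw <- bw
  }
  if ("quality" %in% names(traits))
    traits <- traits[!is.na(traits$quality) & traits$quality >= 3, ,
                     drop = FALSE]
  ok <- complete.cases(traits[, c("bsa", "volume", "bw")]) &
    traits$bsa > 0 & traits$volume > 0 & traits$bw > 0
  dat <- traits[ok, , drop = FALSE]
  if (nrow(dat) < 3) stop("fewer than 3 valid (bsa, volume, bw) records")
  ratio <- dat$bsa / dat$volume
  fit <- if (model == "power") lm(log(ratio) ~ log(bw), data = dat)
         else lm(log(ratio) ~ bw, data = dat)
  a <- exp(coef(fit)[[1]])
  b <- -coef(fit)[[2]]
  if (b <= 0)
    warning("surface-to-volume ratio does not decrease with body weight")
  structure(list(a = a, b = b, model = model,
                 data = data.frame(bw = dat$bw, ratio = ratio), fit = fit),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  form <- if (x$model == "power") "a BW^(-b)" else "a exp(-b BW)"
  cat(sprintf("sv_fit: ratio = %s with a = %.3f, b = %.4f (n = %d)\n",
              form, x$a, x$b, nrow(x$data)))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.sv_fit <- function(object, bw, ...) {
  if (object$model == "power") object$a * bw^(-object$b)
  else object$a * exp(-object$b * bw)
}

#' @export
plot.sv_fit <- function(x, ...) {
  plot(x$data$bw, x$data$ratio, xlab = "body weight [kg]",
       ylab = "surface-to-volume ratio [1/m]", ...)
  bw <- seq(min(x$data$bw), max(x$data$bw), length.out = 200)
  graphics::lines(bw, predict(x, bw))
  invisible(x)
}
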