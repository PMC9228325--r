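#' Body-weight prediction models
#'
#' A `bw_model` is either a linear equation
#' `BW = intercept + sum(coefficient * predictor)` over trait predictors
#' (volume in m^3, bsa in m^2, linear traits in m), or an allometric
#' surface-area law `BSA = scale * BW^exponent` which predicts BW by exact
#' algebraic inversion.  Coefficients are carried both as numbers and as
#' the original decimal strings, so that serialization round-trips
#' reproduce printed coefficients exactly.
#'
#' @param name model identifier.
#' @param form `"linear"` or `"allometric"`.
#' @param intercept intercept in kg (string or number; linear form).
#' @param terms named character/numeric vector of predictor coefficients
#'   (linear form); names drawn from volume, bsa, hg, wh, cd, hw, kw.
#' @param scale,exponent allometric BSA-from-BW parameters.
#' @return an object of class `bw_model`.
#' @export
bw_model <- function(name, form = c("linear", "allometric"), intercept = "0",
                     terms = NULL, scale = NULL, exponent = NULL) {
  form <- match.arg(form)
  allowed <- c("volume", "bsa", "hg", "wh", "cd", "hw", "kw")
  if (form == "linear") {
    if (is.null(terms) || is.null(names(terms)) || !length(terms))
      stop("linear models need named terms")
    if (anyDuplicated(names(terms))) stop("duplicate predictors")
    if (!all(names(terms) %in% allowed))
      stop("unknown predictor: ", paste(setdiff(names(terms), allowed),
                                        collapse = ", "))
    m <- list(name = name, form = form,
              intercept = as.character(intercept),
              terms = setNames(as.character(terms), names(terms)))
  } else {
    if (is.null(scale) || is.null(exponent))
      stop("allometric models need scale and exponent")
    m <- list(name = name, form = form, scale = as.character(scale),
              exponent = as.character(exponent))
  }
  structure(m, class = "bw_model")
}

#' @export
print.bw_model <- function(x, ...) {
  if (x$form == "linear") {
    rhs <- paste(sprintf("%s x %s", x$terms, names(x$terms)), collapse = " + ")
    iv <- as.numeric(x$intercept)
    cat(sprintf("%s: BW = %s %s %s kg\n", x$name, rhs,
                if (iv < 0) "-" else "+", abs(iv)))
  } else {
    cat(sprintf("%s: BSA = %s x BW^%s (inverted for BW)\n", x$name, x$scale,
                x$exponent))
  }
  invisible(x)
}

#' @export
coef.bw_model <- function(object, ...) {
  if (object$form == "linear")
    c("(Intercept)" = as.numeric(object$intercept),
      setNames(as.numeric(object$terms), names(object$terms)))
  else
    c(scale = as.numeric(object$scale), exponent = as.numeric(object$exponent))
}

#' The eight published prediction equations
#'
#' Returns the built-in equations with coefficients exactly as printed:
#' the two Elting allometric surface-area laws (adult cows and growing
#' heifers), the three adult-cow equations relating body weight to surface
#' area, to the full trait set, and to volume alone, and the three
#' equations refitted on growing heifers (surface area; volume and hip
#' width; volume alone).
#'
#' @return named list of [bw_model()] objects (`eq1` ... `eq8`).
#' @export
builtin_models <- function() {
  list(
    eq1 = bw_model("eq1", "allometric", scale = "0.0839", exponent = "0.67"),
    eq2 = bw_model("eq2", "allometric", scale = "0.147", exponent = "0.56"),
    eq3 = bw_model("eq3", "linear", intercept = "-30.3",
                   terms = c(bsa = "102.3")),
    eq4 = bw_model("eq4", "linear", intercept = "-280.7",
                   terms = c(volume = "812.1", bsa = "-81.4", kw = "343.8",
                             hw = "273.8", hg = "208.8", wh = "113.7")),
    eq5 = bw_model("eq5", "linear", intercept = "45.8",
                   terms = c(volume = "827.5")),
    eq6 = bw_model("eq6", "linear", intercept = "-259.3",
                   terms = c(bsa = "118.2")),
    eq7 = bw_model("eq7", "linear", intercept = "-91.3",
                   terms = c(volume = "728.8", hw = "-0.36")),
    eq8 = bw_model("eq8", "linear", intercept = "-34.4",
                   terms = c(volume = "922.3")))
}

#' Elting allometric body surface area
#'
#' `BSA = 0.0839 BW^0.67` for adult cows, `BSA = 0.147 BW^0.56` for
#' growing heifers; `bw_from_bsa_elting()` is the exact inversion
#' `BW = (BSA / scale)^(1 / exponent)`.
#'
#' @param bw body weight in kg (> 0).
#' @param bsa body surface area in m^2 (> 0).
#' @param population `"adult"` or `"heifer"`.
#' @return surface area in m^2, or body weight in kg.
#' @export
elting_bsa <- function(bw, population = c("adult", "heifer")) {
  population <- match.arg(population)
  if (any(bw <= 0)) stop("bw must be positive")
  m <- builtin_models()[[if (population == "adult") "eq1" else "eq2"]]
  as.numeric(m$scale) * bw^as.numeric(m$exponent)
}

#' @rdname elting_bsa
#' @export
bw_from_bsa_elting <- function(bsa, population = c("adult", "heifer")) {
  population <- match.arg(population)
  if (any(bsa <= 0)) stop("bsa must be positive")
  m <- builtin_models()[[if (population == "adult") "eq1" else "eq2"]]
  (bsa / as.numeric(m$scale))^(1 / as.numeric(m$exponent))
}

#' Predict body weight from a trait record
#'
#' @param model a [bw_model()].
#' @param record named list or one-row data.frame supplying every
#'   predictor the model names (SI units: volume m^3, bsa m^2, traits m).
#'   A missing or non-finite predictor is an error, never a silent zero.
#' @return predicted body weight in kg.
#' @export
predict_bw <- function(model, record) {
  if (model$form == "allometric") {
    v <- record[["bsa"]]
    if (is.null(v) || !all(is.finite(v))) stop("record lacks a finite bsa")
    return((v / as.numeric(model$scale))^(1 / as.numeric(model$exponent)))
  }
  out <- as.numeric(model$intercept)
  for (p in names(model$terms)) {
    v <- record[[p]]
    if (is.null(v) || !all(is.finite(v)))
      stop(sprintf("record lacks a finite predictor '%s'", p))
    out <- out + as.numeric(model$terms[[p]]) * v
  }
  out
}

#' Serialize prediction models to a text file
#'
#' Plain key/value text; coefficients are written as their stored decimal
#' strings, so write/read round-trips are exact.
#'
#' @param models list of [bw_model()] objects.
#' @param path file path.
#' @return `read_models()` returns a named list of `bw_model`s.
#' @export
write_models <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    lines <- c(lines, paste0("model: ", m$name), paste0("form: ", m$form))
    if (m$form == "linear") {
      lines <- c(lines, paste0("intercept: ", m$intercept),
                 sprintf("term: %s %s", names(m$terms), m$terms))
    } else {
      lines <- c(lines, paste0("scale: ", m$scale),
                 paste0("exponent: ", m$exponent))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (cur$form == "linear")
      bw_model(cur$name, "linear", intercept = cur$intercept,
               terms = setNames(cur$coefs, cur$preds))
    else
      bw_model(cur$name, "allometric", scale = cur$scale,
               exponent = cur$exponent)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    key <- kv[1]
    val <- kv[2]
    if (key == "model") {
      m <- flush(cur)
      if (!is.null(m)) models[[m$name]] <- m
      cur <- list(name = val, preds = character(0), coefs = character(0))
    } else if (key == "term") {
      parts <- strsplit(val, "\\s+")[[1]]
      cur$preds <- c(cur$preds, parts[1])
      cur$coefs <- c(cur$coefs, parts[2])
    } else cur[[key]] <- val
  }
  m <- flush(cur)
  if (!is.null(m)) models[[m$name]] <- m
  models
}

#' Refit a body-weight prediction equation
#'
#' Ordinary least squares of recorded body weight on trait predictors,
#' optionally forced through the origin (in which case R^2 uses the
#' uncentered convention, about zero), with optional backward elimination:
#' while any predictor has a t-test p-value above `prune_alpha`, the least
#' significant one is dropped and the model refitted.
#'
#' @param records data.frame with one row per observation, a `bw` column
#'   (kg) and one column per candidate predictor (SI units).  Quality
#'   gating is the caller's responsibility.
#' @param predictors character vector of predictor column names.
#' @param through_origin force the intercept to zero.
#' @param prune_alpha significance level for backward elimination; 0
#'   disables pruning.
#' @return an object of class `bw_fit`: `model` (a [bw_model()] with the
#'   fitted coefficients), `r2`, `rmse` (kg), `n`, `p_values`,
#'   `through_origin`, `dropped` (in elimination order) and the underlying
#'   `lm` fit.
#' @export
fit_weight_model <- function(records, predictors, through_origin = FALSE,
                             prune_alpha = 0) {
  records <- as.data.frame(records)
  miss <- setdiff(c("bw", predictors), names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  dat <- records[, c("bw", predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1)
    stop("need more observations than predictors")
  dropped <- character(0)
  keep <- predictors
  repeat {
    fml <- stats::as.formula(paste(
      "bw ~", if (through_origin) "0 + " else "", paste(keep, collapse = " + ")))
    fit <- lm(fml, data = dat)
    if (fit$rank < length(keep) + !through_origin) {
      alias <- names(coef(fit))[is.na(coef(fit))]
      stop("rank-deficient design; collinear predictors: ",
           paste(alias, collapse = ", "))
    }
    sm <- summary(fit)
    pv <- sm$coefficients[, 4]
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    if (prune_alpha <= 0 || all(pv <= prune_alpha) || length(keep) == 1) break
    worst <- names(pv)[which.max(pv)]
    if (max(pv) <= prune_alpha) break
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  cf <- coef(fit)
  model <- bw_model("refit", "linear",
                    intercept = if (through_origin) "0"
                                else as.character(cf[["(Intercept)"]]),
                    terms = setNames(as.character(cf[keep]), keep))
  structure(list(model = model, r2 = sm$r.squared,
                 rmse = sqrt(mean(resid(fit)^2)), n = nrow(dat),
                 p_values = pv, through_origin = through_origin,
                 dropped = dropped, fit = fit),
            class = "bw_fit")
}

#' @export
print.bw_fit <- function(x, ...) {
  cat(sprintf("bw_fit (n = %d%s): R^2 = %.3f, RMSE = %.1f kg\n", x$n,
              if (x$through_origin) ", through origin" else "", x$r2, x$rmse))
  print(x$model)
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bw_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.bw_fit <- function(object, ...) coef(object$model)

#' @export
predict.bw_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$fit))
  vapply(seq_len(nrow(newdata)),
         function(i) predict_bw(object$model, newdata[i, , drop = FALSE]), 0)
}

#' @export
residuals.bw_fit <- function(object, ...) resid(object$fit)

#' Compare measured and estimated body weights
#'
#' Per-pair percent difference is `100 (est - meas) / meas`; the summary
#' mean is the arithmetic mean of the pair percentages.  When ages are
#' supplied the percentages are also averaged per age group.
#'
#' @param measured,estimated equal-length vectors of body weight (kg);
#'   measured values must be positive.
#' @param ages optional grouping vector (e.g. age in months).
#' @return list with `mean_pct`, `bias` (kg), `rmse` (kg), `pct`
#'   (per-pair), and `by_age` (data.frame) when ages are given.
#' @export
compare_estimates <- function(measured, estimated, ages = NULL) {
  if (length(measured) != length(estimated)) stop("length mismatch")
  if (!length(measured)) stop("need at least one pair")
  if (any(measured <= 0)) stop("measured weights must be positive")
  pct <- 100 * (estimated - measured) / measured
  out <- list(mean_pct = mean(pct), bias = mean(estimated - measured),
              rmse = sqrt(mean((estimated - measured)^2)), pct = pct)
  if (!is.null(ages)) {
    ag <- split(pct, ages)
    out$by_age <- data.frame(age = names(ag),
                             mean_pct = vapply(ag, mean, 0),
                             n = lengths(ag), row.names = NULL)
  }
  out
}
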