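#' Growth-curve parameters for a synthetic heifer population
#'
#' Body weight follows a monomolecular (Brody) curve
#' `BW(t) = A - (A - BW0) exp(-k t)`; each linear trait and the body
#' surface area follow an allometric link `trait = a BW^b`; volume is
#' `BW / density` with a constant body density.  Defaults are calibrated
#' to the stage means of the study population (birth weight 40 kg, mature
#' weight 680 kg, rate 0.0019 per day, allometries fitted on the stage
#' table of [heifer_stage_table()]).
#'
#' @param birth_bw birth body weight (kg).
#' @param asymptote_bw mature body weight A (kg), must exceed `birth_bw`.
#' @param rate growth rate k (1/day).
#' @param trait_allometries named list of `c(a, b)` pairs (trait = a BW^b,
#'   SI units) for hg, wh, cd, hw, kw (m) and bsa (m^2).
#' @param noise_sd named vector of per-visit measurement noise (same units
#'   as the trait; `bw` is the weighing-scale noise in kg).
#' @param density body density (kg/m^3) linking volume to body weight.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(birth_bw = 40, asymptote_bw = 680, rate = 0.00191,
                          trait_allometries = list(
                            hg = c(0.22542, 0.3570),
                            wh = c(0.28980, 0.2581),
                            cd = c(0.09026, 0.3477),
                            hw = c(0.02950, 0.4830),
                            kw = c(0.02363, 0.4830),
                            bsa = c(0.37590, 0.4484)),
                          noise_sd = c(hg = 0.012, wh = 0.008, cd = 0.006,
                                       hw = 0.005, kw = 0.005, bsa = 0.06,
                                       volume = 0.008, bw = 4),
                          density = 900) {
  if (birth_bw <= 0 || asymptote_bw <= birth_bw || rate <= 0)
    stop("require birth_bw > 0, asymptote_bw > birth_bw, rate > 0")
  if (any(vapply(trait_allometries, `[`, 0, 1) <= 0))
    stop("allometric coefficients must be positive")
  structure(list(birth_bw = birth_bw, asymptote_bw = asymptote_bw,
                 rate = rate, trait_allometries = trait_allometries,
                 noise_sd = noise_sd, density = density),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("growth_params: BW %.0f -> %.0f kg, k = %.5f /d, density %.0f kg/m^3\n",
              x$birth_bw, x$asymptote_bw, x$rate, x$density))
  invisible(x)
}

#' Expected body state at a given age
#'
#' Evaluates the growth curve and the allometric trait links, returning
#' the noise-free ground truth for one animal-visit.
#'
#' @param params a [growth_params()] object.
#' @param age age in days (>= 0).
#' @return list with `bw` (kg), `volume` (m^3), `bsa` (m^2) and the
#'   linear traits `hg`, `wh`, `cd`, `hw`, `kw` (m).
#' @export
growth_state_at_age <- function(params, age) {
  if (any(age < 0)) stop("age must be non-negative")
  A <- params$asymptote_bw
  bw <- A - (A - params$birth_bw) * exp(-params$rate * age)
  out <- list(bw = bw, volume = bw / params$density)
  for (tr in names(params$trait_allometries)) {
    ab <- params$trait_allometries[[tr]]
    out[[tr]] <- ab[1] * bw^ab[2]
  }
  out
}

# between-animal BW standard deviation at an age implied by parameter
# scatter (delta method on the Brody curve)
herd_bw_sd <- function(params, age, cv = c(asymptote = 0.08, rate = 0.05)) {
  A <- params$asymptote_bw
  k <- params$rate
  dA <- 1 - exp(-k * age)                       # dBW/dA
  dk <- (A - params$birth_bw) * age * exp(-k * age) # dBW/dk
  sqrt((dA * cv[["asymptote"]] * A)^2 + (dk * cv[["rate"]] * k)^2)
}

#' Simulate a longitudinal herd
#'
#' Draws per-animal deviations of the growth parameters (log-normal on the
#' asymptote and rate), evaluates the growth state at each visit age, and
#' adds per-visit measurement noise.  Weighing records carry independent
#' scale noise.  Per-animal seeds are derived as `seed + animal index`, so
#' the simulation is reproducible given the seed.
#'
#' @param growth a [growth_params()] object.
#' @param n_animals number of animals (>= 1).
#' @param visit_ages sorted vector of imaging-visit ages (days).
#' @param seed integer seed.
#' @param cv between-animal coefficients of variation of the asymptote and
#'   rate (0 for a deterministic herd).
#' @param weigh_ages scale-visit ages; defaults to `visit_ages`.
#' @return list with `traits` (one row per animal-visit: trait record
#'   columns as in [measure_all()]) and `weights` (animal_id, age, bw,
#'   interpolated).
#' @export
simulate_herd <- function(growth, n_animals, visit_ages, seed = 1,
                          cv = c(asymptote = 0.08, rate = 0.05),
                          weigh_ages = visit_ages) {
  if (n_animals < 1) stop("n_animals must be at least 1")
  if (is.unsorted(visit_ages)) stop("visit_ages must be sorted ascending")
  ns <- growth$noise_sd
  traits <- list()
  weights <- list()
  for (i in seq_len(n_animals)) {
    id <- sprintf("H%03d", i)
    rec <- with_seed(seed + i, {
      gi <- growth
      gi$asymptote_bw <- growth$asymptote_bw *
        exp(rnorm(1, 0, cv[["asymptote"]]) - cv[["asymptote"]]^2 / 2)
      gi$rate <- growth$rate *
        exp(rnorm(1, 0, cv[["rate"]]) - cv[["rate"]]^2 / 2)
      st <- growth_state_at_age(gi, visit_ages)
      tr <- data.frame(animal_id = id, age = visit_ages,
                       hg = st$hg + rnorm(length(visit_ages), 0, ns[["hg"]]),
                       wh = st$wh + rnorm(length(visit_ages), 0, ns[["wh"]]),
                       cd = st$cd + rnorm(length(visit_ages), 0, ns[["cd"]]),
                       hw = st$hw + rnorm(length(visit_ages), 0, ns[["hw"]]),
                       kw = st$kw + rnorm(length(visit_ages), 0, ns[["kw"]]),
                       bsa = st$bsa + rnorm(length(visit_ages), 0, ns[["bsa"]]),
                       volume = st$volume +
                         rnorm(length(visit_ages), 0, ns[["volume"]]),
                       quality = 4L, stringsAsFactors = FALSE)
      stw <- growth_state_at_age(gi, weigh_ages)
      wt <- data.frame(animal_id = id, age = weigh_ages,
                       bw = stw$bw + rnorm(length(weigh_ages), 0, ns[["bw"]]),
                       interpolated = FALSE, stringsAsFactors = FALSE)
      list(tr = tr, wt = wt)
    })
    traits[[i]] <- rec$tr
    weights[[i]] <- rec$wt
  }
  list(traits = do.call(rbind, traits), weights = do.call(rbind, weights))
}
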