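# Synthetic scenario generator: multi-year seasonal forcing and noisy paired
# observation sets emulating a long-term grassland monitoring design, so the
# whole toolchain is exercisable without any external data download.

#' Scenario specification
#'
#' @param years Horizon (y); the daily grid covers `years * 365` days.
#' @param fplant_mean,fplant_amplitude Mean and seasonal amplitude of the
#'   plant-activity factor `fplant(t) = mean + amplitude *
#'   sin(2*pi*(t - phase)/365)`, clipped into `[0, 1]`.
#' @param fplant_phase Phase shift (d) placing peak activity in summer.
#' @param litter_rate Peak-scaled litter organic-N input: `L(t) =
#'   litter_rate * fplant(t)` (mg N kg^-1 d^-1), i.e. litter follows the
#'   growing season.
#' @param fert `"constant"` or `"pulsed"` mineral N additions.
#' @param fert_NH4,fert_NO3 Constant-regime input rates
#'   (mg N kg^-1 d^-1).
#' @param pulses_per_year,pulse_amount Pulsed regime: evenly spaced
#'   single-day spikes whose trapezoidal integral equals `pulse_amount`
#'   (mg N kg^-1) each, applied to both NH4 and NO3 channels.
#' @param biomass Constant microbial biomass (mg C kg^-1).
#' @param n_rep Observation replicates per time point.
#' @param cv Multiplicative lognormal coefficient of variation of the
#'   observation noise (mean-one noise).
#' @param seed Integer seed for the noise.
#' @return A `codeal_scenario` list.
#' @export
scenario_spec <- function(years = 12, fplant_mean = 0.5,
                          fplant_amplitude = 0.45, fplant_phase = 80,
                          litter_rate = 0.4,
                          fert = c("constant", "pulsed"),
                          fert_NH4 = 0.05, fert_NO3 = 0.05,
                          pulses_per_year = 4, pulse_amount = 1,
                          biomass = 200, n_rep = 24, cv = 0.2, seed = 42) {
  fert <- match.arg(fert)
  if (years <= 0 || cv < 0 || n_rep < 1)
    stop("need `years` > 0, `cv` >= 0, `n_rep` >= 1", call. = FALSE)
  structure(list(years = years, fplant_mean = fplant_mean,
                 fplant_amplitude = fplant_amplitude,
                 fplant_phase = fplant_phase, litter_rate = litter_rate,
                 fert = fert, fert_NH4 = fert_NH4, fert_NO3 = fert_NO3,
                 pulses_per_year = pulses_per_year,
                 pulse_amount = pulse_amount, biomass = biomass,
                 n_rep = n_rep, cv = cv, seed = seed),
            class = "codeal_scenario")
}

#' Generate daily forcing from a scenario
#'
#' Deterministic (no random elements): sinusoidal plant activity, litter
#' input proportional to plant activity, constant biomass, and constant or
#' pulsed mineral N inputs (a pulse is a one-day spike at days
#' `365/(pulses) * (k - 1/2)` of each year; under linear interpolation its
#' integral equals the spike height).
#'
#' @param spec A `codeal_scenario`.
#' @return A `codeal_forcing` on the daily grid `0 .. years*365`.
#' @export
make_forcing <- function(spec) {
  stopifnot(inherits(spec, "codeal_scenario"))
  t <- seq(0, round(spec$years * 365))
  fplant <- spec$fplant_mean + spec$fplant_amplitude *
    sin(2 * pi * (t - spec$fplant_phase) / 365)
  fplant <- pmin(pmax(fplant, 0), 1)
  L <- spec$litter_rate * fplant
  if (spec$fert == "constant") {
    I_NH4 <- rep(spec$fert_NH4, length(t))
    I_NO3 <- rep(spec$fert_NO3, length(t))
  } else {
    I_NH4 <- numeric(length(t))
    gap <- 365 / spec$pulses_per_year
    pulse_days <- round(as.vector(outer(
      (seq_len(spec$pulses_per_year) - 0.5) * gap,
      365 * (seq_len(ceiling(spec$years)) - 1), `+`)))
    pulse_days <- pulse_days[pulse_days > t[1] & pulse_days < t[length(t)]]
    I_NH4[t %in% pulse_days] <- spec$pulse_amount
    I_NO3 <- I_NH4
  }
  forcing_series(t, B = rep(spec$biomass, length(t)), I_NH4 = I_NH4,
                 I_NO3 = I_NO3, L = L, fplant = fplant)
}

#' Generate noisy replicate observations
#'
#' Runs the noise-free model, samples the six observables
#' (see [sim_observables()]) on a monthly grid (every 30 d), and applies
#' independent mean-one multiplicative lognormal noise per observable,
#' replicate and time point: multiplier `exp(z - sdlog^2/2)`,
#' `z ~ N(0, sdlog^2)`, `sdlog^2 = log(1 + cv^2)`.
#'
#' @param spec A `codeal_scenario` (supplies `n_rep`, `cv`, `seed`).
#' @param params,config,forcing Model setup for the noise-free backbone.
#' @return A `codeal_observations` data frame with columns `observable`,
#'   `time`, `value`, `replicate`; attribute `truth` holds the noise-free
#'   sampled series.
#' @export
make_observations <- function(spec, params, config, forcing) {
  stopifnot(inherits(spec, "codeal_scenario"))
  traj <- run_simulation(config, params, forcing)
  so <- sim_observables(traj)
  grid <- seq(config$t0 + 30, config$t1, by = 30)
  truth <- do.call(rbind, lapply(OBSERVABLES, function(v) {
    data.frame(observable = v, time = grid,
               value = stats::approx(so$time, so[[v]], xout = grid)$y)
  }))
  sdlog <- sqrt(log(1 + spec$cv^2))
  obs <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$n_rep), function(r) {
      mult <- if (spec$cv > 0)
        exp(stats::rnorm(nrow(truth), 0, sdlog) - sdlog^2 / 2)
      else rep(1, nrow(truth))
      data.frame(observable = truth$observable, time = truth$time,
                 value = truth$value * mult, replicate = r)
    }))
  })
  structure(obs, truth = truth,
            class = c("codeal_observations", "data.frame"))
}

#' Read / write observation CSV (`observable,time,value,replicate`)
#'
#' @param path File path.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path)
  need <- c("observable", "time", "value", "replicate")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("observation CSV misses: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(d[need], class = c("codeal_observations", "data.frame"))
}

#' @rdname read_observations
#' @param obs A `codeal_observations` data frame.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs)[c("observable", "time", "value",
                                        "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' The canonical synthetic testbed
#'
#' The package's frozen reference setup: a 12-year seasonal grassland-like
#' scenario with 24 observation replicates, the default kinetic parameters
#' of [kinetic_params()] (chosen for realistic magnitudes and heterogeneous
#' substrate saturation levels, NOT a fitted set), and a matching
#' simulation configuration (daily output, adaptive solver, boundary-mode
#' dinitrogen held at 20 mg N kg^-1). All scenario-level comparisons in the
#' package documentation and tests refer to this fixture.
#'
#' @return List with elements `spec` (`codeal_scenario`), `params`
#'   (`codeal_params`) and `config` (`codeal_config`).
#' @examples
#' sc <- default_scenario()
#' frc <- make_forcing(sc$spec)
#' @export
default_scenario <- function() {
  spec <- scenario_spec()          # 12 y, n_rep 24, cv 0.2, seed 42
  params <- kinetic_params()
  config <- simulation_config(t0 = 0, t1 = round(spec$years * 365),
                              dt_out = 1, scheme = "A1",
                              state0 = initial_state())
  list(spec = spec, params = params, config = config)
}
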