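# Parameter calibration against observed pools and fluxes: a composite
# percent-bias / Nash-Sutcliffe objective and a bounded, seeded
# differential-evolution search.

#' Calibration specification
#'
#' @param free Named list of absolute `c(low, high)` bounds for the free
#'   parameters; names as in [default_ranges()] (`"Vmax_NO3"`, `"pEP"`,
#'   ...). Zero-width bounds (`low == high`) pin a parameter.
#' @param weights Named nonnegative weights per observable (defaults to 1
#'   for every observable present in the data).
#' @param budget Total objective evaluations (>= population size).
#' @param pop_size Population size (default 10).
#' @param seed Integer seed.
#' @return A `codeal_calibspec` list.
#' @export
calibration_spec <- function(free, weights = NULL, budget = 200,
                             pop_size = 10, seed = 1) {
  if (!length(free) || is.null(names(free)))
    stop("`free` must be a named list of bounds", call. = FALSE)
  ok <- vapply(free, function(b) length(b) == 2L && all(is.finite(b)) &&
                 b[1] <= b[2], logical(1))
  if (!all(ok)) stop("invalid bounds for: ",
                     paste(names(free)[!ok], collapse = ", "),
                     call. = FALSE)
  if (!is.null(weights) && (any(weights < 0) || all(weights == 0)))
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  if (budget < pop_size)
    stop("`budget` must be at least the population size", call. = FALSE)
  structure(list(free = free, weights = weights, budget = budget,
                 pop_size = pop_size, seed = seed),
            class = "codeal_calibspec")
}

#' Composite calibration objective
#'
#' For each observable `k` present in the observations, the simulated
#' series is linearly interpolated to the observation times (replicates
#' averaged per time point; NO3 and NO2 pools are summed before comparison
#' to the combined observed pool) and scored as
#' `0.5 * min(|PBIAS_k|/100, 1) + 0.5 * (1 - max(NSE_k, -1)) / 2`,
#' a value in `[0, 1]` that is 0 only for a perfect fit. The objective is
#' the weighted sum over observables.
#'
#' @param params A `codeal_params`.
#' @param config,forcing Simulation setup.
#' @param obs A `codeal_observations` data frame (columns `observable`,
#'   `time`, `value`, `replicate`).
#' @param weights Named weights per observable (default 1 each).
#' @return Nonnegative scalar `J`.
#' @export
objective <- function(params, config, forcing, obs, weights = NULL) {
  traj <- run_simulation(config, params, forcing)
  so <- sim_observables(traj)
  present <- intersect(OBSERVABLES, unique(obs$observable))
  if (!length(present)) stop("no known observables in `obs`", call. = FALSE)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(present)), present)
  J <- 0
  for (v in present) {
    ob <- obs[obs$observable == v, ]
    om <- tapply(ob$value, ob$time, mean)
    tt <- as.numeric(names(om))
    if (!(v %in% names(so)))
      stop("observable missing from trajectory: ", v, call. = FALSE)
    sm <- stats::approx(so$time, so[[v]], xout = tt)$y
    if (anyNA(sm))
      stop("observation times outside the simulated span for ", v,
           call. = FALSE)
    pb <- percent_bias(sm, as.numeric(om))
    ns <- nse(sm, as.numeric(om))
    w <- if (v %in% names(weights)) weights[[v]] else 0
    J <- J + w * (0.5 * min(abs(pb) / 100, 1) +
                    0.5 * (1 - max(ns, -1)) / 2)
  }
  J
}

#' Calibrate free parameters by bounded differential evolution
#'
#' Seeded rand/1/bin differential evolution inside the stated bounds:
#' the population is initialized by Latin-hypercube sampling, candidates
#' are built by recombining current members (mutation factor 0.8,
#' crossover 0.9, reflection at the bounds) and replace their parent only
#' when they improve the objective. Deterministic given the seed; the
#' evaluation budget is fixed up-front.
#'
#' @param spec A `codeal_calibspec`.
#' @param config,forcing Simulation setup.
#' @param obs Observations (see [objective()]).
#' @param base A `codeal_params` supplying every non-free parameter
#'   (default [kinetic_params()]).
#' @return List with `params` (best-found `codeal_params`), `values`
#'   (named numeric best free-parameter values), `J` (best objective) and
#'   `trace` (best `J` after each generation, nonincreasing).
#' @export
calibrate <- function(spec, config, forcing, obs, base = kinetic_params()) {
  stopifnot(inherits(spec, "codeal_calibspec"),
            inherits(base, "codeal_params"))
  nm <- names(spec$free)
  lo <- vapply(spec$free, `[`, numeric(1), 1)
  hi <- vapply(spec$free, `[`, numeric(1), 2)
  d <- length(nm)
  fixed <- hi == lo
  make_params <- function(x) {
    p <- base
    for (i in seq_len(d)) p <- set_param(p, nm[i], x[i])
    p
  }
  evalJ <- function(x) objective(make_params(x), config, forcing, obs,
                                 spec$weights)
  if (all(fixed)) {
    x <- lo
    return(list(params = make_params(x), values = stats::setNames(x, nm),
                J = evalJ(x), trace = evalJ(x)))
  }
  np <- spec$pop_size
  with_seed(spec$seed, {
    u <- lhs::randomLHS(np, d)
    pop <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    pop[, fixed] <- matrix(rep(lo[fixed], each = np), nrow = np)
    fit <- apply(pop, 1, evalJ)
    used <- np
    trace <- min(fit)
    Fm <- 0.8; CR <- 0.9
    while (used + np <= spec$budget) {
      for (i in seq_len(np)) {
        idx <- sample(setdiff(seq_len(np), i), 3)
        v <- pop[idx[1], ] + Fm * (pop[idx[2], ] - pop[idx[3], ])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        x <- ifelse(cross, v, pop[i, ])
        # reflect at the bounds, then clamp any double overshoot
        below <- x < lo; x[below] <- (2 * lo - x)[below]
        above <- x > hi; x[above] <- (2 * hi - x)[above]
        x <- pmin(pmax(x, lo), hi)
        x[fixed] <- lo[fixed]
        Jx <- evalJ(x)
        if (Jx <= fit[i]) { pop[i, ] <- x; fit[i] <- Jx }
      }
      used <- used + np
      trace <- c(trace, min(fit))
    }
    best <- which.min(fit)
    list(params = make_params(pop[best, ]),
         values = stats::setNames(pop[best, ], nm),
         J = fit[best], trace = trace)
  })
}
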