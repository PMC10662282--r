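# ODE integration of the nitrogen-enzyme system via deSolve, with a
# mass-balance audit (cumIn/cumOut accumulators integrated alongside the
# pools) and a nonnegativity policy: consuming fluxes vanish with their pool
# inside the right-hand side, so the exact dynamics cannot cross zero;
# residual integrator undershoot below -`neg_tol` is treated as solver
# failure, smaller undershoot is reported as zero.
#
# The integrator uses a lean closure over pre-extracted parameters and a
# single piecewise-linear forcing interpolation; it is algebraically
# identical to the documented reference right-hand side codeal_rhs() (the
# test suite pins the two together at randomized states).

# Fast derivative closure used inside the solver loop.
make_deriv_fn <- function(params, forcing, scheme) {
  tt <- forcing$time
  vals <- cbind(forcing$B, forcing$I_NH4, forcing$I_NO3, forcing$L,
                forcing$fplant)
  nT <- length(tt)
  Vmax <- params$Vmax; Ks <- params$Ks
  pEP <- params$pEP; rE <- params$rE; kmin <- params$kmin
  Vup1 <- params$Vup_NH4; Vup2 <- params$Vup_NO3
  Kup1 <- params$Kup_NH4; Kup2 <- params$Kup_NO3
  gNO <- params$gNO; gN2O <- params$gN2O
  dynamic <- params$dynamic_n2
  N2b <- if (dynamic) NA_real_ else params$N2_boundary
  inhib <- params$bnf_inhibition
  flr <- params$alloc_floor
  builtin <- scheme %in% c("A0", "A1", "A2")
  wfn <- if (!builtin) get(scheme, envir = .scheme_registry) else NULL
  function(t, y, p) {
    if (t < tt[1]) t <- tt[1] else if (t > tt[nT]) t <- tt[nT]
    i <- findInterval(t, tt, rightmost.closed = TRUE)
    if (i >= nT) i <- nT - 1L
    wt <- (t - tt[i]) / (tt[i + 1L] - tt[i])
    fr <- vals[i, ] + wt * (vals[i + 1L, ] - vals[i, ])
    N <- y[1:6]; N[N < 0] <- 0
    if (!dynamic) N[6] <- N2b
    E <- y[7:12]; E[E < 0] <- 0
    ON <- if (y[13] > 0) y[13] else 0
    sat <- N / (Ks + N)
    Fe <- Vmax * E * sat
    if (inhib) Fe[6] <- Fe[6] * (1 - sat[1])
    Fmin <- kmin * ON
    U1 <- Vup1 * fr[5] * N[1] / (Kup1 + N[1])
    U2 <- Vup2 * fr[5] * N[2] / (Kup2 + N[2])
    GNO <- gNO * N[4]; GN2O <- gN2O * N[5]
    Nf <- N; Nf[Nf < flr] <- flr
    w <- if (builtin) {
      if (scheme == "A0") Nf else if (scheme == "A1") Nf / Ks else Ks / Nf
    } else wfn(Nf, Ks)
    f <- w / sum(w)
    list(c(Fmin + Fe[6] - Fe[1] - U1 + fr[2],
           Fe[1] - Fe[2] - U2 + fr[3],
           Fe[2] - Fe[3],
           Fe[3] - Fe[4] - GNO,
           Fe[4] - Fe[5] - GN2O,
           if (dynamic) Fe[5] - Fe[6] else 0,
           f * pEP * fr[1] - rE * E,
           fr[4] - Fmin,
           fr[2] + fr[3] + fr[4] + (if (dynamic) 0 else Fe[6]),
           U1 + U2 + GNO + GN2O + (if (dynamic) 0 else Fe[5])))
  }
}

# Vectorized re-evaluation of allocation coefficients and instantaneous
# fluxes at the output times (matrix arithmetic over all rows at once).
trajectory_diagnostics <- function(times, state, params, forcing, scheme) {
  N <- state[, 1:6, drop = FALSE]
  E <- pmax(state[, 7:12, drop = FALSE], 0)
  ON <- pmax(state[, 13], 0)
  fp <- attr(forcing, "interp")$fplant(times)
  B <- attr(forcing, "interp")$B(times)
  Ks <- rep(params$Ks, each = nrow(N))
  sat <- N / (Ks + N)
  Fe <- rep(params$Vmax, each = nrow(N)) * E * sat
  if (params$bnf_inhibition) Fe[, 6] <- Fe[, 6] * (1 - sat[, 1])
  Nf <- pmax(N, params$alloc_floor)
  w <- switch(scheme, A0 = Nf, A1 = Nf / Ks, A2 = Ks / Nf,
              t(apply(Nf, 1, get(scheme, envir = .scheme_registry),
                      Ks = params$Ks)))
  alloc <- w / rowSums(w)
  colnames(alloc) <- paste0("f_", ENZYME_GROUPS)
  flux <- cbind(
    F_nit = Fe[, 1], F_nar = Fe[, 2], F_nir = Fe[, 3], F_nor = Fe[, 4],
    F_nos = Fe[, 5], F_fix = Fe[, 6],
    F_min = params$kmin * ON,
    U_NH4 = params$Vup_NH4 * fp * N[, 1] / (params$Kup_NH4 + N[, 1]),
    U_NO3 = params$Vup_NO3 * fp * N[, 2] / (params$Kup_NO3 + N[, 2]),
    G_NO = params$gNO * N[, 4],
    G_N2O = params$gN2O * N[, 5])
  list(alloc = alloc, flux = flux)
}

#' Simulation configuration
#'
#' @param t0,t1 Simulation span (d), `t1 > t0`.
#' @param dt_out Output grid step (d); decoupled from the solver's internal
#'   steps (adaptive dense output / fixed-step subsampling).
#' @param scheme Allocation scheme identifier (default `"A1"`).
#' @param state0 Initial state from [initial_state()].
#' @param solver `"adaptive"` (lsoda) or `"rk4"` (fixed step).
#' @param rtol,atol Adaptive solver tolerances.
#' @param rk4_step Fixed step (d) for the RK4 solver; `dt_out` must be an
#'   integer multiple of it.
#' @param neg_tol Nonnegativity policy: output states in `(-neg_tol, 0)`
#'   are reported as 0; anything below `-neg_tol` raises an error.
#' @return A `codeal_config` list.
#' @export
simulation_config <- function(t0 = 0, t1 = 365, dt_out = 1,
                              scheme = "A1", state0 = initial_state(),
                              solver = c("adaptive", "rk4"),
                              rtol = 1e-8, atol = 1e-10,
                              rk4_step = 0.25, neg_tol = 1e-6) {
  solver <- match.arg(solver)
  if (!(t1 > t0)) stop("`t1` must exceed `t0`", call. = FALSE)
  if (dt_out <= 0 || rtol <= 0 || atol <= 0 || rk4_step <= 0)
    stop("`dt_out`, tolerances and `rk4_step` must be positive",
         call. = FALSE)
  if (solver == "rk4" &&
      abs(dt_out / rk4_step - round(dt_out / rk4_step)) > 1e-9)
    stop("`dt_out` must be an integer multiple of `rk4_step`",
         call. = FALSE)
  structure(list(t0 = t0, t1 = t1, dt_out = dt_out, scheme = scheme,
                 state0 = state0, solver = solver, rtol = rtol,
                 atol = atol, rk4_step = rk4_step, neg_tol = neg_tol),
            class = "codeal_config")
}

#' Run one simulation
#'
#' Integrates [codeal_rhs()] over `[t0, t1]` and samples states on the
#' output grid; allocation coefficients and instantaneous fluxes are
#' re-evaluated exactly at the output times. In boundary-N2 mode the N2
#' column is held at the boundary concentration.
#'
#' @param config A `codeal_config` (see [simulation_config()]).
#' @param params A `codeal_params` (see [kinetic_params()]).
#' @param forcing A `codeal_forcing` spanning `[t0, t1]`.
#' @return A `codeal_trajectory`: list with `times`, `state` (matrix, one
#'   row per output time, columns the 15 states), `alloc` (6 columns),
#'   `flux` (11 columns), and metadata (`scheme`, `params`, `config`).
#' @examples
#' sc <- default_scenario()
#' frc <- make_forcing(scenario_spec(years = 1))
#' traj <- run_simulation(simulation_config(t1 = 365, scheme = "A1",
#'                                          state0 = initial_state()),
#'                        sc$params, frc)
#' summary(as.data.frame(traj)$NH4)
#' @export
run_simulation <- function(config, params, forcing) {
  stopifnot(inherits(config, "codeal_config"),
            inherits(params, "codeal_params"),
            inherits(forcing, "codeal_forcing"))
  span <- range(forcing$time)
  if (config$t0 < span[1] || config$t1 > span[2])
    stop(sprintf("forcing [%g, %g] does not span simulation [%g, %g]",
                 span[1], span[2], config$t0, config$t1), call. = FALSE)
  y0 <- config$state0
  if (!params$dynamic_n2) y0[6] <- params$N2_boundary
  times <- seq(config$t0, config$t1, by = config$dt_out)
  if (times[length(times)] < config$t1) times <- c(times, config$t1)
  builtin <- config$scheme %in% c("A0", "A1", "A2")
  if (builtin) {
    # compiled right-hand side (src/codeal_rhs.c); forcings linearly
    # interpolated by deSolve, matching forcing_at()
    parms <- c(params$Vmax, params$Ks, params$pEP, params$rE, params$kmin,
               params$Vup_NH4, params$Vup_NO3, params$Kup_NH4,
               params$Kup_NO3, params$gNO, params$gN2O,
               if (params$dynamic_n2) 0 else params$N2_boundary,
               as.numeric(params$dynamic_n2),
               as.numeric(params$bnf_inhibition), params$alloc_floor,
               match(config$scheme, c("A0", "A1", "A2")) - 1)
    forcmat <- lapply(c("B", "I_NH4", "I_NO3", "L", "fplant"),
                      function(v) cbind(forcing$time, forcing[[v]]))
  } else {
    deriv_fn <- make_deriv_fn(params, forcing, config$scheme)
  }
  ode_args <- if (builtin) {
    list(y = y0, func = "codeal_derivs", parms = parms,
         dllname = "codeal", initfunc = "codeal_initmod",
         initforc = "codeal_initforc", forcings = forcmat)
  } else {
    list(y = y0, func = deriv_fn, parms = NULL)
  }
  sol <- if (config$solver == "adaptive") {
    do.call(deSolve::ode, c(ode_args, list(times = times, method = "lsoda",
                                           rtol = config$rtol,
                                           atol = config$atol)))
  } else {
    fine <- seq(config$t0, config$t1, by = config$rk4_step)
    if (fine[length(fine)] < config$t1) fine <- c(fine, config$t1)
    full <- do.call(deSolve::ode, c(ode_args, list(times = fine,
                                                   method = "rk4")))
    idx <- vapply(times, function(t) which.min(abs(fine - t)), integer(1))
    sub <- full[idx, , drop = FALSE]
    attr(sub, "istate") <- attr(full, "istate")
    sub
  }
  if (is.null(attr(sol, "istate"))) attr(sol, "istate") <- 0L
  if (attr(sol, "istate")[1] < 0 || anyNA(sol))
    stop("solver failure near t = ", max(sol[stats::complete.cases(sol), 1]),
         call. = FALSE)
  state <- unclass(sol)[, -1, drop = FALSE]
  colnames(state) <- STATE_NAMES
  low <- min(state)
  if (low < -config$neg_tol)
    stop(sprintf("state fell below zero (min %.3e) - solver failure", low),
         call. = FALSE)
  state[state < 0] <- 0
  if (!params$dynamic_n2) state[, 6] <- params$N2_boundary
  diag <- trajectory_diagnostics(times, state, params, forcing,
                                 config$scheme)
  structure(list(times = times, state = state, alloc = diag$alloc,
                 flux = diag$flux,
                 scheme = config$scheme, params = params, config = config),
            class = "codeal_trajectory")
}

#' @export
as.data.frame.codeal_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$state[, 1:6, drop = FALSE],
             ON = x$state[, "ON"], x$state[, 7:12, drop = FALSE],
             x$alloc, x$flux,
             cumIn = x$state[, "cumIn"], cumOut = x$state[, "cumOut"])
}

#' @export
print.codeal_trajectory <- function(x, ...) {
  cat(sprintf("<codeal_trajectory> scheme %s, %d output times on [%g, %g] d\n",
              x$scheme, length(x$times), x$times[1],
              x$times[length(x$times)]))
  cat("terminal pools (mg N kg^-1):\n")
  print(round(x$state[nrow(x$state), c(N_SPECIES, "ON")], 4))
  invisible(x)
}

#' Write a trajectory to CSV (plus a JSON metadata sidecar)
#'
#' @param traj A `codeal_trajectory`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(scheme = traj$scheme, solver = traj$config$solver,
               t0 = traj$config$t0, t1 = traj$config$t1,
               dt_out = traj$config$dt_out,
               params = traj$params[c("Vmax", "Ks", "pEP", "rE", "kmin")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Mass-balance audit of a trajectory
#'
#' Total tracked nitrogen (the six inorganic pools plus organic N; enzyme
#' pools are carbon and excluded) must satisfy
#' `totalN(t) - totalN(t0) = cumIn(t) - cumOut(t)` for the exact dynamics;
#' the residual measures integrator error.
#'
#' @param traj A `codeal_trajectory`.
#' @return Data frame with `time`, `totalN` and the audit `residual`.
#' @export
mass_balance <- function(traj) {
  totalN <- rowSums(traj$state[, c(N_SPECIES, "ON"), drop = FALSE])
  resid <- (totalN - totalN[1]) -
    (traj$state[, "cumIn"] - traj$state[, "cumOut"])
  data.frame(time = traj$times, totalN = totalN, residual = resid)
}
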