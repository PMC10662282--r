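# Independent oracles used across the suite.

# Exact signed-rank p-value by literal enumeration of all 2^m sign
# assignments (zero differences dropped, average ranks).
enum_signrank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Ws <- as.vector(signs %*% r)
  p_ge <- mean(Ws >= Wp)
  p_le <- mean(Ws <= Wp)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Implicit closed-form solution of single-substrate Michaelis-Menten
# depletion with constant enzyme: Ks*ln(N0/N) + (N0 - N) = Vmax*E*t.
mm_depletion_oracle <- function(t, N0, Vmax, E, Ks) {
  vapply(t, function(tt) {
    if (tt == 0) return(N0)
    stats::uniroot(function(N) Ks * log(N0 / N) + (N0 - N) - Vmax * E * tt,
                   lower = N0 * 1e-12, upper = N0, tol = 1e-14)$root
  }, numeric(1))
}

# Small shared simulation setup: `years`-long scenario with default params.
quick_setup <- function(years = 2, scheme = "A1", ...) {
  spec <- scenario_spec(years = years, ...)
  list(spec = spec,
       params = kinetic_params(),
       config = simulation_config(t0 = 0, t1 = round(years * 365),
                                  dt_out = 1, scheme = scheme),
       forcing = make_forcing(spec))
}

# Quiescent forcing: nothing enters, plants inactive.
dead_forcing <- function(t1 = 1000, B = 200) {
  forcing_series(c(0, t1), B = c(B, B), I_NH4 = c(0, 0), I_NO3 = c(0, 0),
                 L = c(0, 0), fplant = c(0, 0))
}

# Minimal hand-built trajectory for aggregation arithmetic.
fake_traj <- function(times, flux_total = NULL, alloc = NULL, pEP = 0.01) {
  n <- length(times)
  flux <- matrix(0, n, 11, dimnames = list(NULL, c(
    "F_nit", "F_nar", "F_nir", "F_nor", "F_nos", "F_fix", "F_min",
    "U_NH4", "U_NO3", "G_NO", "G_N2O")))
  if (!is.null(flux_total)) flux[, "F_nit"] <- flux_total
  if (is.null(alloc)) alloc <- matrix(1 / 6, n, 6)
  p <- kinetic_params(pEP = pEP)
  structure(list(times = times, flux = flux, alloc = alloc, params = p,
                 state = matrix(0, n, 15,
                                dimnames = list(NULL, codeal:::STATE_NAMES))),
            class = "codeal_trajectory")
}

const_forcing <- function(t1, B) {
  forcing_series(c(0, t1), B = c(B, B), I_NH4 = c(0, 0), I_NO3 = c(0, 0),
                 L = c(0, 0), fplant = c(0, 0))
}

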