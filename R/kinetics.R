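# Reduced nitrogen-enzyme subsystem: Michaelis-Menten transformation fluxes,
# ammonium inhibition of N fixation, enzyme-pool dynamics under competitive
# dynamic allocation, mineralization, plant uptake and boundary exchanges.
#
# Topology (one enzyme group per consumed substrate, substrate order):
#   amo: NH4 -> NO3 (nitrification, lumped; no explicit NO2 intermediate on
#        the oxidative side - NO2 arises only from nitrate reduction)
#   nar: NO3 -> NO2, nir: NO2 -> NO, nor: NO -> N2O, nos: N2O -> N2
#   nif: N2  -> NH4 (biological N fixation, inhibited by NH4 saturation)
# plus mineralization ON -> NH4, plant uptake of NH4/NO3, and first-order
# gaseous escape of NO and N2O.
#
# Units: days; pools mg N kg^-1 soil; enzyme pools mg enzyme-C kg^-1 soil
# (enzyme C is NOT part of the nitrogen balance); rates d^-1 or
# mg N (mg enzyme-C)^-1 d^-1.

#' Kinetic parameter set
#'
#' Constructs and validates the parameter list of the nitrogen-enzyme
#' model. Vector parameters follow the fixed substrate order [N_SPECIES].
#'
#' @param Vmax Six positive maximal specific rates
#'   (mg N (mg enzyme-C)^-1 d^-1) for amo, nar, nir, nor, nos, nif.
#' @param Ks Six positive half-saturation constants (mg N kg^-1).
#' @param pEP Enzyme production fraction (d^-1, biomass-specific): total
#'   gross enzyme synthesis is `pEP * B(t)`, split by the allocation
#'   coefficients.
#' @param rE First-order enzyme turnover rate (d^-1).
#' @param kmin First-order mineralization rate of organic N (d^-1).
#' @param Vup_NH4,Vup_NO3 Maximal plant uptake rates (mg N kg^-1 d^-1).
#' @param Kup_NH4,Kup_NO3 Uptake half-saturation constants (mg N kg^-1).
#' @param gNO,gN2O First-order gaseous efflux rates of NO and N2O (d^-1).
#' @param N2_boundary Either a fixed dinitrogen concentration
#'   (mg N kg^-1; the N2 pool is then held at this boundary value and
#'   fixation/reduction cross the system boundary) or the string
#'   `"dynamic"` to track N2 as a closed internal pool.
#' @param bnf_inhibition Logical; multiply the N-fixation flux by
#'   `1 - NH4/(NH4 + Ks_NH4)` (ammonium saturation inhibition).
#' @param alloc_floor Concentration floor passed to [compute_allocation()].
#' @return A validated list of class `codeal_params`.
#' @seealso [default_scenario()] for the packaged reference
#'   parameterization.
#' @export
kinetic_params <- function(Vmax = c(amo = 1.0, nar = 0.8, nir = 6.0,
                                    nor = 20.0, nos = 20.0, nif = 0.6),
                           Ks = c(NH4 = 1.0, NO3 = 10.0, NO2 = 0.3,
                                  NO = 0.05, N2O = 0.08, N2 = 2.0),
                           pEP = 0.005, rE = 0.05, kmin = 0.005,
                           Vup_NH4 = 0.3, Vup_NO3 = 0.4,
                           Kup_NH4 = 1.0, Kup_NO3 = 2.0,
                           gNO = 0.1, gN2O = 0.05,
                           N2_boundary = 20, bnf_inhibition = TRUE,
                           alloc_floor = 1e-10) {
  Vmax <- unname(as.numeric(Vmax)); Ks <- unname(as.numeric(Ks))
  if (length(Vmax) != 6L || anyNA(Vmax) || any(Vmax <= 0))
    stop("`Vmax` must be six positive rates", call. = FALSE)
  check_ks_vector(Ks)
  scalars <- c(pEP = pEP, rE = rE, kmin = kmin, Vup_NH4 = Vup_NH4,
               Vup_NO3 = Vup_NO3, Kup_NH4 = Kup_NH4, Kup_NO3 = Kup_NO3)
  if (anyNA(scalars) || any(scalars <= 0))
    stop("rate and half-saturation parameters must be positive",
         call. = FALSE)
  if (anyNA(c(gNO, gN2O)) || gNO < 0 || gN2O < 0)
    stop("gas efflux rates must be nonnegative", call. = FALSE)
  dynamic_n2 <- identical(N2_boundary, "dynamic")
  if (!dynamic_n2 &&
      (!is.numeric(N2_boundary) || length(N2_boundary) != 1L ||
       N2_boundary < 0))
    stop("`N2_boundary` must be \"dynamic\" or a nonnegative concentration",
         call. = FALSE)
  p <- list(Vmax = Vmax, Ks = Ks, pEP = pEP, rE = rE, kmin = kmin,
            Vup_NH4 = Vup_NH4, Vup_NO3 = Vup_NO3,
            Kup_NH4 = Kup_NH4, Kup_NO3 = Kup_NO3,
            gNO = gNO, gN2O = gN2O, N2_boundary = N2_boundary,
            dynamic_n2 = dynamic_n2,
            bnf_inhibition = isTRUE(bnf_inhibition),
            alloc_floor = alloc_floor)
  class(p) <- "codeal_params"
  p
}

#' Michaelis-Menten transformation flux
#'
#' Rate of one enzymatic transformation: `Vmax * E * N / (Ks + N)`
#' (mg N kg^-1 d^-1). Zero without enzyme or substrate and bounded above
#' by `Vmax * E`.
#'
#' @param E Enzyme pool (mg enzyme-C kg^-1), nonnegative.
#' @param Vmax Maximal specific rate (mg N (mg enzyme-C)^-1 d^-1).
#' @param N Substrate concentration (mg N kg^-1), nonnegative.
#' @param Ks Half-saturation constant (mg N kg^-1), positive.
#' @return Nonnegative flux(es); vectorized.
#' @export
transformation_flux <- function(E, Vmax, N, Ks) {
  if (anyNA(c(E, Vmax, N, Ks)) || any(E < 0) || any(N < 0))
    stop("`E` and `N` must be nonnegative", call. = FALSE)
  if (any(Vmax <= 0) || any(Ks <= 0))
    stop("`Vmax` and `Ks` must be positive", call. = FALSE)
  Vmax * E * N / (Ks + N)
}

#' Ammonium inhibition factor of biological N fixation
#'
#' Nitrogen fixation is down-regulated when mineral ammonium is already
#' available; the factor `1 - NH4/(NH4 + Ks_NH4)` (one minus the ammonium
#' saturation level) multiplies the fixation flux. It equals 1 without
#' ammonium and decreases strictly with NH4.
#'
#' @param NH4 Ammonium concentration (mg N kg^-1), nonnegative.
#' @param Ks_NH4 Ammonium half-saturation constant (mg N kg^-1), positive.
#' @return Factor in `(0, 1]`; vectorized.
#' @export
bnf_inhibition_factor <- function(NH4, Ks_NH4) {
  1 - saturation(NH4, Ks_NH4)
}

#' Enzyme pool derivatives under competitive allocation
#'
#' `dE_i/dt = f_i * pEP * B - rE * E_i`: each group receives its allocated
#' share of the biomass-proportional synthesis budget and decays at a
#' common first-order rate. Because the coefficients sum to 1, gross
#' production totals `pEP * B` under every allocation scheme - allocation
#' moves enzyme carbon between groups, never changes its total cost.
#'
#' @param E Six nonnegative enzyme pools (mg enzyme-C kg^-1).
#' @param f Six allocation coefficients summing to 1
#'   (see [compute_allocation()]).
#' @param B Microbial biomass (mg C kg^-1), nonnegative.
#' @param pEP Enzyme production fraction (d^-1).
#' @param rE Enzyme turnover rate (d^-1).
#' @return Six derivatives (mg enzyme-C kg^-1 d^-1).
#' @export
enzyme_derivatives <- function(E, f, B, pEP, rE) {
  if (length(E) != 6L || length(f) != 6L || anyNA(c(E, f, B, pEP, rE)))
    stop("`E` and `f` must be length-6 numeric, inputs free of NA",
         call. = FALSE)
  if (any(E < 0) || B < 0) stop("`E` and `B` must be nonnegative",
                                call. = FALSE)
  as.numeric(f) * pEP * B - rE * E
}

# Instantaneous fluxes at a given state. Concentrations are clamped at zero
# before evaluating the Michaelis-Menten terms so a pool touching zero (to
# integrator tolerance) contributes no consumption - every consuming flux
# thereby scales with its available pool, which keeps the mass-balance audit
# intact without clipping derivatives.
codeal_fluxes <- function(N, E, ON, fplant, params) {
  Np <- pmax(N, 0)
  if (!params$dynamic_n2) Np[6] <- params$N2_boundary
  Fe <- params$Vmax * pmax(E, 0) * Np / (params$Ks + Np)
  if (params$bnf_inhibition)
    Fe[6] <- Fe[6] * (1 - Np[1] / (Np[1] + params$Ks[1]))
  c(F_nit = Fe[1], F_nar = Fe[2], F_nir = Fe[3], F_nor = Fe[4],
    F_nos = Fe[5], F_fix = Fe[6],
    F_min = params$kmin * max(ON, 0),
    U_NH4 = params$Vup_NH4 * fplant * Np[1] / (params$Kup_NH4 + Np[1]),
    U_NO3 = params$Vup_NO3 * fplant * Np[2] / (params$Kup_NO3 + Np[2]),
    G_NO  = params$gNO  * Np[4],
    G_N2O = params$gN2O * Np[5])
}

FLUX_NAMES <- c("F_nit", "F_nar", "F_nir", "F_nor", "F_nos", "F_fix",
                "F_min", "U_NH4", "U_NO3", "G_NO", "G_N2O")
ENZYMATIC_FLUXES <- c("F_fix", "F_nit", "F_nar", "F_nir", "F_nor", "F_nos")

# State layout: N (6), E (6), ON, cumIn, cumOut  -> 15 states.
STATE_NAMES <- c(N_SPECIES, paste0("E_", ENZYME_GROUPS),
                 "ON", "cumIn", "cumOut")

#' Model right-hand side
#'
#' Assembles the instantaneous flux vector and the state derivative at time
#' `t`. Pool balances (mg N kg^-1 d^-1):
#' \preformatted{
#' dNH4 = F_min + F_fix - F_nit - U_NH4 + I_NH4
#' dNO3 = F_nit - F_nar - U_NO3 + I_NO3
#' dNO2 = F_nar - F_nir
#' dNO  = F_nir - F_nor - gNO * NO
#' dN2O = F_nor - F_nos - gN2O * N2O
#' dN2  = 0 (boundary mode)  or  F_nos - F_fix (dynamic mode)
#' dON  = L - F_min,  F_min = kmin * ON
#' }
#' with plant uptake `U_x = Vup_x * fplant * N_x / (Kup_x + N_x)` and
#' enzyme dynamics from [enzyme_derivatives()] using coefficients
#' recomputed at every evaluation. The `cumIn`/`cumOut` accumulators
#' integrate all boundary inputs (deposition, litter, and in boundary-N2
#' mode the fixation influx) and exports (uptake, gas losses, and in
#' boundary-N2 mode the terminal N2 efflux), so
#' `totalN(t) - totalN(t0) = cumIn - cumOut` at all times.
#'
#' @param t Time (d), inside the forcing span.
#' @param state Named numeric state vector (see Details) or a list as built
#'   by [initial_state()].
#' @param params A `codeal_params` object.
#' @param forcing A `codeal_forcing` object (see [make_forcing()],
#'   [read_forcing()]).
#' @param scheme Allocation scheme identifier.
#' @return List of `deriv` (length-15 derivative), `fluxes` (named flux
#'   vector) and `alloc` (six allocation coefficients).
#' @export
codeal_rhs <- function(t, state, params, forcing, scheme) {
  y <- as.numeric(state)
  if (length(y) != 15L) stop("state must have 15 entries", call. = FALSE)
  if (anyNA(y)) stop("NaN/NA in model state at t = ", t, call. = FALSE)
  frc <- forcing_at(forcing, t)
  N <- y[1:6]; E <- y[7:12]; ON <- y[13]
  if (!params$dynamic_n2) N[6] <- params$N2_boundary
  fl <- codeal_fluxes(N, E, ON, frc[["fplant"]], params)
  f <- compute_allocation(scheme, pmax(N, 0), params$Ks,
                          floor = params$alloc_floor)
  dN <- c(
    fl[["F_min"]] + fl[["F_fix"]] - fl[["F_nit"]] - fl[["U_NH4"]] +
      frc[["I_NH4"]],
    fl[["F_nit"]] - fl[["F_nar"]] - fl[["U_NO3"]] + frc[["I_NO3"]],
    fl[["F_nar"]] - fl[["F_nir"]],
    fl[["F_nir"]] - fl[["F_nor"]] - fl[["G_NO"]],
    fl[["F_nor"]] - fl[["F_nos"]] - fl[["G_N2O"]],
    if (params$dynamic_n2) fl[["F_nos"]] - fl[["F_fix"]] else 0
  )
  dE <- enzyme_derivatives(pmax(E, 0), f, frc[["B"]], params$pEP, params$rE)
  dON <- frc[["L"]] - fl[["F_min"]]
  boundary <- !params$dynamic_n2
  dIn <- frc[["I_NH4"]] + frc[["I_NO3"]] + frc[["L"]] +
    (if (boundary) fl[["F_fix"]] else 0)
  dOut <- fl[["U_NH4"]] + fl[["U_NO3"]] + fl[["G_NO"]] + fl[["G_N2O"]] +
    (if (boundary) fl[["F_nos"]] else 0)
  list(deriv = c(dN, dE, dON, dIn, dOut), fluxes = fl, alloc = f)
}

#' Initial model state
#'
#' @param N Six initial inorganic N concentrations (mg N kg^-1).
#' @param E Six initial enzyme pools (mg enzyme-C kg^-1).
#' @param ON Initial organic N pool (mg N kg^-1).
#' @return Named numeric vector of the 15 model states (boundary-exchange
#'   accumulators start at zero).
#' @export
initial_state <- function(N = c(2, 5, 0.05, 0.01, 0.01, 20),
                          E = rep(0.5, 6), ON = 40) {
  check_substrate_vector(N)
  if (length(E) != 6L || anyNA(E) || any(E < 0))
    stop("`E` must be six nonnegative pools", call. = FALSE)
  if (is.na(ON) || ON < 0) stop("`ON` must be nonnegative", call. = FALSE)
  y <- c(as.numeric(N), as.numeric(E), ON, 0, 0)
  names(y) <- STATE_NAMES
  y
}
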