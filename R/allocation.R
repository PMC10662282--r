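#' @title Substrate and enzyme-group ordering
#' @description The six inorganic nitrogen substrates are kept in a fixed
#' order throughout the package. Every length-6 vector (concentrations,
#' half-saturation constants, enzyme pools, maximal rates, allocation
#' coefficients, transformation fluxes) follows this order, with each slot
#' holding the enzyme group that consumes that substrate:
#'
#' | slot | substrate | enzyme group            | code |
#' |------|-----------|-------------------------|------|
#' | 1    | NH4       | ammonia oxidases        | amo  |
#' | 2    | NO3       | nitrate reductases      | nar  |
#' | 3    | NO2       | nitrite reductases      | nir  |
#' | 4    | NO        | nitric oxide reductases | nor  |
#' | 5    | N2O       | nitrous oxide reductases| nos  |
#' | 6    | N2        | nitrogenases            | nif  |
#'
#' @format Character vectors of length 6.
#' @name substrate-order
NULL

#' @rdname substrate-order
#' @export
N_SPECIES <- c("NH4", "NO3", "NO2", "NO", "N2O", "N2")

#' @rdname substrate-order
#' @export
ENZYME_GROUPS <- c("amo", "nar", "nir", "nor", "nos", "nif")

# ---- scheme registry --------------------------------------------------------

# Weight functions map (floored concentration, Ks) -> nonnegative weights.
.scheme_registry <- new.env(parent = emptyenv())

#' Register an allocation scheme
#'
#' The three canonical schemes `A0`, `A1`, `A2` are pre-registered. New
#' schemes can be added by supplying a weight function `function(N, Ks)`
#' returning six nonnegative weights; coefficients are the normalized
#' weights.
#'
#' @param name Scheme identifier (string token used in configs and the CLI).
#' @param weight_fn Function of `(N, Ks)` returning a nonnegative numeric
#'   vector of length 6. `N` arrives already floored away from zero.
#' @export
register_scheme <- function(name, weight_fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(weight_fn))
  assign(name, weight_fn, envir = .scheme_registry)
  invisible(name)
}

#' List registered allocation schemes
#' @return Character vector of scheme identifiers.
#' @export
allocation_schemes <- function() sort(ls(.scheme_registry))

register_scheme("A0", function(N, Ks) N)
register_scheme("A1", function(N, Ks) N / Ks)
register_scheme("A2", function(N, Ks) Ks / N)

# ---- validators -------------------------------------------------------------

check_substrate_vector <- function(N, what = "N") {
  if (!is.numeric(N) || length(N) != 6L)
    stop(sprintf("`%s` must be a numeric vector of length 6 (order %s)",
                 what, paste(N_SPECIES, collapse = ",")), call. = FALSE)
  if (anyNA(N) || any(N < 0))
    stop(sprintf("`%s` must be nonnegative and free of NA", what),
         call. = FALSE)
  invisible(TRUE)
}

check_ks_vector <- function(Ks) {
  if (!is.numeric(Ks) || length(Ks) != 6L)
    stop("`Ks` must be a numeric vector of length 6", call. = FALSE)
  if (anyNA(Ks) || any(Ks <= 0))
    stop("`Ks` entries must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

# ---- operations -------------------------------------------------------------

#' Michaelis-Menten saturation level
#'
#' The occupancy `N / (N + Ks)` of a substrate: 0 at zero concentration,
#' 0.5 at the half-saturation constant, approaching 1 as the substrate
#' saturates. This is the weighting factor underlying the A1 allocation
#' scenario and the ammonium-inhibition term of biological N fixation.
#'
#' @param N Nonnegative concentration(s) (mg N kg^-1 soil).
#' @param Ks Strictly positive half-saturation constant(s) (mg N kg^-1).
#' @return Saturation level(s) in `[0, 1)`. Vectorized with recycling.
#' @examples
#' saturation(1, 1)   # 0.5
#' saturation(3, 1)   # 0.75
#' @export
saturation <- function(N, Ks) {
  if (anyNA(N) || any(N < 0)) stop("`N` must be nonnegative", call. = FALSE)
  if (anyNA(Ks) || any(Ks <= 0)) stop("`Ks` must be positive", call. = FALSE)
  N / (N + Ks)
}

#' Competitive dynamic allocation coefficients
#'
#' Distributes enzyme synthesis among the six nitrogen-cycle enzyme groups
#' by normalizing a substrate-linked weight:
#' \describe{
#'   \item{A0}{weight `N_i` - proportion of each substrate's concentration
#'     in the total inorganic N.}
#'   \item{A1}{weight `N_i / Ks_i` - the relative saturation level of each
#'     substrate, so enzymes flow to substrates near kinetic saturation.}
#'   \item{A2}{weight `Ks_i / N_i` - the inverse of A1, favouring
#'     under-saturated substrates (a stable-flux strategy).}
#' }
#' Coefficient `i` belongs to the enzyme group consuming substrate `i`
#' (see [N_SPECIES]). Concentrations are floored at `floor` before
#' weighting so A2 remains defined as a concentration approaches zero.
#'
#' @param scheme Scheme identifier: `"A0"`, `"A1"`, `"A2"` or a name added
#'   via [register_scheme()].
#' @param N Six nonnegative concentrations (mg N kg^-1), substrate order.
#' @param Ks Six positive half-saturation constants (mg N kg^-1).
#' @param floor Small positive concentration floor (default 1e-10
#'   mg N kg^-1).
#' @return Named numeric vector of six coefficients in `[0, 1]` summing to
#'   1, names [ENZYME_GROUPS], with attribute `scheme`.
#' @examples
#' Ks <- rep(1, 6)
#' compute_allocation("A0", c(2, 1, 1, 1, 1, 1), Ks)  # 2/7 then 1/7 each
#' compute_allocation("A1", Ks, Ks)                   # uniform 1/6
#' @export
compute_allocation <- function(scheme, N, Ks, floor = 1e-10) {
  check_substrate_vector(N)
  check_ks_vector(Ks)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("`floor` must be a single positive number", call. = FALSE)
  if (!is.character(scheme) || length(scheme) != 1L ||
      !exists(scheme, envir = .scheme_registry, inherits = FALSE))
    stop(sprintf("unknown allocation scheme '%s' (registered: %s)",
                 as.character(scheme)[1],
                 paste(allocation_schemes(), collapse = ", ")),
         call. = FALSE)
  wfn <- get(scheme, envir = .scheme_registry)
  w <- wfn(pmax(N, floor), Ks)
  if (anyNA(w) || any(w < 0))
    stop("scheme weight function produced negative or NA weights",
         call. = FALSE)
  tot <- sum(w)
  if (tot <= 0) stop("all allocation weights are zero", call. = FALSE)
  f <- w / tot
  names(f) <- ENZYME_GROUPS
  attr(f, "scheme") <- scheme
  f
}
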