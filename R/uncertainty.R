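# Parameter-perturbation ensembles (Latin hypercube) and the relative
# uncertainty statistic ReUn = width of the 90% inter-percentile interval
# divided by the ensemble mean.

#' Default multiplicative sampling ranges
#'
#' The "N-relevant" parameters varied by default: the six maximal rates,
#' the six half-saturation constants, the enzyme production fraction and
#' the enzyme turnover rate (14 dimensions).
#'
#' @param low,high Multiplicative bounds applied to the base value
#'   (default 0.75 and 1.25, i.e. +/-25%).
#' @return Named list of `c(low, high)` pairs keyed by parameter name;
#'   vector parameters use `Vmax_NH4` ... `Ks_N2` element names.
#' @export
default_ranges <- function(low = 0.75, high = 1.25) {
  nm <- c(paste0("Vmax_", N_SPECIES), paste0("Ks_", N_SPECIES),
          "pEP", "rE")
  stats::setNames(rep(list(c(low, high)), length(nm)), nm)
}

# get/set a scalar parameter addressed by name: plain scalars ("pEP") or
# vector elements ("Vmax_NO3", "Ks_NH4").
get_param <- function(params, name) {
  if (grepl("^(Vmax|Ks)_", name)) {
    parts <- strsplit(name, "_", fixed = TRUE)[[1]]
    sp <- paste(parts[-1], collapse = "_")
    params[[parts[1]]][match(sp, N_SPECIES)]
  } else params[[name]]
}

set_param <- function(params, name, value) {
  if (grepl("^(Vmax|Ks)_", name)) {
    parts <- strsplit(name, "_", fixed = TRUE)[[1]]
    sp <- paste(parts[-1], collapse = "_")
    i <- match(sp, N_SPECIES)
    if (is.na(i)) stop("unknown substrate in parameter name: ", name,
                       call. = FALSE)
    params[[parts[1]]][i] <- value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else stop("unknown parameter: ", name, call. = FALSE)
  params
}

#' Latin-hypercube parameter ensemble
#'
#' Draws `n` parameter sets: each sampled parameter's multiplicative range
#' is split into `n` equal strata with exactly one uniform draw per
#' stratum, and the strata order is permuted independently per parameter
#' (stratified, space-filling marginals). Fully deterministic given
#' `(seed, n, ranges)`.
#'
#' @param base A `codeal_params` providing the central values.
#' @param ranges Named list of multiplicative `c(low, high)` bounds (see
#'   [default_ranges()]).
#' @param n Ensemble size (>= 2).
#' @param seed Integer seed.
#' @return A `codeal_ensemble`: list with `sets` (list of `codeal_params`),
#'   `design` (n x d matrix of multipliers), `ranges`, `seed`,
#'   `method = "lhs"`.
#' @export
sample_parameters <- function(base, ranges = default_ranges(), n = 100,
                              seed = 1) {
  stopifnot(inherits(base, "codeal_params"))
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  # zero-width (low == high) is allowed and yields a degenerate ensemble
  bad <- vapply(ranges, function(r) length(r) != 2L || anyNA(r) ||
                  r[1] > r[2], logical(1))
  if (any(bad))
    stop("invalid range bounds for: ",
         paste(names(ranges)[bad], collapse = ", "), call. = FALSE)
  d <- length(ranges)
  u <- with_seed(seed, lhs::randomLHS(n, d))
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  mult <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(mult) <- names(ranges)
  sets <- lapply(seq_len(n), function(i) {
    p <- base
    for (nm in names(ranges))
      p <- set_param(p, nm, get_param(base, nm) * mult[i, nm])
    p
  })
  structure(list(sets = sets, design = mult, ranges = ranges, seed = seed,
                 method = "lhs"), class = "codeal_ensemble")
}

#' Relative uncertainty (ReUn)
#'
#' `ReUn = (p95 - p5) / mean`: the width of the 90% inter-percentile
#' interval of an ensemble output divided by its mean. Percentiles use
#' linear interpolation of order statistics (R's default type-7
#' convention).
#'
#' @param values Numeric ensemble of a scalar output (length >= 2).
#' @return Nonnegative scalar (dimensionless).
#' @export
reun <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop("`values` must have length >= 2 and no NA", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("ensemble mean is zero; ReUn undefined", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  (q[2] - q[1]) / m
}

#' Ensemble relative uncertainty of the aggregate outputs
#'
#' Propagates a Latin-hypercube parameter ensemble through the simulator
#' under one allocation scheme and returns the ReUn of Flux-Ninorg and of
#' Enz-Ninorg (production reading), plus the raw ensembles. Individual run
#' failures are excluded with a count; more than 10% failures aborts.
#'
#' @param scheme Allocation scheme identifier.
#' @param base Central `codeal_params`.
#' @param config A `codeal_config` (its scheme is overridden).
#' @param forcing A `codeal_forcing`.
#' @param ranges,n,seed Passed to [sample_parameters()].
#' @return List with `reun_flux`, `reun_enz`, `values` (data frame of the
#'   per-run outputs), `n_failed`.
#' @export
ensemble_reun <- function(scheme, base, config, forcing,
                          ranges = default_ranges(), n = 100, seed = 1) {
  ens <- sample_parameters(base, ranges, n, seed)
  cfg <- config; cfg$scheme <- scheme
  out <- lapply(ens$sets, function(p) {
    tryCatch({
      tr <- run_simulation(cfg, p, forcing)
      c(flux = flux_ninorg(tr),
        enz = enz_ninorg(tr, forcing, "production")$total)
    }, error = function(e) NULL)
  })
  failed <- vapply(out, is.null, logical(1))
  if (mean(failed) > 0.10)
    stop(sprintf("%d of %d ensemble runs failed (> 10%%)",
                 sum(failed), n), call. = FALSE)
  if (any(failed))
    message(sum(failed), " ensemble run(s) failed and were excluded")
  vals <- do.call(rbind, out[!failed])
  list(reun_flux = reun(vals[, "flux"]), reun_enz = reun(vals[, "enz"]),
       values = as.data.frame(vals), n_failed = sum(failed))
}
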