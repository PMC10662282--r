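# Forcing time series: the external drivers the reduced model does not
# simulate (microbial biomass, mineral N deposition, litter organic N input,
# plant activity). Values between grid points are linearly interpolated.

FORCING_COLS <- c("time", "B", "I_NH4", "I_NO3", "L", "fplant")

#' Construct a forcing object
#'
#' @param time Time grid (d), strictly increasing.
#' @param B Microbial biomass (mg C kg^-1), nonnegative.
#' @param I_NH4,I_NO3 Mineral N input rates (mg N kg^-1 d^-1), nonnegative.
#' @param L Litter organic-N input rate (mg N kg^-1 d^-1), nonnegative.
#' @param fplant Plant-activity factor in `[0, 1]` scaling potential uptake.
#' @return A `codeal_forcing` object (a data frame with linear
#'   interpolators attached).
#' @export
forcing_series <- function(time, B, I_NH4, I_NO3, L, fplant) {
  d <- data.frame(time = time, B = B, I_NH4 = I_NH4, I_NO3 = I_NO3,
                  L = L, fplant = fplant)
  if (nrow(d) < 2L) stop("forcing needs at least two time points",
                         call. = FALSE)
  if (is.unsorted(d$time, strictly = TRUE))
    stop("forcing `time` must be strictly increasing", call. = FALSE)
  if (anyNA(d)) stop("forcing contains NA", call. = FALSE)
  if (any(d$B < 0) || any(d$I_NH4 < 0) || any(d$I_NO3 < 0) || any(d$L < 0))
    stop("forcing rates must be nonnegative", call. = FALSE)
  if (any(d$fplant < 0 | d$fplant > 1))
    stop("`fplant` must lie in [0, 1]", call. = FALSE)
  fns <- lapply(FORCING_COLS[-1], function(v)
    stats::approxfun(d$time, d[[v]], method = "linear", rule = 1))
  names(fns) <- FORCING_COLS[-1]
  structure(d, interp = fns, class = c("codeal_forcing", "data.frame"))
}

# Evaluate all forcing channels at time t; errors outside the span.
forcing_at <- function(forcing, t) {
  fns <- attr(forcing, "interp")
  out <- vapply(fns, function(f) f(t), numeric(1))
  if (anyNA(out))
    stop(sprintf("forcing lookup at t = %g outside span [%g, %g]",
                 t, forcing$time[1], forcing$time[nrow(forcing)]),
         call. = FALSE)
  out
}

#' Read / write forcing CSV
#'
#' The on-disk format is a CSV with header
#' `time,B,I_NH4,I_NO3,L,fplant` (days; mg C or N per kg soil as in
#' [forcing_series()]).
#'
#' @param path File path.
#' @return [read_forcing()] returns a `codeal_forcing`;
#'   [write_forcing()] returns `path` invisibly.
#' @export
read_forcing <- function(path) {
  d <- utils::read.csv(path)
  missing <- setdiff(FORCING_COLS, names(d))
  if (length(missing))
    stop("forcing CSV misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(forcing_series, d[FORCING_COLS])
}

#' @rdname read_forcing
#' @param forcing A `codeal_forcing` object.
#' @export
write_forcing <- function(forcing, path) {
  utils::write.csv(as.data.frame(forcing)[FORCING_COLS], path,
                   row.names = FALSE)
  invisible(path)
}
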