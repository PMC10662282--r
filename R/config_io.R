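# Configuration I/O: a single JSON (or YAML) file carries the kinetic
# parameters, the simulation settings and the initial state.

#' Read / write a model configuration file
#'
#' The file (JSON; YAML accepted when the `yaml` package is available)
#' holds up to three blocks:
#' \preformatted{
#' {
#'   "params":  { ... arguments of kinetic_params() ... },
#'   "config":  { "t0": 0, "t1": 4380, "dt_out": 1, "scheme": "A1", ... },
#'   "state0":  { "N": [...6...], "E": [...6...], "ON": 40 }
#' }
#' }
#' Omitted entries fall back to the package defaults.
#'
#' @param path File path (`.json`, `.yml`/`.yaml`).
#' @return List with `params` (`codeal_params`) and `config`
#'   (`codeal_config`).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  params <- do.call(kinetic_params, as.list(raw$params))
  st <- raw$state0
  state0 <- do.call(initial_state, if (is.null(st)) list() else as.list(st))
  cfg_args <- if (is.null(raw$config)) list() else as.list(raw$config)
  cfg_args$state0 <- state0
  config <- do.call(simulation_config, cfg_args)
  list(params = params, config = config)
}

#' @rdname read_config
#' @param params A `codeal_params`.
#' @param config A `codeal_config`.
#' @export
write_config <- function(params, config, path) {
  p <- unclass(params)
  p$dynamic_n2 <- NULL
  out <- list(
    params = p,
    config = list(t0 = config$t0, t1 = config$t1, dt_out = config$dt_out,
                  scheme = config$scheme, solver = config$solver,
                  rtol = config$rtol, atol = config$atol,
                  rk4_step = config$rk4_step, neg_tol = config$neg_tol),
    state0 = list(N = unname(config$state0[1:6]),
                  E = unname(config$state0[7:12]),
                  ON = unname(config$state0[13])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
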