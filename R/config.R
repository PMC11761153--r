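experiment_names <- c("fig9_extinction", "fig10_persistence", "fig11_phiT",
                      "fig12_sigmaT", "fig13_gammahT", "fig14_gammabT",
                      "threshold", "custom")

#' Parse and validate a run configuration file
#'
#' Reads a YAML key-value configuration describing one run: which
#' experiment to execute, parameter overrides, thermal curve blocks,
#' temperature forcing, solver settings and initial states. Unknown keys
#' are rejected; all defaults are resolved so the returned specification
#' is complete and can be serialized and re-parsed to the identical
#' specification.
#'
#' Recognized top-level keys: `experiment` (one of the named scenarios or
#' `"threshold"`/`"custom"`), `params` (named overrides of the baseline
#' constants), `thermal` (per-symbol curve blocks, each either a number or
#' a mapping with a `family` key), `forcing` (`T0`, `T1`, `omega`,
#' `kappa`, `variant`), `solver` (`method`, `rtol`, `atol`, `t_max`,
#' `n_out`), `init` (list of initial state vectors).
#'
#' @param path path to a YAML file, or a list already in memory.
#' @return a validated specification of class `locustdyn_spec`.
#' @export
parse_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("experiment", "params", "thermal", "forcing", "solver", "init")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  experiment <- raw$experiment %||% "threshold"
  if (!experiment %in% experiment_names)
    stop("unknown experiment '", experiment, "'; valid: ",
         paste(experiment_names, collapse = ", "))
  params <- locust_params(raw$params %||% list())
  thermal_cfg <- raw$thermal %||% list()
  thermal <- build_thermal_param_set(thermal_cfg, params = params)
  fdef <- list(T0 = 20, T1 = 2, omega = 2, kappa = 100,
               variant = "additive")
  f <- utils::modifyList(fdef, raw$forcing %||% list())
  forcing <- temperature_forcing(f$T0, f$T1, f$omega, f$kappa, f$variant)
  sdef <- list(method = "ode45", rtol = 1e-8, atol = 1e-10,
               t_max = 2000, n_out = 400)
  solver <- utils::modifyList(sdef, raw$solver %||% list())
  init <- raw$init
  if (length(init) == 0L) init <- NULL else
    init <- lapply(init, function(x) as_stage_state(unlist(x)))
  structure(list(experiment = experiment, params = params,
                 thermal_config = thermal_cfg, thermal = thermal,
                 forcing = forcing, solver = solver, init = init),
            class = "locustdyn_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run specification back to a YAML-compatible list
#'
#' @param spec a [parse_config()] specification.
#' @return a plain list; `parse_config()` on it reproduces `spec`.
#' @export
serialize_config <- function(spec) {
  stopifnot(inherits(spec, "locustdyn_spec"))
  list(experiment = spec$experiment,
       params = as.list(unclass(spec$params)),
       thermal = spec$thermal_config,
       forcing = unclass(spec$forcing),
       solver = spec$solver,
       init = lapply(spec$init, as.list))
}

#' Threshold diagnostics as a serializable report
#'
#' Scalar summary of the autonomous model at a parameter set: rate
#' aggregates, closed-form and next-generation `N0`, `phi*`, the
#' equilibria with their stability, and the bifurcation classification.
#'
#' @param params a [locust_params()] set.
#' @return a nested list ready for JSON serialization.
#' @export
threshold_report <- function(params) {
  on <- offspring_number(params)
  rep <- list(
    aggregates = as.list(rate_aggregates(params)),
    N0S = on$N0S, N0G = on$N0G, N0 = on$N0,
    N0_ngm = offspring_number_ngm(params),
    phi_star = suppressWarnings(phi_star(params)),
    origin = stability_report(params, rep(0, 5))[c("max_re", "stable",
                                                   "verdict")]
  )
  if (on$N0 > 1) {
    eq <- nontrivial_equilibrium(params)
    rep$equilibrium <- as.list(eq)
    rep$equilibrium_stability <-
      stability_report(params, eq)[c("max_re", "stable", "verdict")]
  }
  bif <- suppressWarnings(bifurcation_coefficients(params))
  rep$bifurcation <- bif[c("phi_star", "a", "b", "v1_sign",
                           "classification")]
  rep
}

default_inits <- function(K) {
  lapply(c(1e-4, 0.02, 0.25), function(f)
    c(E = f * K, H = 0.5 * f * K, B = 0.3 * f * K,
      S = 0.1 * f * K, G = 0.05 * f * K))
}

#' Run a named simulation experiment
#'
#' Executes one of the packaged simulation scenarios and writes its
#' artifacts (trajectory CSV per initial state, threshold JSON, resolved
#' configuration) to a directory:
#' \describe{
#'   \item{fig9_extinction}{autonomous, baseline with `phi = 1.75`
#'     (`N0 < 1`): decay to extinction from spread-out initial states.}
#'   \item{fig10_persistence}{autonomous, `phi = 25`, `mu_h = 0.25`,
#'     `mu_b = 0.3` (`N0 > 1`): convergence to the positive equilibrium.}
#'   \item{fig11_phiT / fig12_sigmaT / fig13_gammahT / fig14_gammabT}{
#'     seasonally forced runs in which one rate at a time follows its
#'     fitted thermal curve.}
#'   \item{threshold}{no simulation; threshold diagnostics only.}
#'   \item{custom}{simulate exactly what the spec describes.}
#' }
#'
#' @param spec a `locustdyn_spec` from [parse_config()], or the name of a
#'   scenario (run with its default configuration).
#' @param out_dir output directory (created if missing); `NULL` returns
#'   results without writing files.
#' @return list with `spec`, `threshold` (report) and `trajectories`
#'   (one per initial state), invisibly when writing files.
#' @export
run_experiment <- function(spec, out_dir = NULL) {
  if (is.character(spec)) spec <- parse_config(list(experiment = spec))
  stopifnot(inherits(spec, "locustdyn_spec"))
  name <- spec$experiment
  params <- spec$params
  thermal_cfg <- spec$thermal_config
  forced <- FALSE
  if (name == "fig9_extinction") {
    params <- locust_params(modifyList(as.list(unclass(params)),
                                       list(phi = 1.75)))
  } else if (name == "fig10_persistence") {
    params <- locust_params(modifyList(as.list(unclass(params)),
                                       list(phi = 25, mu_h = 0.25,
                                            mu_b = 0.3)))
  } else if (name %in% c("fig11_phiT", "fig12_sigmaT", "fig13_gammahT",
                         "fig14_gammabT")) {
    sym <- switch(name, fig11_phiT = "phi", fig12_sigmaT = "sigma",
                  fig13_gammahT = "gamma_h", fig14_gammabT = "gamma_b")
    if (is.null(thermal_cfg[[sym]]))
      thermal_cfg[[sym]] <- fitted_thermal_curve(sym)
    forced <- TRUE
  } else if (name == "custom") {
    forced <- length(thermal_cfg) > 0
  }
  thermal <- build_thermal_param_set(thermal_cfg, params = params)
  thr <- threshold_report(params)
  solver <- spec$solver
  times <- seq(0, solver$t_max, length.out = solver$n_out)
  inits <- spec$init %||% default_inits(unclass(params)[["K"]])
  trajectories <- NULL
  if (name != "threshold") {
    model <- if (forced) {
      list(thermal = thermal, forcing = spec$forcing,
           constants = unclass(params)[c("theta", "beta_1", "beta_2",
                                         "psi", "eta", "K")])
    } else params
    trajectories <- lapply(inits, function(y0)
      simulate_locusts(y0, model, times, method = solver$method,
                       rtol = solver$rtol, atol = solver$atol))
  }
  result <- list(spec = spec, params = params, threshold = thr,
                 trajectories = trajectories)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(thr, file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(serialize_config(spec),
                     file.path(out_dir, "config.yaml"))
    for (i in seq_along(trajectories))
      write_trajectory_csv(trajectories[[i]],
                           file.path(out_dir,
                                     sprintf("trajectory_%02d.csv", i)))
    return(invisible(result))
  }
  result
}
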