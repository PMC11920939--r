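#' Scenario configuration for random-community experiments
#'
#' Bundles every knob of a simulation scenario: community size and sampling
#' parameters, the sign regime of interspecific interactions, the dynamical
#' model (classical or bounded GLV), stopping thresholds, solver tolerances,
#' and replication/seeding.
#'
#' @param S Species richness (integer, at least 2).
#' @param connectance Proportion of off-diagonal interaction coefficients that
#'   are nonzero, in `[0, 1]`. The realised number of nonzero entries is the
#'   exact count `round(connectance * S * (S - 1))`, not a per-entry coin flip.
#' @param sigma Standard deviation of the Gaussian from which nonzero
#'   interspecific coefficients are drawn (per-capita rate per unit abundance).
#' @param sign_mode One of `"mixed"` (both signs allowed), `"all_negative"`
#'   (competition/amensalism only) or `"all_positive"`
#'   (mutualism/commensalism only). The diagonal is always -1.
#' @param bounded Logical; if `TRUE` the bounded model with ceiling `Nmax` is
#'   integrated, otherwise the classical GLV.
#' @param Nmax Abundance ceiling of the bounded model.
#' @param perturb_sd Standard deviation of the Gaussian perturbation applied
#'   to the equilibrium to obtain initial conditions.
#' @param blow_up_threshold Abundance at which a species is declared to be on
#'   its way to infinity and the (unbounded) simulation is stopped.
#' @param extinction_threshold Abundance below which a species is considered
#'   extinct at the end of a simulation (strict inequality: a species exactly
#'   at the threshold counts as extinct).
#' @param derivative_tol Convergence criterion: the run is declared converged
#'   at the first checkpoint where `max_i |dN_i/dt|` falls below this value.
#' @param t_max Integration horizon in model time units.
#' @param n_reps Number of replicates per richness value in sweeps.
#' @param seed Root seed; per-replicate seeds are pre-assigned deterministically
#'   from it so results do not depend on execution order.
#' @param rtol,atol Relative and absolute solver tolerances passed to
#'   [deSolve::lsoda()].
#' @param checkpoint_dt Spacing of the dense output checkpoints at which the
#'   convergence criterion is evaluated.
#' @param near_total_fraction Fraction of `S` at or below which a surviving
#'   community counts as "near-total extinction" when classifying outcomes of
#'   all-positive scenarios.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(S = 10)
#' cfg$connectance
#' @export
scenario_config <- function(S,
                            connectance = 0.7,
                            sigma = 0.2,
                            sign_mode = c("mixed", "all_negative", "all_positive"),
                            bounded = FALSE,
                            Nmax = 1000,
                            perturb_sd = 0.02,
                            blow_up_threshold = 1000,
                            extinction_threshold = 1e-4,
                            derivative_tol = 1e-5,
                            t_max = 1000,
                            n_reps = 100,
                            seed = 1L,
                            rtol = 1e-8,
                            atol = 1e-10,
                            checkpoint_dt = 1,
                            near_total_fraction = 0.1) {
  sign_mode <- match.arg(sign_mode)
  cfg <- list(
    S = as.integer(S), connectance = connectance, sigma = sigma,
    sign_mode = sign_mode, bounded = isTRUE(bounded), Nmax = Nmax,
    perturb_sd = perturb_sd, blow_up_threshold = blow_up_threshold,
    extinction_threshold = extinction_threshold,
    derivative_tol = derivative_tol, t_max = t_max,
    n_reps = as.integer(n_reps), seed = as.integer(seed),
    rtol = rtol, atol = atol, checkpoint_dt = checkpoint_dt,
    near_total_fraction = near_total_fraction
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$S) != 1L || is.na(cfg$S) || cfg$S < 2L)
    stop("invalid richness: S must be a single integer >= 2", call. = FALSE)
  if (cfg$connectance < 0 || cfg$connectance > 1)
    stop("invalid connectance: must lie in [0, 1]", call. = FALSE)
  if (cfg$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (cfg$perturb_sd < 0) stop("perturb_sd must be nonnegative", call. = FALSE)
  if (!(cfg$extinction_threshold < 1 && 1 < cfg$blow_up_threshold))
    stop("thresholds must satisfy extinction_threshold < 1 < blow_up_threshold",
         call. = FALSE)
  if (cfg$blow_up_threshold > cfg$Nmax)
    stop("blow_up_threshold must not exceed Nmax", call. = FALSE)
  if (cfg$t_max <= 0 || cfg$derivative_tol <= 0)
    stop("t_max and derivative_tol must be positive", call. = FALSE)
  if (cfg$n_reps < 1L) stop("n_reps must be at least 1", call. = FALSE)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  S = %d, connectance = %g, sigma = %g, sign_mode = %s\n",
              x$S, x$connectance, x$sigma, x$sign_mode))
  cat(sprintf("  model = %s, Nmax = %g, perturb_sd = %g\n",
              if (x$bounded) "bounded GLV" else "GLV", x$Nmax, x$perturb_sd))
  cat(sprintf("  stop: blow_up > %g, converged when max|dN/dt| < %g, t_max = %g\n",
              x$blow_up_threshold, x$derivative_tol, x$t_max))
  cat(sprintf("  n_reps = %d, seed = %d\n", x$n_reps, x$seed))
  invisible(x)
}

#' Read a scenario configuration from a key-value text file
#'
#' The file is flat YAML (`key: value` per line) whose keys are the arguments
#' of [scenario_config()]. Keys absent from the file keep their defaults.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values taking precedence over the file,
#'   e.g. parsed command-line flags.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain key: value pairs", call. = FALSE)
  vals[names(overrides)] <- overrides
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(scenario_config, vals)
}

#' Write a scenario configuration to a key-value text file
#'
#' @param cfg A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
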