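#' Right-hand side of the classical GLV model
#'
#' `dN_i/dt = N_i (r_i + sum_j a_ij N_j)`.
#'
#' @param N Abundance vector, componentwise nonnegative.
#' @param model A [community_model()] (the unbounded variant).
#' @return Vector of time derivatives `dN/dt`.
#' @export
glv_rhs <- function(N, model) {
  if (any(N < 0)) stop("abundances must be nonnegative", call. = FALSE)
  as.vector(N * (model$r + model$A %*% N))
}

#' Right-hand side of the bounded GLV model
#'
#' The classical GLV growth of each species is attenuated by the factor
#' `(Nmax - N_i) / Nmax`, which vanishes at the ceiling and leaves the sign
#' of the growth rate unchanged anywhere inside `(0, Nmax)`. Any equilibrium
#' of the classical model below the ceiling remains an equilibrium.
#'
#' @inheritParams glv_rhs
#' @param model A bounded [community_model()].
#' @return Vector of time derivatives `dN/dt`.
#' @export
bounded_glv_rhs <- function(N, model) {
  if (!isTRUE(model$bounded)) stop("model is not bounded", call. = FALSE)
  if (any(N < 0)) stop("abundances must be nonnegative", call. = FALSE)
  if (any(N > model$Nmax)) stop("abundances must not exceed Nmax", call. = FALSE)
  as.vector(N * (model$r + model$A %*% N) * (model$Nmax - N) / model$Nmax)
}

# Dispatch on the model's own variant; used internally by the solver and the
# convergence checks.
model_rhs <- function(N, model) {
  if (model$bounded) bounded_glv_rhs(N, model) else glv_rhs(N, model)
}

#' Jacobian of the governing model at an arbitrary state
#'
#' Analytic Jacobian of the (bounded or classical) GLV right-hand side with
#' respect to the abundances, evaluated at `N`. At an interior equilibrium of
#' the classical model this reduces to `diag(N*) A`.
#'
#' @param model A [community_model()].
#' @param N Abundance vector at which to differentiate.
#' @return An `S x S` numeric matrix.
#' @export
model_jacobian <- function(model, N) {
  A <- model$A
  B <- as.vector(model$r + A %*% N)
  if (!model$bounded) {
    J <- A * N                # row i scaled by N_i
    diag(J) <- diag(J) + B
    return(J)
  }
  phi <- (model$Nmax - N) / model$Nmax
  J <- A * (N * phi)
  diag(J) <- diag(J) + B * phi - N * B / model$Nmax
  J
}

#' Integrate a community model from a perturbed initial state
#'
#' Integrates the governing system with [deSolve::lsoda()] and the model's
#' analytic Jacobian, applying three stopping rules:
#'
#' * `blow_up` - in the classical model, the integration stops (by root
#'   location, so the stopping time is accurate) as soon as any abundance
#'   crosses `blow_up_threshold` from below;
#' * `converged` - at the first dense checkpoint (every `checkpoint_dt` time
#'   units) where `max_i |dN_i/dt| < derivative_tol`;
#' * `time_limit` - at `t = t_max` if neither of the above fired.
#'
#' Abundances are propagated in transformed coordinates (log abundance for
#' the classical model, log of `N / (Nmax - N)` for the bounded model), in
#' which both extinction and the ceiling become asymptotes of a smooth
#' vector field. Reported abundances are therefore strictly positive and, in
#' the bounded model, strictly below `Nmax`, by construction.
#'
#' @param model A [community_model()].
#' @param N0 Strictly positive initial abundances (below `Nmax` if bounded).
#' @param config A [scenario_config()] supplying thresholds, horizon and
#'   solver tolerances.
#' @param keep_trajectory If `TRUE`, the checkpointed trajectory is retained
#'   in the result (one row per checkpoint).
#' @return An object of class `glv_sim`: a list with `stop_reason` (one of
#'   `"converged"`, `"blow_up"`, `"time_limit"`), `t_stop`, `N_final`,
#'   `alive_mask`, `n_alive`, `n_at_ceiling` (bounded model, else `NA`),
#'   `returned_to_Nstar`, and optionally `trajectory` (a tibble).
#' @examples
#' m <- community_model(matrix(-1), 1)
#' cfg <- scenario_config(S = 2)
#' out <- simulate_community(m, 0.01, cfg)
#' out$stop_reason
#' @export
simulate_community <- function(model, N0, config, keep_trajectory = FALSE) {
  if (any(N0 <= 0)) stop("initial abundances must be strictly positive", call. = FALSE)
  if (model$bounded && any(N0 >= model$Nmax))
    stop("initial abundances must lie strictly below Nmax", call. = FALSE)
  A <- model$A; r <- model$r
  bounded <- model$bounded; Nmax <- model$Nmax
  blow <- config$blow_up_threshold

  # state transform: y -> N
  to_N <- if (bounded) function(y) Nmax / (1 + exp(-y)) else function(y) exp(y)
  y <- if (bounded) log(N0 / (Nmax - N0)) else log(N0)
  # guard against exp overflow on speculative solver trial steps
  ycap <- if (bounded) Inf else log(blow) + 30

  rhs <- function(t, y, p) {
    N <- to_N(pmin(y, ycap))
    list(as.vector(r + A %*% N))
  }
  jac <- if (bounded) {
    function(t, y, p) {
      N <- to_N(y)
      A * rep(N * (Nmax - N) / Nmax, each = nrow(A))
    }
  } else {
    function(t, y, p) A * rep(to_N(pmin(y, ycap)), each = nrow(A))
  }
  rootf <- function(t, y, p) max(y) - log(blow)

  deriv <- function(N) {
    d <- N * (r + as.vector(A %*% N))
    if (bounded) d <- d * (Nmax - N) / Nmax
    d
  }

  t0 <- 0
  reason <- "time_limit"
  chunk <- 50 * config$checkpoint_dt
  traj_t <- 0
  traj_N <- matrix(to_N(y), nrow = 1)

  while (t0 < config$t_max) {
    t1 <- min(t0 + chunk, config$t_max)
    times <- seq(t0, t1, by = config$checkpoint_dt)
    if (times[length(times)] < t1) times <- c(times, t1)
    out <- suppressWarnings(deSolve::lsoda(
      y, times, rhs, parms = NULL,
      jacfunc = jac, jactype = "fullusr",
      rtol = config$rtol, atol = config$atol, maxsteps = 100000,
      rootfunc = if (bounded) NULL else rootf
    ))
    istate <- attr(out, "istate")
    hit_root <- !bounded && !is.null(istate) && istate[1] == 3
    nr <- nrow(out)
    ys <- out[, -1, drop = FALSE]

    if (keep_trajectory && nr > 1) {
      traj_t <- c(traj_t, unname(out[-1, 1]))
      traj_N <- rbind(traj_N, to_N(ys[-1, , drop = FALSE]))  # elementwise
    }

    converged_at <- NA_integer_
    for (i in seq_len(nr)) {
      if (max(abs(deriv(to_N(ys[i, ])))) < config$derivative_tol) {
        converged_at <- i
        break
      }
    }
    if (!is.na(converged_at)) {
      y <- ys[converged_at, ]; t0 <- unname(out[converged_at, 1])
      reason <- "converged"
      break
    }
    if (hit_root) {
      y <- ys[nr, ]; t0 <- unname(out[nr, 1])
      reason <- "blow_up"
      break
    }
    if (nr < length(times)) {
      stop(sprintf("integration failure (step-size underflow) at t = %g", out[nr, 1]),
           call. = FALSE)
    }
    y <- ys[nr, ]; t0 <- unname(out[nr, 1])
  }

  N_final <- unname(to_N(y))
  alive <- classify_survivors(N_final, config$extinction_threshold)
  res <- structure(list(
    stop_reason = reason,
    t_stop = t0,
    N_final = N_final,
    alive_mask = alive,
    n_alive = sum(alive),
    n_at_ceiling = if (bounded) sum(N_final >= 0.999 * Nmax) else NA_integer_,
    returned_to_Nstar = reason == "converged" &&
      max(abs(N_final - model$Nstar)) < 10 * config$perturb_sd,
    model = model
  ), class = "glv_sim")
  if (keep_trajectory) {
    colnames(traj_N) <- paste0("N", seq_len(ncol(traj_N)))
    res$trajectory <- dplyr::bind_cols(tibble::tibble(time = traj_t),
                                       tibble::as_tibble(traj_N))
  }
  res
}

#' @export
print.glv_sim <- function(x, ...) {
  cat(sprintf("<glv_sim> %s at t = %g; %d/%d species alive\n",
              x$stop_reason, x$t_stop, x$n_alive, length(x$N_final)))
  invisible(x)
}

#' Survivor classification
#'
#' A species is alive iff its final abundance strictly exceeds the extinction
#' threshold; an abundance exactly at the threshold counts as extinct.
#'
#' @param N_final Final abundance vector.
#' @param extinction_threshold Threshold abundance.
#' @return Logical mask, `TRUE` for surviving species.
#' @export
classify_survivors <- function(N_final, extinction_threshold = 1e-4) {
  N_final > extinction_threshold
}

#' @rdname tidiers
#' @export
tidy.glv_sim <- function(x, ...) {
  tibble::tibble(
    species = seq_along(x$N_final),
    N_final = x$N_final,
    alive = x$alive_mask,
    at_ceiling = if (!is.na(x$n_at_ceiling)) x$N_final >= 0.999 * x$model$Nmax else NA
  )
}

#' @rdname tidiers
#' @export
glance.glv_sim <- function(x, ...) {
  tibble::tibble(
    stop_reason = x$stop_reason,
    t_stop = x$t_stop,
    n_alive = x$n_alive,
    n_at_ceiling = x$n_at_ceiling,
    returned_to_Nstar = x$returned_to_Nstar
  )
}
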