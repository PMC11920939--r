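#' Two-species Lotka-Volterra model
#'
#' Parameterises a two-species system `dN_i/dt = N_i (r_i + a_i1 N_1 +
#' a_i2 N_2)`, optionally bounded by an abundance ceiling, for phase-plane
#' analysis: isoclines, equilibria and the vector field.
#'
#' @param r1,r2 Intrinsic per-capita growth rates.
#' @param a11,a12,a21,a22 Per-capita interaction coefficients; the
#'   self-limitation terms `a11`, `a22` must be negative.
#' @param Nmax Abundance ceiling; `NULL` for the classical model.
#' @return An object of class `two_species_model`.
#' @examples
#' # mutualism with an interior saddle (a12 * a21 > a11 * a22)
#' m <- two_species_model(r1 = -1, r2 = -1, a11 = -1, a12 = 2,
#'                        a21 = 2, a22 = -1, Nmax = 10)
#' @export
two_species_model <- function(r1, r2, a11, a12, a21, a22, Nmax = NULL) {
  if (a11 >= 0 || a22 >= 0)
    stop("self-limitation requires a11 < 0 and a22 < 0", call. = FALSE)
  if (!is.null(Nmax) && Nmax <= 0) stop("Nmax must be positive", call. = FALSE)
  structure(list(r = c(r1, r2),
                 A = matrix(c(a11, a21, a12, a22), 2, 2),
                 Nmax = Nmax,
                 bounded = !is.null(Nmax)),
            class = "two_species_model")
}

# RHS of a two-species model at (possibly many) states; N is a 2-column matrix
two_species_rhs <- function(model, N) {
  B <- sweep(N %*% t(model$A), 2, model$r, `+`)
  d <- N * B
  if (model$bounded) d <- d * (model$Nmax - N) / model$Nmax
  d
}

classify_equilibrium <- function(model, N, tol = 1e-9) {
  # two_species_model carries the same A/r/bounded/Nmax fields as a
  # community_model, so the shared analytic Jacobian applies unchanged
  ev <- eigen(model_jacobian(model, N), only.values = TRUE)$values
  re <- Re(ev)
  if (any(abs(re) <= tol)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

#' Interior equilibrium of a two-species model
#'
#' Solves the linear system \eqn{r + A N = 0}. The point is reported only when
#' both coordinates are strictly positive; its stability is classified from
#' the Jacobian of the governing (bounded or classical) model.
#'
#' @param model A [two_species_model()].
#' @return A one-row tibble with columns `N1`, `N2`, `kind`, `stability`, or
#'   a zero-row tibble when no interior equilibrium exists. A singular
#'   interaction matrix (parallel isoclines) yields the zero-row result with
#'   attribute `degenerate = TRUE`.
#' @export
interior_equilibrium <- function(model) {
  empty <- tibble::tibble(N1 = double(), N2 = double(),
                          kind = character(), stability = character())
  if (abs(det(model$A)) < 1e-12) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  N <- solve(model$A, -model$r)
  if (any(N <= 0)) return(empty)
  if (model$bounded && any(N >= model$Nmax)) return(empty)
  tibble::tibble(N1 = N[1], N2 = N[2], kind = "interior",
                 stability = classify_equilibrium(model, N))
}

#' Enumerate all equilibria of a two-species model
#'
#' Returns the trivial origin, the single-species boundary points
#' `(-r_i / a_ii, 0)` and `(0, -r_j / a_jj)` when positive, the interior
#' intersection of the isoclines when feasible, and - for the bounded model -
#' all ceiling equilibria: states with one species pinned at `Nmax` and the
#' partner either extinct, at its conditional equilibrium, or itself at
#' `Nmax`. Ceiling points are located analytically by substituting
#' `N_i = Nmax` into the partner's zero-growth condition. Each point is
#' classified from the Jacobian of the governing system; non-hyperbolic
#' points are reported as `"marginal"`.
#'
#' @param model A [two_species_model()].
#' @return A tibble with columns `N1`, `N2`, `kind` (one of `"trivial"`,
#'   `"boundary"`, `"interior"`, `"ceiling"`) and `stability` (one of
#'   `"stable"`, `"unstable"`, `"saddle"`, `"marginal"`).
#' @export
enumerate_equilibria <- function(model) {
  pts <- list(c(0, 0))
  kinds <- "trivial"
  add <- function(N, kind) {
    pts[[length(pts) + 1]] <<- N
    kinds[length(kinds) + 1] <<- kind
  }
  K1 <- -model$r[1] / model$A[1, 1]
  K2 <- -model$r[2] / model$A[2, 2]
  inmax <- function(v) !model$bounded || v < model$Nmax
  if (K1 > 0 && inmax(K1)) add(c(K1, 0), "boundary")
  if (K2 > 0 && inmax(K2)) add(c(0, K2), "boundary")
  int <- interior_equilibrium(model)
  if (nrow(int) == 1) add(c(int$N1, int$N2), "interior")
  if (model$bounded) {
    Nmax <- model$Nmax
    # species 1 at ceiling: partner must satisfy N2 = 0, N2 = Nmax, or B2 = 0
    add(c(Nmax, 0), "ceiling")
    add(c(0, Nmax), "ceiling")
    add(c(Nmax, Nmax), "ceiling")
    n2 <- -(model$r[2] + model$A[2, 1] * Nmax) / model$A[2, 2]
    if (n2 > 0 && n2 < Nmax) add(c(Nmax, n2), "ceiling")
    n1 <- -(model$r[1] + model$A[1, 2] * Nmax) / model$A[1, 1]
    if (n1 > 0 && n1 < Nmax) add(c(n1, Nmax), "ceiling")
  }
  tibble::tibble(
    N1 = purrr::map_dbl(pts, 1),
    N2 = purrr::map_dbl(pts, 2),
    kind = kinds,
    stability = purrr::map_chr(pts, \(N) classify_equilibrium(model, N))
  )
}

#' Nontrivial zero-growth isoclines as polylines
#'
#' For each species, the classical nontrivial isocline is the line
#' `r_i + a_i1 N_1 + a_i2 N_2 = 0`; the bounded model adds the ceiling
#' isocline `N_i = Nmax`. Each isocline is evaluated on a dense grid over
#' the requested window for export or plotting.
#'
#' @param model A [two_species_model()].
#' @param N1_range,N2_range Plot window, vectors `c(min, max)`.
#' @param n Number of points per polyline.
#' @return A tibble with columns `isocline`, `species`, `N1`, `N2`.
#' @export
isoclines <- function(model, N1_range, N2_range, n = 201) {
  A <- model$A; r <- model$r
  out <- list()
  s1 <- seq(N1_range[1], N1_range[2], length.out = n)
  s2 <- seq(N2_range[1], N2_range[2], length.out = n)
  # species 1 bracket: r1 + a11 N1 + a12 N2 = 0
  if (A[1, 2] != 0) {
    out$g1 <- tibble::tibble(isocline = "growth", species = 1L, N1 = s1,
                             N2 = -(r[1] + A[1, 1] * s1) / A[1, 2])
  } else {
    out$g1 <- tibble::tibble(isocline = "growth", species = 1L,
                             N1 = -r[1] / A[1, 1], N2 = s2)
  }
  if (A[2, 1] != 0) {
    out$g2 <- tibble::tibble(isocline = "growth", species = 2L, N1 = s1,
                             N2 = -(r[2] + A[2, 1] * s1) / A[2, 2])
  } else {
    out$g2 <- tibble::tibble(isocline = "growth", species = 2L,
                             N1 = s1, N2 = -r[2] / A[2, 2])
  }
  if (model$bounded) {
    out$c1 <- tibble::tibble(isocline = "ceiling", species = 1L,
                             N1 = model$Nmax, N2 = s2)
    out$c2 <- tibble::tibble(isocline = "ceiling", species = 2L,
                             N1 = s1, N2 = model$Nmax)
  }
  purrr::list_rbind(out) |>
    dplyr::filter(.data$N2 >= N2_range[1], .data$N2 <= N2_range[2],
                  .data$N1 >= N1_range[1], .data$N1 <= N1_range[2])
}

#' Vector field of a two-species model on a regular grid
#'
#' @param model A [two_species_model()].
#' @param N1_range,N2_range Positive ranges `c(min, max)` for each axis.
#' @param resolution Number of grid points per axis.
#' @return A tibble with columns `N1`, `N2`, `dN1`, `dN2`, ordered
#'   lexicographically by `(N1, N2)`.
#' @export
vector_field_grid <- function(model, N1_range, N2_range, resolution = 20) {
  if (any(c(N1_range, N2_range) < 0))
    stop("ranges must be nonnegative", call. = FALSE)
  grid <- tidyr::expand_grid(
    N1 = seq(N1_range[1], N1_range[2], length.out = resolution),
    N2 = seq(N2_range[1], N2_range[2], length.out = resolution)
  )
  d <- two_species_rhs(model, as.matrix(grid))
  grid |> dplyr::mutate(dN1 = d[, 1], dN2 = d[, 2])
}

#' Simulate a two-species model from one initial state
#'
#' Thin wrapper turning the model into a [community_model()] with the given
#' interior equilibrium-free parameterisation and integrating it with the
#' package solver; used for phase-portrait trajectories and for brute-force
#' classification cross-checks.
#'
#' @param model A [two_species_model()].
#' @param N0 Initial abundances (length 2, strictly positive).
#' @param t_max Integration horizon.
#' @param config Optional [scenario_config()] carrying thresholds; defaults
#'   to standard thresholds with `t_max` as given.
#' @return A `glv_sim` object (see [simulate_community()]).
#' @export
simulate_two_species <- function(model, N0, t_max = 1000, config = NULL) {
  if (is.null(config)) {
    config <- scenario_config(S = 2, t_max = t_max,
                              bounded = model$bounded,
                              Nmax = if (model$bounded) model$Nmax else 1000,
                              blow_up_threshold = if (model$bounded) model$Nmax else 1000)
  }
  cm <- structure(list(A = model$A, Nstar = c(NA_real_, NA_real_),
                       r = model$r, bounded = model$bounded,
                       Nmax = model$Nmax),
                  class = "community_model")
  sim <- simulate_community(cm, N0, config)
  sim$returned_to_Nstar <- NA
  sim
}
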