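#' Sample a random per-capita interaction matrix
#'
#' Draws an `S x S` interaction matrix with diagonal fixed at -1
#' (intraspecific competition) and exactly `round(c * S * (S - 1))` nonzero
#' off-diagonal coefficients placed uniformly at random without replacement.
#' Nonzero values are Gaussian with mean zero and standard deviation `sigma`;
#' under a constrained sign regime the magnitude `|N(0, sigma^2)|` is used
#' with the prescribed sign. Entries `a[i, j]` and `a[j, i]` are sampled
#' independently, so the interaction type of a pair (competition, antagonism,
#' mutualism, ...) emerges from the realised sign pair.
#'
#' @param config A [scenario_config()]; `S`, `connectance`, `sigma` and
#'   `sign_mode` are used.
#' @return A base matrix of per-capita interaction coefficients with
#'   attribute `connectance_realized` (the nonzero off-diagonal count).
#' @examples
#' set.seed(1)
#' A <- sample_interaction_matrix(scenario_config(S = 10))
#' sum(A[row(A) != col(A)] != 0) # exactly round(0.7 * 10 * 9) = 63
#' @export
sample_interaction_matrix <- function(config) {
  config <- validate_scenario_config(config)
  S <- config$S
  A <- matrix(0, S, S)
  diag(A) <- -1
  k <- round_half_away(config$connectance * S * (S - 1))
  if (k > 0) {
    off <- which(row(A) != col(A))
    pos <- sample(off, k, replace = FALSE)
    v <- stats::rnorm(k, mean = 0, sd = config$sigma)
    v <- switch(config$sign_mode,
      mixed        = v,
      all_negative = -abs(v),
      all_positive = abs(v)
    )
    A[pos] <- v
  }
  attr(A, "connectance_realized") <- k
  A
}

# round() in R rounds half to even; the realised-connectance contract is
# "half away from zero", which only differs at exact .5 counts.
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Sample equilibrium abundances
#'
#' Each species' equilibrium abundance is log-Gaussian: `ln N*_i ~ N(0, 1)`,
#' independent across species, so abundances are strictly positive with
#' median 1 and mean `exp(1/2)`.
#'
#' @param S Number of species (positive integer).
#' @return A numeric vector of length `S` of strictly positive abundances.
#' @export
sample_equilibrium <- function(S) {
  if (length(S) != 1L || is.na(S) || S < 1) stop("S must be a positive integer", call. = FALSE)
  exp(stats::rnorm(S, 0, 1))
}

#' Intrinsic growth rates that make an abundance vector an equilibrium
#'
#' Solves \eqn{r = -A N^*}, the unique choice of per-capita intrinsic growth
#' rates for which `N*` is an interior equilibrium of the GLV system with
#' interaction matrix `A`. The identity `A N* + r = 0` then holds exactly in
#' floating point, because `r` is literally the negated product.
#'
#' @param A Interaction matrix (`S x S`).
#' @param Nstar Equilibrium abundance vector (length `S`, strictly positive).
#' @return Numeric vector of intrinsic growth rates (1/time).
#' @export
growth_rates_from_equilibrium <- function(A, Nstar) {
  check_matrix_vector(A, Nstar)
  as.vector(-A %*% Nstar)
}

check_matrix_vector <- function(A, Nstar) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix", call. = FALSE)
  if (nrow(A) != length(Nstar))
    stop("dimension mismatch: A is ", nrow(A), "x", ncol(A),
         " but N* has length ", length(Nstar), call. = FALSE)
  invisible(TRUE)
}

#' Perturb an equilibrium to obtain initial conditions
#'
#' Adds independent Gaussian noise of mean zero and standard deviation
#' `perturb_sd` to every abundance; any negative result is replaced by its
#' absolute value so initial abundances stay strictly positive.
#'
#' @param Nstar Equilibrium abundance vector.
#' @param perturb_sd Standard deviation of the perturbation (>= 0).
#' @return Perturbed abundance vector, componentwise positive.
#' @export
perturb_equilibrium <- function(Nstar, perturb_sd = 0.02) {
  if (perturb_sd < 0) stop("perturb_sd must be nonnegative", call. = FALSE)
  abs(Nstar + stats::rnorm(length(Nstar), 0, perturb_sd))
}

#' Build a GLV community model around a sampled equilibrium
#'
#' Packages the interaction matrix, the equilibrium vector, the implied
#' intrinsic growth rates \eqn{r = -A N^*}, and (for the bounded variant) the
#' abundance ceiling into a single model object consumed by the dynamics,
#' stability and experiment functions.
#'
#' @param A Interaction matrix.
#' @param Nstar Strictly positive equilibrium abundances.
#' @param bounded Logical; `TRUE` selects the bounded model.
#' @param Nmax Abundance ceiling, required when `bounded = TRUE`; must
#'   strictly exceed `max(Nstar)` so the equilibrium lies inside the box.
#' @return An object of class `community_model`.
#' @examples
#' m <- community_model(diag(-1, 2), c(1, 1))
#' m$r # c(1, 1)
#' @export
community_model <- function(A, Nstar, bounded = FALSE, Nmax = NULL) {
  check_matrix_vector(A, Nstar)
  if (any(Nstar <= 0)) stop("N* must be strictly positive", call. = FALSE)
  if (isTRUE(bounded)) {
    if (is.null(Nmax)) stop("Nmax is required for the bounded model", call. = FALSE)
    if (Nmax <= max(Nstar))
      stop("Nmax must strictly exceed max(N*)", call. = FALSE)
  }
  structure(
    list(A = A, Nstar = as.numeric(Nstar),
         r = growth_rates_from_equilibrium(A, Nstar),
         bounded = isTRUE(bounded),
         Nmax = if (isTRUE(bounded)) Nmax else NULL),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  S <- length(x$Nstar)
  nz <- sum(x$A[row(x$A) != col(x$A)] != 0)
  cat(sprintf("<community_model> %s, S = %d, %d realised interactions\n",
              if (x$bounded) sprintf("bounded GLV (Nmax = %g)", x$Nmax) else "GLV",
              S, nz))
  invisible(x)
}

#' Sample a complete replicate community
#'
#' Convenience wrapper performing the full sampling chain of one replicate:
#' interaction matrix, equilibrium abundances, growth rates and the perturbed
#' initial state.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `model` (a [community_model()]) and `N0`
#'   (the perturbed initial abundances).
#' @export
sample_community <- function(config) {
  config <- validate_scenario_config(config)
  A <- sample_interaction_matrix(config)
  Nstar <- sample_equilibrium(config$S)
  model <- community_model(A, Nstar, bounded = config$bounded,
                           Nmax = if (config$bounded) config$Nmax else NULL)
  list(model = model, N0 = perturb_equilibrium(Nstar, config$perturb_sd))
}
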