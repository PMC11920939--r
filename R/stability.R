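#' Jacobian of the GLV system at its interior equilibrium
#'
#' At an interior equilibrium the bracket \eqn{r + A N^*} vanishes, so the
#' Jacobian collapses to the closed form `diag(N*) A`.
#'
#' @param A Interaction matrix.
#' @param Nstar Interior equilibrium abundances.
#' @return The `S x S` Jacobian matrix.
#' @export
jacobian_at_equilibrium <- function(A, Nstar) {
  check_matrix_vector(A, Nstar)
  A * as.numeric(Nstar)   # row i scaled by N*_i, i.e. diag(N*) %*% A
}

#' Local stability from the Jacobian spectrum
#'
#' Computes the full eigenvalue spectrum of the Jacobian and declares the
#' equilibrium locally stable iff every eigenvalue has real part below
#' `-stability_tol`. This spectral test is equivalent to the Routh-Hurwitz
#' criterion on the characteristic polynomial but numerically robust at
#' large richness. Eigenvalues whose largest real part lies within
#' `stability_tol` of zero are flagged as marginal rather than silently
#' classified.
#'
#' @param J Square Jacobian matrix, or a [community_model()] (in which case
#'   the Jacobian at the model's equilibrium is used).
#' @param stability_tol Half-width of the marginal band around zero.
#' @return An object of class `glv_stability` with elements `eigenvalues`
#'   (complex vector), `max_real_part`, `is_stable` and `marginal`.
#' @examples
#' local_stability(diag(-1, 3))$is_stable
#' @export
local_stability <- function(J, stability_tol = 1e-9) {
  if (inherits(J, "community_model")) J <- jacobian_at_equilibrium(J$A, J$Nstar)
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square", call. = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  mrp <- max(Re(ev))
  structure(list(
    eigenvalues = ev,
    max_real_part = mrp,
    is_stable = mrp < -stability_tol,
    marginal = abs(mrp) <= stability_tol
  ), class = "glv_stability")
}

#' @export
print.glv_stability <- function(x, ...) {
  cat(sprintf("<glv_stability> %s (max Re lambda = %.6g%s)\n",
              if (x$is_stable) "locally stable" else "unstable",
              x$max_real_part,
              if (x$marginal) ", marginal" else ""))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.glv_stability <- function(x, ...) {
  tibble::tibble(
    eigenvalue = seq_along(x$eigenvalues),
    real = Re(x$eigenvalues),
    imaginary = Im(x$eigenvalues)
  )
}

#' @rdname tidiers
#' @export
glance.glv_stability <- function(x, ...) {
  tibble::tibble(
    n = length(x$eigenvalues),
    max_real_part = x$max_real_part,
    is_stable = x$is_stable,
    marginal = x$marginal
  )
}
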