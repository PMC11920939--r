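# Shared fixtures, built in code at test time.

# Two mutualists with an interior saddle: r = (-1, -1), diagonal -1,
# a12 = a21 = 2, so a12 * a21 = 4 > 1 = a11 * a22 and the interior
# equilibrium (1, 1) has Jacobian eigenvalues 1 and -3.
saddle_mutualism <- function(Nmax = NULL) {
  two_species_model(r1 = -1, r2 = -1, a11 = -1, a12 = 2, a21 = 2, a22 = -1,
                    Nmax = Nmax)
}

saddle_mutualism_community <- function(bounded = FALSE, Nmax = NULL) {
  A <- matrix(c(-1, 2, 2, -1), 2, 2)
  community_model(A, c(1, 1), bounded = bounded, Nmax = Nmax)
}

# Small scenario used widely in unit tests
tiny_config <- function(...) {
  scenario_config(S = 10, n_reps = 5, seed = 42, ...)
}

# Componentwise re-implementation of the two-species RHS, written out
# term by term as an independent oracle for the phase-plane module.
two_species_rhs_for_test <- function(m, N) {
  N <- matrix(N, ncol = 2)
  a <- m$A
  d1 <- N[, 1] * (m$r[1] + a[1, 1] * N[, 1] + a[1, 2] * N[, 2])
  d2 <- N[, 2] * (m$r[2] + a[2, 1] * N[, 1] + a[2, 2] * N[, 2])
  if (m$bounded) {
    d1 <- d1 * (m$Nmax - N[, 1]) / m$Nmax
    d2 <- d2 * (m$Nmax - N[, 2]) / m$Nmax
  }
  cbind(d1, d2)
}

# Central-difference Jacobian of the governing RHS; independent of the
# analytic formulas under test.
fd_jacobian <- function(model, N, h = 1e-6) {
  S <- length(N)
  rhs <- function(x) if (model$bounded) bounded_glv_rhs(x, model) else glv_rhs(x, model)
  J <- matrix(0, S, S)
  for (j in seq_len(S)) {
    e <- numeric(S); e[j] <- h * max(1, abs(N[j]))
    J[, j] <- (rhs(N + e) - rhs(N - e)) / (2 * e[j])
  }
  J
}
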