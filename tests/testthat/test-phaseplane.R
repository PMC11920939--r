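test_that("decoupled logistic pair has a stable interior point at the carrying capacities", {
  m <- two_species_model(1, 1, -1, 0, 0, -1)
  eq <- interior_equilibrium(m)
  expect_equal(c(eq$N1, eq$N2), c(1, 1))
  expect_equal(eq$stability, "stable")
})

test_that("the strong-mutualism interior point is a saddle", {
  m <- saddle_mutualism()
  eq <- interior_equilibrium(m)
  expect_equal(c(eq$N1, eq$N2), c(1, 1))
  expect_equal(eq$stability, "saddle")
  ev <- sort(Re(eigen(model_jacobian(m, c(1, 1)), only.values = TRUE)$values))
  expect_equal(ev, c(-3, 1))
})

test_that("parallel isoclines are reported as degenerate, not solved", {
  m <- two_species_model(1, 1, -1, 0.5, -2, -1)
  m$A <- matrix(c(-1, -2, 0.5, 1), 2, 2) # singular by construction
  eq <- interior_equilibrium(m)
  expect_equal(nrow(eq), 0)
  expect_true(isTRUE(attr(eq, "degenerate")))
})

test_that("bounded mutualism gains a stable ceiling equilibrium and keeps a stable origin", {
  m <- saddle_mutualism(Nmax = 10)
  eq <- enumerate_equilibria(m)
  expect_true(any(eq$kind == "trivial"))
  origin <- dplyr::filter(eq, N1 == 0, N2 == 0)
  expect_equal(origin$stability, "stable")
  ceiling_pt <- dplyr::filter(eq, N1 == 10, N2 == 10)
  expect_equal(nrow(ceiling_pt), 1)
  expect_equal(ceiling_pt$stability, "stable")
  # interior saddle also present
  expect_true(any(eq$kind == "interior" & eq$stability == "saddle"))
})

test_that("every enumerated equilibrium has a vanishing RHS, and a grid scan finds no others", {
  m <- saddle_mutualism(Nmax = 10)
  eq <- enumerate_equilibria(m)
  res <- two_species_rhs_for_test(m, as.matrix(eq[, c("N1", "N2")]))
  expect_lt(max(abs(res)), 1e-10)

  # dense grid scan at resolution 1e-3 * Nmax: every point where the field
  # nearly vanishes must be near an enumerated equilibrium, and each
  # equilibrium must be hit
  h <- 1e-3 * 10
  g <- as.matrix(expand.grid(N1 = seq(0, 10, by = h), N2 = seq(0, 10, by = h)))
  d <- two_species_rhs_for_test(m, g)
  nrm <- sqrt(d[, 1]^2 + d[, 2]^2)
  low <- g[nrm < 0.02, , drop = FALSE]
  dist_to_eq <- function(P) {
    apply(P, 1, function(p) min(sqrt((p[1] - eq$N1)^2 + (p[2] - eq$N2)^2)))
  }
  expect_lt(max(dist_to_eq(low)), 0.06)
  hit <- apply(as.matrix(eq[, c("N1", "N2")]), 1, function(p) {
    min(sqrt((low[, 1] - p[1])^2 + (low[, 2] - p[2])^2))
  })
  expect_lt(max(hit), 2 * h)
})

test_that("random mutualism classifications agree with brute-force trajectory fates", {
  set.seed(23)
  n_models <- 0
  while (n_models < 8) {
    a12 <- runif(1, 0.5, 3); a21 <- runif(1, 0.5, 3)
    m <- two_species_model(-1, -1, -1, a12, a21, -1)
    eq <- interior_equilibrium(m)
    if (nrow(eq) == 0 || eq$stability == "marginal") next
    n_models <- n_models + 1
    fates <- purrr::map_chr(1:20, function(i) {
      N0 <- abs(c(eq$N1, eq$N2) + rnorm(2, 0, 0.05))
      out <- simulate_two_species(m, N0, t_max = 500)
      if (out$stop_reason == "blow_up") "escape"
      else if (out$n_alive == 2 &&
               max(abs(out$N_final - c(eq$N1, eq$N2))) < 0.05) "return"
      else "elsewhere"
    })
    if (eq$stability == "stable") {
      expect_true(all(fates == "return"))
    } else {
      expect_true(all(fates != "return"))
    }
  }
})

test_that("the vector field vanishes at equilibria and respects the ceiling", {
  m <- saddle_mutualism(Nmax = 10)
  vf <- vector_field_grid(m, c(0, 10), c(0, 10), resolution = 11)
  expect_equal(nrow(vf), 121)
  at_eq <- dplyr::filter(vf, N1 == 1, N2 == 1)
  expect_equal(c(at_eq$dN1, at_eq$dN2), c(0, 0))
  expect_true(all(dplyr::filter(vf, N1 == 10)$dN1 == 0))
  expect_true(all(dplyr::filter(vf, N2 == 10)$dN2 == 0))

  # interior signs agree with the unbounded field
  mu <- saddle_mutualism()
  vfu <- vector_field_grid(mu, c(0, 10), c(0, 10), resolution = 11)
  interior <- vf$N1 > 0 & vf$N1 < 10 & vf$N2 > 0 & vf$N2 < 10
  expect_equal(sign(vf$dN1[interior]), sign(vfu$dN1[interior]))
  expect_equal(sign(vf$dN2[interior]), sign(vfu$dN2[interior]))
})

test_that("perturbed saddle trajectories end at the origin or the ceiling, never elsewhere", {
  set.seed(29)
  m <- saddle_mutualism(Nmax = 10)
  ends <- purrr::map_chr(1:200, function(i) {
    N0 <- abs(c(1, 1) + rnorm(2, 0, 0.02))
    out <- simulate_two_species(m, N0, t_max = 2000)
    if (out$n_alive == 0) "origin"
    else if (all(out$N_final > 0.999 * 10)) "ceiling"
    else "other"
  })
  expect_true(all(ends %in% c("origin", "ceiling")))
  expect_gt(sum(ends == "origin"), 0)
  expect_gt(sum(ends == "ceiling"), 0)
})

test_that("isoclines lie on the zero-growth lines", {
  m <- saddle_mutualism(Nmax = 10)
  iso <- isoclines(m, c(0, 10), c(0, 10))
  g1 <- dplyr::filter(iso, isocline == "growth", species == 1)
  bracket <- -1 - g1$N1 + 2 * g1$N2
  expect_lt(max(abs(bracket)), 1e-10)
  expect_true(any(iso$isocline == "ceiling"))
})
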