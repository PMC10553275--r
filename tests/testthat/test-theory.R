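# Direct transcription of the printed Poisson-average payoff expressions,
# kept as an independent oracle for the kernel form used in the package.
payoffs_direct <- function(rho_C, rho_D, r, cost) {
  rho <- rho_C + rho_D
  pi_C <- -cost * ((1 - r) * rho_C^2 + (2 - r) * rho_C * rho_D +
                     rho_D * (r * (exp(-rho) - 1) + rho_D)) / rho^2
  pi_D <- cost * exp(-rho) * r * rho_C * (1 + exp(rho) * (rho - 1)) / rho^2
  list(pi_C = pi_C, pi_D = pi_D)
}

test_that("Poisson payoff closed forms match their direct transcription", {
  set.seed(5)
  for (i in 1:40) {
    rc <- runif(1, 0.05, 3); rd <- runif(1, 0.05, 3)
    r <- runif(1, 1.05, 5); cost <- runif(1, 0.02, 0.4)
    got <- expected_payoffs_poisson(rc, rd, r, cost)
    want <- payoffs_direct(rc, rd, r, cost)
    expect_equal(got$pi_C, want$pi_C, tolerance = 1e-10)
    expect_equal(got$pi_D, want$pi_D, tolerance = 1e-10)
  }
})

test_that("Poisson payoffs respect their limits and stay stable near zero", {
  # no cooperators, no pot
  expect_equal(expected_payoffs_poisson(0, 1.7, 3, 0.1)$pi_D, 0)
  # lone-cooperator limit c(r-1), exactly at zero and smoothly nearby
  expect_equal(expected_payoffs_poisson(0, 0, 3, 0.1)$pi_C, 0.2)
  near <- expected_payoffs_poisson(1e-7, 1e-7, 3, 0.1)
  expect_equal(near$pi_C, 0.2, tolerance = 1e-6)
  expect_true(is.finite(near$pi_D))
  expect_error(expected_payoffs_poisson(-0.1, 1, 3, 0.1), "non-negative")
})

test_that("Poisson payoffs agree with Monte-Carlo group sampling", {
  set.seed(42)
  n <- 2e5
  for (case in list(c(2.64288, 0.17856, 3), c(0.5, 1.0, 2), c(1.5, 0.3, 4))) {
    rc <- case[1]; rd <- case[2]; r <- case[3]; cost <- 0.1
    ncs <- rpois(n, rc); nds <- rpois(n, rd)
    mc_C <- pgg_focal_payoff(TRUE, ncs, nds, r, cost)
    mc_D <- pgg_focal_payoff(FALSE, ncs, nds, r, cost)
    cf <- expected_payoffs_poisson(rc, rd, r, cost)
    expect_lt(abs(mean(mc_C) - cf$pi_C), 3 * sd(mc_C) / sqrt(n))
    expect_lt(abs(mean(mc_D) - cf$pi_D), 3 * sd(mc_D) / sqrt(n))
  }
})

test_that("payoff equality holds at the coexistence point", {
  cf <- expected_payoffs_poisson(2.64288, 0.17856, 3, 0.1)
  expect_equal(cf$pi_C, cf$pi_D, tolerance = 1e-5)
  # equal payoffs also pin down eta - lambda/rho at the base parameters
  expect_equal(cf$pi_C, 0.4 - 0.6 / (2.64288 + 0.17856), tolerance = 1e-5)
})

test_that("equilibrium densities select the right branch with known values", {
  b1 <- eq_densities(0.6, 0.4, 1.2, 0.1)
  expect_equal(b1$branch, "I")
  expect_equal(c(b1$rho_C, b1$rho_D), c(0, 1.5))

  b2 <- eq_densities(0.6, 0.4, 3, 0.1)
  expect_equal(b2$branch, "II")
  expect_equal(b2$rho_C, 2.64288, tolerance = 1e-4)
  expect_equal(b2$rho_D, 0.17856, tolerance = 1e-3)

  b3 <- eq_densities(0.05, 0.4, 2, 0.1)
  expect_equal(b3$branch, "III")
  expect_equal(b3$rho_C, 1 / 6, tolerance = 1e-10)
  expect_equal(b3$rho_D, 0)
})

test_that("coexistence densities solve conservation and payoff equality", {
  # independent 2-D root solve of the two stationarity conditions
  res <- function(x, lam, eta, r, cost) {
    pay <- expected_payoffs_poisson(x[1], x[2], r, cost)
    c((r - 1) * cost * x[1] + lam - eta * (x[1] + x[2]),
      pay$pi_C - pay$pi_D)
  }
  root <- pracma::fsolve(function(x) res(x, 0.6, 0.4, 3, 0.1), c(2, 0.5))$x
  b2 <- eq_densities(0.6, 0.4, 3, 0.1)
  expect_equal(b2$rho_C, root[1], tolerance = 1e-6)
  expect_equal(b2$rho_D, root[2], tolerance = 1e-6)

  # residuals vanish across a parameter sweep wherever branch II is selected
  grid <- expand.grid(r = seq(2.1, 5, by = 0.4),
                      ratio = c(0.5, 1.5, 2.5), cost = c(0.05, 0.1, 0.3))
  for (i in seq_len(nrow(grid))) {
    lam <- 0.4 * grid$ratio[i]
    eq <- eq_densities(lam, 0.4, grid$r[i], grid$cost[i])
    if (eq$branch != "II") next
    rr <- res(c(eq$rho_C, eq$rho_D), lam, 0.4, grid$r[i], grid$cost[i])
    expect_lt(max(abs(rr)), 1e-9)
  }
})

test_that("the coexistence branch emerges continuously at r_star", {
  # cooperator density of the coexistence solution crosses zero exactly at
  # the analytic onset
  rho_c2 <- function(r) eq_scan(r, 0.6, 0.4, 0.1)  # not used below boundary
  f <- function(r) {
    w <- pracma::lambertWp(-r * exp(-r))
    (-0.6 + r * 0.4 + 0.4 * w) / (0.1 * (r - 1))
  }
  boundary <- uniroot(f, c(1.5, 2.5), tol = 1e-12)$root
  expect_equal(boundary, r_star(0.6, 0.4), tolerance = 1e-8)
})

test_that("total coexistence density depends on r alone", {
  base <- sum(eq_densities(0.6, 0.4, 3, 0.1)[, c("rho_C", "rho_D")])
  for (par in list(c(0.9, 0.4, 0.1), c(0.6, 0.5, 0.1), c(0.6, 0.4, 0.05))) {
    eq <- eq_densities(par[1], par[2], 3, par[3])
    if (eq$branch == "II") {
      expect_equal(eq$rho_C + eq$rho_D, base, tolerance = 1e-10)
    }
  }
  expect_equal(base, 3 + pracma::lambertWp(-3 * exp(-3)), tolerance = 1e-10)
})

test_that("the cooperation threshold depends only on lambda/eta", {
  expect_equal(r_star(0.6, 0.4), 1.930825, tolerance = 1e-6)
  expect_equal(r_star(0.6, 0.4), r_star(0.3, 0.2), tolerance = 1e-12)
  expect_equal(r_star(1e-8, 1), 1, tolerance = 1e-6)       # poor limit
  expect_equal(r_star(10, 1), 10.00045, tolerance = 1e-4)  # rich asymptote
  expect_error(r_star(0, 0.4), "zero_lambda")
})

test_that("the zero-regeneration threshold is 1 + eta/cost", {
  expect_equal(r_star_zero_lambda(0.4, 0.1), 5)
  expect_equal(r_star_zero_lambda(0.1, 0.1), 2)
  # consistency with the density ratio: gamma changes sign at the threshold
  expect_equal(coop_defector_ratio(0, 1, 6, 0.1, 0.4), 4)
  expect_gt(coop_defector_ratio(0, 1, 5.01, 0.1, 0.4), 100)
  expect_lt(coop_defector_ratio(0, 1, 4.5, 0.1, 0.4), 0)
  expect_error(coop_defector_ratio(0, 1, 5, 0.1, 0.4), "singular")
})

test_that("the invasion payoff of a rare cooperator behaves as derived", {
  # vanishes at the onset by construction
  rs <- r_star(0.6, 0.4)
  expect_lt(abs(onset_payoff_identity(1.5, rs, 0.1)), 1e-12)
  # lone-mutant limit
  expect_equal(onset_payoff_identity(0, 3, 0.1), 0.2)
  # above the onset it is positive and matches Poisson sampling
  v <- onset_payoff_identity(1.5, 3, 0.1)
  expect_gt(v, 0)
  set.seed(9)
  nd <- rpois(2e5, 1.5)
  draws <- 3 * 0.1 / (1 + nd) - 0.1
  expect_lt(abs(mean(draws) - v), 3 * sd(draws) / sqrt(2e5))
})
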