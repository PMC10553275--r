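#' Principal Lambert W function
#'
#' Thin wrapper around [pracma::lambertWp()] with the argument clamped to
#' `>= -1/e` against floating-point rounding; arguments below the clamp by
#' more than `1e-12` are an error.
#'
#' @param x Numeric vector in `[-1/e, Inf)`.
#' @return `W0(x)`, the principal real branch.
#' @keywords internal
lambert_w0 <- function(x) {
  lo <- -exp(-1)
  if (any(x < lo - 1e-12)) stop("lambert_w0: argument below -1/e", call. = FALSE)
  vapply(pmax(x, lo + 1e-15), pracma::lambertWp, numeric(1))
}

# Shared kernel of the Poisson-mixture payoffs:
# g(rho) = (rho - 1 + exp(-rho)) / rho^2, with the series
# g(rho) = sum_{j>=0} (-rho)^j / (j+2)! used below rho = 1e-4 to avoid
# catastrophic cancellation. g(0) = 1/2.
poisson_kernel <- function(rho) {
  out <- numeric(length(rho))
  small <- abs(rho) < 1e-4
  if (any(small)) {
    x <- rho[small]
    out[small] <- 1 / 2 - x / 6 + x^2 / 24 - x^3 / 120
  }
  if (any(!small)) {
    x <- rho[!small]
    out[!small] <- (x - 1 + exp(-x)) / x^2
  }
  out
}

#' Expected public-goods payoffs under Poisson group composition
#'
#' In a perfectly mixed population at densities `rho_C`, `rho_D`, the number
#' of co-players of each type found on a focal individual's site is Poisson
#' distributed. Averaging the per-group payoffs over that mixture gives the
#' closed forms
#' \deqn{\bar\pi_C = c(r-1) - r c \rho_D \, g(\rho), \qquad
#'       \bar\pi_D = r c \rho_C \, g(\rho),}
#' with \eqn{g(\rho) = (\rho - 1 + e^{-\rho})/\rho^2} and
#' \eqn{\rho = \rho_C + \rho_D}. A series expansion of \eqn{g} is used at
#' small total density for numerical stability, so the lone-cooperator limit
#' \eqn{\bar\pi_C \to c(r-1)} is exact.
#'
#' @param rho_C,rho_D Non-negative densities (individuals per site);
#'   vectorised.
#' @param r Enhancement factor (> 1).
#' @param cost Cooperation cost per step (positive).
#' @return A tibble with columns `rho_C`, `rho_D`, `pi_C`, `pi_D`.
#' @examples
#' expected_payoffs_poisson(2.64288, 0.17856, r = 3, cost = 0.1)
#' @export
expected_payoffs_poisson <- function(rho_C, rho_D, r, cost) {
  if (any(rho_C < 0) || any(rho_D < 0)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  poisson_payoffs_raw(rho_C, rho_D, r, cost)
}

# Unvalidated analytic continuation of the Poisson payoff closed forms;
# finite-difference Jacobians probe marginally negative densities.
poisson_payoffs_raw <- function(rho_C, rho_D, r, cost) {
  rho <- rho_C + rho_D
  g <- poisson_kernel(rho)
  tibble::tibble(
    rho_C = rho_C, rho_D = rho_D,
    pi_C = cost * (r - 1) - r * cost * rho_D * g,
    pi_D = r * cost * rho_C * g
  )
}

#' Equilibrium densities of cooperators and defectors
#'
#' Solves the two stationarity principles of the perfectly mixed model —
#' resource conservation, \eqn{(r-1)c\rho_C + \lambda = \eta(\rho_C+\rho_D)},
#' and payoff equality between coexisting types — in closed form. Three
#' branches cover the parameter space:
#' \describe{
#'   \item{I (no cooperation)}{\eqn{\rho_C = 0}, \eqn{\rho_D = \lambda/\eta};
#'     selected when the coexistence cooperator density would be negative.}
#'   \item{II (coexistence)}{\eqn{\rho_C = (-\lambda + r\eta + \eta W_0(-r
#'     e^{-r})) / (c(r-1))}, \eqn{\rho_D = r + W_0(-r e^{-r}) - \rho_C}.}
#'   \item{III (full cooperation)}{\eqn{\rho_D = 0},
#'     \eqn{\rho_C = \lambda / (\eta - (r-1)c)}; selected when the
#'     coexistence defector density would be negative.}
#' }
#' The total coexistence density \eqn{r + W_0(-r e^{-r})} depends on `r`
#' alone. Exact branch boundaries (within `1e-12`) return the boundary
#' branch.
#'
#' @param lambda Basal regeneration rate per site (non-negative); vectorised.
#' @param eta Metabolic rate (positive); vectorised.
#' @inheritParams expected_payoffs_poisson
#' @return A tibble with columns `lambda`, `eta`, `r`, `cost`, `branch`
#'   (`"I"`, `"II"` or `"III"`), `rho_C`, `rho_D`.
#' @examples
#' eq_densities(lambda = 0.6, eta = 0.4, r = 3, cost = 0.1)
#' eq_densities(lambda = 0.6, eta = 0.4, r = c(1.2, 2.5, 3), cost = 0.1)
#' @export
eq_densities <- function(lambda, eta, r, cost) {
  n <- max(length(lambda), length(eta), length(r), length(cost))
  lambda <- rep_len(lambda, n); eta <- rep_len(eta, n)
  r <- rep_len(r, n); cost <- rep_len(cost, n)
  if (any(lambda < 0)) stop("parameter 'lambda' must be non-negative",
                            call. = FALSE)
  if (any(eta <= 0)) stop("parameter 'eta' must be positive", call. = FALSE)
  if (any(r <= 1)) stop("parameter 'r' must exceed 1", call. = FALSE)
  if (any(cost <= 0)) stop("parameter 'cost' must be positive", call. = FALSE)
  w <- lambert_w0(-r * exp(-r))
  rho_tot <- r + w
  rho_c2 <- (-lambda + r * eta + eta * w) / (cost * (r - 1))
  rho_d2 <- rho_tot - rho_c2
  tol <- 1e-12
  branch <- dplyr::case_when(
    rho_c2 < tol ~ "I",
    rho_d2 < tol ~ "III",
    TRUE ~ "II"
  )
  if (any(branch == "III" & eta <= (r - 1) * cost & lambda > 0)) {
    stop(paste("no finite full-cooperation equilibrium:",
               "eta <= (r - 1) * cost with lambda > 0"), call. = FALSE)
  }
  rho_C <- dplyr::case_when(
    branch == "I" ~ 0,
    branch == "II" ~ rho_c2,
    TRUE ~ ifelse(lambda == 0, 0, lambda / (eta - (r - 1) * cost))
  )
  rho_D <- dplyr::case_when(
    branch == "I" ~ lambda / eta,
    branch == "II" ~ rho_d2,
    TRUE ~ 0
  )
  tibble::tibble(lambda = lambda, eta = eta, r = r, cost = cost,
                 branch = branch, rho_C = rho_C, rho_D = rho_D)
}

#' Critical enhancement factor for the evolution of cooperation
#'
#' For positive basal regeneration the onset of cooperation lies at
#' \deqn{r^* = \frac{\lambda/\eta}{1 - e^{-\lambda/\eta}},}
#' a function of the ratio \eqn{\lambda/\eta} alone: the transition is set
#' entirely by resource inflow and metabolic consumption.
#'
#' @inheritParams eq_densities
#' @return `r_star`, vectorised over the inputs.
#' @examples
#' r_star(0.6, 0.4) # about 1.93083
#' @export
r_star <- function(lambda, eta) {
  if (any(eta <= 0)) stop("parameter 'eta' must be positive", call. = FALSE)
  if (any(lambda <= 0)) {
    stop("r_star requires lambda > 0; use r_star_zero_lambda() for lambda = 0",
         call. = FALSE)
  }
  x <- lambda / eta
  x / (-expm1(-x))
}

#' Cooperation threshold in the zero-regeneration limit
#'
#' With no basal inflow, cooperation can persist only if each cooperator's
#' net surplus exceeds its own metabolic drain: \eqn{c(r-1) > \eta}, i.e.
#' \eqn{r > 1 + \eta/c}.
#'
#' @inheritParams eq_densities
#' @return The threshold `1 + eta / cost`, vectorised.
#' @examples
#' r_star_zero_lambda(0.4, 0.1) # 5
#' @export
r_star_zero_lambda <- function(eta, cost) {
  if (any(cost <= 0)) stop("parameter 'cost' must be positive", call. = FALSE)
  1 + eta / cost
}

#' Cooperator-to-defector density ratio from resource conservation
#'
#' Dividing the resource-conservation balance by the defector density gives
#' \deqn{\gamma = \frac{-\lambda/\rho_D}{(r-1)c - \eta} +
#'       \frac{\eta}{(r-1)c - \eta},}
#' which at \eqn{\lambda = 0} reduces to
#' \eqn{\gamma = \eta / ((r-1)c - \eta)}; requiring \eqn{\gamma > 0} recovers
#' the zero-regeneration threshold `r > 1 + eta/cost`.
#'
#' @inheritParams eq_densities
#' @param rho_D Defector density (positive).
#' @return `gamma = rho_C / rho_D`, vectorised.
#' @export
coop_defector_ratio <- function(lambda, rho_D, r, cost, eta) {
  if (any(rho_D <= 0)) stop("parameter 'rho_D' must be positive", call. = FALSE)
  den <- (r - 1) * cost - eta
  if (any(abs(den) < 1e-14)) {
    stop("singular at (r - 1) * cost = eta", call. = FALSE)
  }
  -(lambda / rho_D) / den + eta / den
}

#' Invasion payoff of a rare cooperator in an all-defector population
#'
#' At the onset of cooperation the resident population is all defectors at
#' density `rho_D`, the resident game payoff is zero, and a rare cooperator's
#' expected net game payoff over Poisson-distributed group sizes is
#' \deqn{c\left(\frac{r\,(1 - e^{-\rho_D})}{\rho_D} - 1\right).}
#' Its zero in `rho_D = lambda/eta` reproduces [r_star()]; its limit at
#' `rho_D -> 0` is the lone-cooperator surplus `cost * (r - 1)`.
#'
#' @inheritParams coop_defector_ratio
#' @return The expected invasion payoff, vectorised.
#' @export
onset_payoff_identity <- function(rho_D, r, cost) {
  if (any(rho_D < 0)) stop("parameter 'rho_D' must be non-negative",
                           call. = FALSE)
  frac <- ifelse(rho_D < 1e-8,
                 1 - rho_D / 2 + rho_D^2 / 6,
                 -expm1(-rho_D) / rho_D)
  cost * (r * frac - 1)
}

#' Scan equilibrium branches over an enhancement-factor grid
#'
#' Convenience wrapper around [eq_densities()] used by the command-line
#' `theory --scan` interface.
#'
#' @param r_grid Numeric vector of enhancement factors (each > 1).
#' @inheritParams eq_densities
#' @return Tibble of `r`, `branch`, `rho_C`, `rho_D`.
#' @export
eq_scan <- function(r_grid, lambda, eta, cost) {
  eq_densities(lambda, eta, r_grid, cost)[c("r", "branch", "rho_C", "rho_D")]
}
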