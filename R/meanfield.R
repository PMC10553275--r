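#' Mean-field growth rates
#'
#' The dynamical mean-field equation grows each subpopulation at its net
#' per-capita resource gain: with `F_s = pi_s + lambda / (rho_C + rho_D) -
#' eta`,
#' \deqn{\dot\rho_C = (1-\nu) F_C + \nu F_D, \qquad
#'       \dot\rho_D = (1-\nu) F_D + \nu F_C,}
#' which at `nu = 0` is the plain gradient-ascent form. Expected payoffs are
#' the Poisson closed forms of [expected_payoffs_poisson()]. The fixed points
#' of this flow are exactly the equilibrium branches of [eq_densities()].
#'
#' @param rho_C,rho_D Current densities; their sum must be positive.
#' @inheritParams eq_densities
#' @param nu Mutation rate in \[0, 1\] (default 0).
#' @return A named numeric vector `c(dC, dD)`.
#' @examples
#' mf_rhs(2.64288, 0.17856, lambda = 0.6, eta = 0.4, r = 3, cost = 0.1)
#' @export
mf_rhs <- function(rho_C, rho_D, lambda, eta, r, cost, nu = 0) {
  rho <- rho_C + rho_D
  if (rho <= 0) stop("total density must be positive (lambda/rho undefined)",
                     call. = FALSE)
  pay <- poisson_payoffs_raw(rho_C, rho_D, r, cost)
  f_c <- pay$pi_C + lambda / rho - eta
  f_d <- pay$pi_D + lambda / rho - eta
  c(dC = (1 - nu) * f_c + nu * f_d,
    dD = (1 - nu) * f_d + nu * f_c)
}

#' Integrate the mean-field equations
#'
#' Adaptive stiff-capable integration (`deSolve::ode`, method `"lsoda"`)
#' with a non-negativity projection: derivatives are evaluated at the
#' clamped state and a component sitting at zero with a negative derivative
#' is frozen, so the axes are respected.
#'
#' @param rho_C0,rho_D0 Initial densities (sum must be positive).
#' @inheritParams mf_rhs
#' @param t_end Integration horizon (time units of the model step).
#' @param dt_out Output sampling interval.
#' @return A tibble with columns `time`, `rho_C`, `rho_D`.
#' @examples
#' tr <- mf_integrate(0.1, 1.4, lambda = 0.6, eta = 0.4, r = 3, cost = 0.1,
#'                    t_end = 50)
#' tail(tr)
#' @export
mf_integrate <- function(rho_C0, rho_D0, lambda, eta, r, cost, nu = 0,
                         t_end, dt_out = 0.5) {
  if (rho_C0 + rho_D0 <= 0) stop("initial total density must be positive",
                                 call. = FALSE)
  deriv <- function(t, y, parms) {
    yc <- pmax(y, 0)
    dy <- mf_rhs(yc[1], yc[2], lambda, eta, r, cost, nu)
    # continuous non-negativity projection: marginally negative excursions
    # are pulled back to the axis without making the field discontinuous
    neg <- y < 0
    dy[neg] <- dy[neg] - 50 * y[neg]
    list(dy)
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = c(rho_C = rho_C0, rho_D = rho_D0), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) {
    stop("mean-field integration failed; solver diagnostics: ",
         paste(attr(sol, "istate"), collapse = " "), call. = FALSE)
  }
  tibble::tibble(time = sol[, "time"],
                 rho_C = pmax(sol[, "rho_C"], 0),
                 rho_D = pmax(sol[, "rho_D"], 0))
}

# Central-difference Jacobian of the (unclamped) mean-field vector field.
mf_jacobian <- function(rho_C, rho_D, lambda, eta, r, cost, nu = 0,
                        h = 1e-6) {
  f <- function(x) mf_rhs(x[1], x[2], lambda, eta, r, cost, nu)
  x0 <- c(rho_C, rho_D)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

# Newton iteration for a root of the mean-field vector field.
mf_newton <- function(x0, lambda, eta, r, cost, nu, tol = 1e-12,
                      max_iter = 60) {
  x <- x0
  for (i in seq_len(max_iter)) {
    fx <- mf_rhs(x[1], x[2], lambda, eta, r, cost, nu)
    if (max(abs(fx)) < tol) {
      return(list(x = x, converged = TRUE))
    }
    J <- mf_jacobian(x[1], x[2], lambda, eta, r, cost, nu)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, converged = FALSE))
    x <- x - step
    if (any(!is.finite(x)) || sum(x) <= 0) {
      return(list(x = x0, converged = FALSE))
    }
  }
  fx <- mf_rhs(x[1], x[2], lambda, eta, r, cost, nu)
  list(x = x, converged = max(abs(fx)) < 1e-8)
}

#' Fixed points of the mean-field flow and their stability
#'
#' Locates the boundary fixed points (defectors-only and cooperators-only,
#' matching equilibrium branches I and III) and the interior coexistence
#' fixed point (branch II), seeded from the closed-form equilibrium theory
#' and polished by Newton iteration. Stability is judged from the
#' central-difference Jacobian (step `h`).
#'
#' For `nu = 0`, boundary points are fixed points of the flow restricted to
#' their axis; the tibble reports the along-axis eigenvalue (`eig_re_1`) and
#' the transverse growth rate of the absent type (`transverse`, the rate at
#' which the missing strategy would increase at that point). A boundary
#' point is stable when both are negative. Interior rows report the complex
#' eigenvalue pair of the full Jacobian.
#'
#' With `nu > 0` the axes are no longer invariant and — since any fixed
#' point of the mutation-mixed flow requires both per-capita net gains to
#' vanish simultaneously — only genuine fixed points (the coexistence point,
#' which is exactly `nu`-independent) are returned; single-strategy states
#' survive only as projected equilibria of the clamped flow, visible with
#' [mf_integrate()].
#'
#' @inheritParams mf_rhs
#' @param h Finite-difference step for the Jacobian (default `1e-6`).
#' @return A tibble with columns `kind` (`"boundary_D"`, `"boundary_C"`,
#'   `"interior"`), `rho_C`, `rho_D`, `eig_re_1`, `eig_im_1`, `eig_re_2`,
#'   `eig_im_2`, `max_re`, `transverse`, `stable`, `converged`.
#' @examples
#' mf_fixed_points(lambda = 0.6, eta = 0.4, r = 3, cost = 0.1)
#' @export
mf_fixed_points <- function(lambda, eta, r, cost, nu = 0, h = 1e-6) {
  rows <- list()
  w <- lambert_w0(-r * exp(-r))
  rho_tot2 <- r + w
  rho_c2 <- (-lambda + r * eta + eta * w) / (cost * (r - 1))
  rho_d2 <- rho_tot2 - rho_c2

  # defectors-only boundary (branch I); exists for lambda > 0
  if (lambda > 0) {
    bd <- c(0, lambda / eta)
    keep <- TRUE
    if (nu > 0) {
      # with mutation the axis is no longer invariant: keep the point only
      # if a genuine fixed point persists nearby (transversally stable side)
      ns <- mf_newton(bd + c(1e-4, 0), lambda, eta, r, cost, nu)
      if (ns$converged && ns$x[1] >= 0 && ns$x[1] < 0.2 * ns$x[2]) bd <- ns$x
      else keep <- FALSE
    }
    if (keep) {
      rows[[length(rows) + 1L]] <-
        fp_row("boundary_D", bd, lambda, eta, r, cost, nu, h)
    }
  }

  # cooperators-only boundary (branch III); finite when eta > (r-1) cost
  if (lambda > 0 && eta > (r - 1) * cost) {
    bc <- c(lambda / (eta - (r - 1) * cost), 0)
    keep <- TRUE
    if (nu > 0) {
      ns <- mf_newton(bc + c(0, 1e-4), lambda, eta, r, cost, nu)
      if (ns$converged && ns$x[2] >= 0 && ns$x[2] < 0.2 * ns$x[1]) bc <- ns$x
      else keep <- FALSE
    }
    if (keep) {
      rows[[length(rows) + 1L]] <-
        fp_row("boundary_C", bc, lambda, eta, r, cost, nu, h)
    }
  }

  # interior coexistence point (branch II)
  if (rho_c2 > 0 && rho_d2 > 0) {
    ns <- mf_newton(c(rho_c2, rho_d2), lambda, eta, r, cost, nu)
    rows[[length(rows) + 1L]] <-
      fp_row("interior", ns$x, lambda, eta, r, cost, nu, h,
             converged = ns$converged)
  }
  proto <- tibble::tibble(
    kind = character(0), rho_C = numeric(0), rho_D = numeric(0),
    eig_re_1 = numeric(0), eig_im_1 = numeric(0), eig_re_2 = numeric(0),
    eig_im_2 = numeric(0), max_re = numeric(0), transverse = numeric(0),
    stable = logical(0), converged = logical(0)
  )
  dplyr::bind_rows(proto, !!!rows)
}

fp_row <- function(kind, x, lambda, eta, r, cost, nu, h, converged = TRUE) {
  J <- mf_jacobian(x[1], x[2], lambda, eta, r, cost, nu, h = h)
  f <- mf_rhs(x[1], x[2], lambda, eta, r, cost, nu)
  if (kind == "interior" || nu > 0) {
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    max_re <- max(Re(ev))
    transverse <- NA_real_
    stable <- max_re < 0
    re1 <- Re(ev[1]); im1 <- Im(ev[1]); re2 <- Re(ev[2]); im2 <- Im(ev[2])
  } else {
    # nu = 0 boundary: along-axis derivative + transverse invasion rate
    axis <- if (kind == "boundary_D") 2L else 1L
    re1 <- J[axis, axis]; im1 <- 0
    re2 <- NA_real_; im2 <- NA_real_
    transverse <- f[if (kind == "boundary_D") 1L else 2L]
    max_re <- re1
    stable <- re1 < 0 && transverse < 0
  }
  tibble::tibble(kind = kind, rho_C = x[1], rho_D = x[2],
                 eig_re_1 = re1, eig_im_1 = im1,
                 eig_re_2 = re2, eig_im_2 = im2,
                 max_re = max_re, transverse = transverse,
                 stable = stable, converged = converged)
}

# Max real part of the interior fixed point's eigenvalues as a function of r;
# NA when no interior point exists.
interior_max_re <- function(r, lambda, eta, cost, nu) {
  fps <- mf_fixed_points(lambda, eta, r, cost, nu)
  row <- fps[fps$kind == "interior", ]
  if (nrow(row) == 0L || !row$converged) return(NA_real_)
  row$max_re
}

#' Onset of non-equilibrium fluctuations
#'
#' As the enhancement factor grows, the interior (coexistence) fixed point
#' of the mean-field flow loses stability and sustained oscillations set in.
#' This locates the critical `r_c` where the largest real part of the
#' interior Jacobian eigenvalues crosses zero, by bisection on `r`.
#'
#' @inheritParams mf_rhs
#' @param r_lo,r_hi Bracket for the crossing; the interior fixed point must
#'   exist at both ends and the eigenvalue real part must change sign.
#' @param tol Bisection tolerance on `r` (default `1e-4`).
#' @return The critical enhancement factor `r_c`.
#' @examples
#' \donttest{
#' mf_fluctuation_onset(lambda = 0.6, eta = 0.4, cost = 0.1,
#'                      r_lo = 2, r_hi = 8)
#' }
#' @export
mf_fluctuation_onset <- function(lambda, eta, cost, nu = 0, r_lo, r_hi,
                                 tol = 1e-4) {
  f <- function(r) interior_max_re(r, lambda, eta, cost, nu)
  f_lo <- f(r_lo); f_hi <- f(r_hi)
  if (is.na(f_lo) || is.na(f_hi)) {
    stop(sprintf(paste("interior fixed point missing at a bracket end:",
                       "f(%g)=%s, f(%g)=%s"),
                 r_lo, format(f_lo), r_hi, format(f_hi)), call. = FALSE)
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste("no sign change of the leading eigenvalue in",
                       "[%g, %g]: f_lo=%.3g, f_hi=%.3g"),
                 r_lo, r_hi, f_lo, f_hi), call. = FALSE)
  }
  stats::uniroot(f, c(r_lo, r_hi), tol = tol)$root
}

#' Mean-field phase diagram over an (r, lambda/eta) grid
#'
#' Classifies each grid point from the closed-form theory plus the linear
#' stability of the interior fixed point: `"no_cooperation"` below the onset
#' [r_star()], `"full_cooperation"` on branch III, and coexistence split
#' into `"coexistence_equilibrium"` / `"coexistence_fluctuating"` by the
#' sign of the leading interior eigenvalue. The no-cooperation boundary
#' depends only on the ratio `lambda/eta`.
#'
#' @param r_grid Enhancement factors (> 1).
#' @param ratio_grid Values of `lambda/eta`.
#' @inheritParams mf_rhs
#' @return A tibble of `r`, `ratio`, `lambda`, `eta`, `branch`, `phase`,
#'   `max_re`.
#' @export
mf_phase_diagram <- function(r_grid, ratio_grid, eta, cost, nu = 0) {
  grid <- tidyr::expand_grid(r = r_grid, ratio = ratio_grid)
  purrr::pmap_dfr(grid, function(r, ratio) {
    lambda <- ratio * eta
    eq <- eq_densities(lambda, eta, r, cost)
    max_re <- NA_real_
    if (eq$branch == "II") {
      max_re <- interior_max_re(r, lambda, eta, cost, nu)
    }
    phase <- if (eq$branch == "I") "no_cooperation"
             else if (eq$branch == "III") "full_cooperation"
             else if (!is.na(max_re) && max_re > 0) "coexistence_fluctuating"
             else "coexistence_equilibrium"
    tibble::tibble(r = r, ratio = ratio, lambda = lambda, eta = eta,
                   branch = eq$branch, phase = phase, max_re = max_re)
  })
}
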