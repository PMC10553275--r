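#' Simulation parameters
#'
#' Construct and validate the full parameter record of the resource-flow
#' model. Every rate is in energy units per time step; densities derived from
#' a run are counts per lattice site.
#'
#' @param lambda Basal-resource regeneration rate per lattice site per step
#'   (non-negative). Each site's standing stock increases by `lambda` at the
#'   end of every step.
#' @param eta Metabolic rate: energy every individual dissipates per step
#'   (positive). An individual whose internal energy drops below zero after
#'   paying `eta` dies.
#' @param d Reproduction threshold (positive). An individual whose energy
#'   strictly exceeds `d` divides, sharing its energy equally with the
#'   offspring.
#' @param r Public-goods enhancement factor (> 1): pooled investments are
#'   multiplied by `r` before being shared equally by all group members.
#' @param cost Cost `c` each cooperator invests per step (positive).
#' @param nu Mutation probability per birth, in \[0, 1\]: the offspring's
#'   inherited strategy is flipped with probability `nu`.
#' @param q Movement probability per individual per step, in \[0, 1\].
#' @param L Lattice side length (positive integer); the world has `L^2` sites.
#' @param topology `"mixed"` (every site connected to every site) or
#'   `"lattice_moore"` (8-neighbour Moore lattice with periodic boundaries).
#' @param steps Number of time steps `T` to simulate (positive integer).
#' @param burn_in Steps discarded before time averaging (non-negative,
#'   `< steps`).
#' @param seed Non-negative integer seed for the run's random generator.
#' @param init_pop Number of founding individuals (positive integer).
#' @param init_energy Founder (and rescue-immigrant) internal energy;
#'   defaults to `d / 2`. Values `>= d` are allowed but warned about, since
#'   founders then divide at the first step.
#'
#' @return A validated list of class `"ecoflow_params"`.
#' @examples
#' p <- sim_params(lambda = 0.6, eta = 0.4, r = 3, steps = 100)
#' p$r
#' @export
sim_params <- function(lambda = 0.6, eta = 0.4, d = 2, r = 2, cost = 0.1,
                       nu = 1e-4, q = 1, L = 100,
                       topology = c("mixed", "lattice_moore"),
                       steps = 10000L, burn_in = 2000L, seed = 1L,
                       init_pop = 100L, init_energy = d / 2) {
  topology <- match.arg(topology)
  p <- list(
    lambda = lambda, eta = eta, d = d, r = r, cost = cost, nu = nu, q = q,
    L = L, topology = topology, steps = steps, burn_in = burn_in,
    seed = seed, init_pop = init_pop, init_energy = init_energy
  )
  class(p) <- "ecoflow_params"
  validate_params(p)
  for (f in c("L", "steps", "burn_in", "seed", "init_pop")) {
    p[[f]] <- as.integer(p[[f]])
  }
  p
}

#' @keywords internal
#' @noRd
check_num <- function(x, field, lo = -Inf, hi = Inf, strict_lo = FALSE,
                      integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", field),
         call. = FALSE)
  }
  if (x < lo || (strict_lo && x == lo) || x > hi) {
    stop(sprintf("parameter '%s' = %g out of range %s%g, %g]",
                 field, x, if (strict_lo) "(" else "[", lo, hi),
         call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("parameter '%s' must be an integer", field), call. = FALSE)
  }
  invisible(x)
}

#' Validate a parameter record
#'
#' Checks every field range and cross-field invariant of an
#' [sim_params()] record; errors name the offending field.
#'
#' @param p An `"ecoflow_params"` list.
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_params <- function(p) {
  check_num(p$lambda, "lambda", lo = 0)
  check_num(p$eta, "eta", lo = 0, strict_lo = TRUE)
  check_num(p$d, "d", lo = 0, strict_lo = TRUE)
  check_num(p$r, "r", lo = 1, strict_lo = TRUE)
  check_num(p$cost, "cost", lo = 0, strict_lo = TRUE)
  check_num(p$nu, "nu", lo = 0, hi = 1)
  check_num(p$q, "q", lo = 0, hi = 1)
  check_num(p$L, "L", lo = 1, integerish = TRUE)
  check_num(p$steps, "steps", lo = 1, integerish = TRUE)
  check_num(p$burn_in, "burn_in", lo = 0, integerish = TRUE)
  check_num(p$seed, "seed", lo = 0, integerish = TRUE)
  check_num(p$init_pop, "init_pop", lo = 1, integerish = TRUE)
  check_num(p$init_energy, "init_energy", lo = 0, strict_lo = TRUE)
  if (!p$topology %in% c("mixed", "lattice_moore")) {
    stop("parameter 'topology' must be \"mixed\" or \"lattice_moore\"",
         call. = FALSE)
  }
  if (p$burn_in >= p$steps) {
    stop("parameter 'burn_in' must be smaller than 'steps'", call. = FALSE)
  }
  if (p$init_energy >= p$d) {
    warning("init_energy >= d: founders divide immediately at t = 1",
            call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ecoflow_params <- function(x, ...) {
  cat("<ecoflow_params>\n")
  cat(sprintf("  lambda=%g eta=%g d=%g r=%g cost=%g nu=%g q=%g\n",
              x$lambda, x$eta, x$d, x$r, x$cost, x$nu, x$q))
  cat(sprintf("  %s L=%d (%d sites), steps=%d burn_in=%d seed=%d\n",
              x$topology, x$L, x$L^2, x$steps, x$burn_in, x$seed))
  cat(sprintf("  init_pop=%d init_energy=%g\n", x$init_pop, x$init_energy))
  invisible(x)
}
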