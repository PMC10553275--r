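#' @title World state of the resource-flow simulation
#' @description
#' The world is a plain list holding the lattice of basal-resource stocks and
#' the agent population as parallel vectors (`id`, `is_c`, `energy`, `site`,
#' `birth`), the current time `t`, and a snapshot of the random generator
#' state so that every stage is reproducible. Sites are indexed `1..L^2`,
#' row-major: site `s` sits at `x = (s-1) %% L`, `y = (s-1) %/% L`.
#' @name ecoflow_world
NULL

rng_restore <- function(world) {
  assign(".Random.seed", world$rng, envir = globalenv())
  invisible(NULL)
}

rng_save <- function(world) {
  # force the argument before reading the generator state: callers pass
  # unevaluated stage expressions whose draws must land first
  force(world)
  world$rng <- get(".Random.seed", envir = globalenv())
  world
}

#' Initialise a simulation world
#'
#' Founds the population on an empty lattice: `init_pop` agents, all
#' defectors unless `init_coop_frac > 0`, each placed on an independently
#' uniform random site with energy `init_energy`; all basal stocks start at
#' zero and `t = 0`. The world's random generator is seeded from
#' `params$seed`, and all later stochastic stages draw from it in a fixed
#' order (agents in id order), so runs are bitwise reproducible.
#'
#' @param params An [sim_params()] record.
#' @param init_coop_frac Fraction of founders initialised as cooperators
#'   (default 0: the all-defector start used throughout).
#' @return A world list; see [ecoflow_world].
#' @export
init_world <- function(params, init_coop_frac = 0) {
  validate_params(params)
  if (init_coop_frac < 0 || init_coop_frac > 1) {
    stop("parameter 'init_coop_frac' must lie in [0, 1]", call. = FALSE)
  }
  n_sites <- params$L^2
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(params$seed, kind = "Mersenne-Twister")
  n0 <- params$init_pop
  n_c0 <- round(init_coop_frac * n0)
  world <- list(
    t = 0L,
    L = params$L,
    n_sites = n_sites,
    stock = numeric(n_sites),
    id = seq_len(n0),
    is_c = seq_len(n0) <= n_c0,
    energy = rep(params$init_energy, n0),
    site = sample.int(n_sites, n0, replace = TRUE),
    birth = integer(n0),
    kappa = numeric(n0),
    payoff = numeric(n0),
    next_id = n0 + 1L
  )
  world <- rng_save(world)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  world
}

# --- internal stages (no RNG bookkeeping; used by the run loop) -------------

gather_impl <- function(world, params) {
  n <- length(world$site)
  if (n == 0L) {
    world$gather <- list(N_C = 0L, N_D = 0L, payoff_C = NA_real_,
                         payoff_D = NA_real_, basal_C = NA_real_,
                         basal_D = NA_real_, consumed = 0, n_C_played = 0L)
    return(world)
  }
  occ <- world$site
  cnt <- tabulate(occ, nbins = world$n_sites)
  n_c <- sum(world$is_c)
  nc_site <- if (n_c > 0L) tabulate(occ[world$is_c], nbins = world$n_sites)
             else integer(world$n_sites)
  share <- world$stock[occ] / cnt[occ]
  pay <- params$r * params$cost * (nc_site[occ] / cnt[occ]) -
    params$cost * world$is_c
  occupied <- cnt > 0L
  consumed <- sum(world$stock[occupied])
  world$stock[occupied] <- 0
  world$energy <- world$energy + share + pay
  world$kappa <- share
  world$payoff <- pay
  world$gather <- list(
    N_C = n_c, N_D = n - n_c,
    payoff_C = if (n_c > 0L) sum(pay[world$is_c]) / n_c else NA_real_,
    payoff_D = if (n_c < n) sum(pay[!world$is_c]) / (n - n_c) else NA_real_,
    basal_C = if (n_c > 0L) sum(share[world$is_c]) / n_c else NA_real_,
    basal_D = if (n_c < n) sum(share[!world$is_c]) / (n - n_c) else NA_real_,
    consumed = consumed, n_C_played = n_c
  )
  world
}

reproduce_impl <- function(world, params, t_birth) {
  rep_i <- which(world$energy > params$d)
  nb <- length(rep_i)
  if (nb == 0L) {
    world$births <- list(parent_id = integer(0), child_id = integer(0),
                         child_c = logical(0), by_parent_C = 0L,
                         by_parent_D = 0L)
    return(world)
  }
  half <- world$energy[rep_i] / 2
  world$energy[rep_i] <- half
  parent_c <- world$is_c[rep_i]
  child_c <- parent_c
  if (params$nu > 0) {
    child_c <- xor(child_c, stats::runif(nb) < params$nu)
  }
  child_id <- seq.int(world$next_id, length.out = nb)
  world$next_id <- world$next_id + nb
  world$id <- c(world$id, child_id)
  world$is_c <- c(world$is_c, child_c)
  world$energy <- c(world$energy, half)
  world$site <- c(world$site, world$site[rep_i])
  world$birth <- c(world$birth, rep.int(t_birth, nb))
  world$kappa <- c(world$kappa, numeric(nb))
  world$payoff <- c(world$payoff, numeric(nb))
  world$births <- list(parent_id = world$id[rep_i], child_id = child_id,
                       child_c = child_c, by_parent_C = sum(parent_c),
                       by_parent_D = nb - sum(parent_c))
  world
}

move_impl <- function(world, params) {
  n <- length(world$site)
  if (n == 0L || params$q == 0) return(world)
  idx <- if (params$q >= 1) seq_len(n) else which(stats::runif(n) < params$q)
  nm <- length(idx)
  if (nm == 0L) return(world)
  if (params$topology == "mixed") {
    world$site[idx] <- sample.int(world$n_sites, nm, replace = TRUE)
  } else {
    off <- sample.int(8L, nm, replace = TRUE)
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)[off]
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)[off]
    s0 <- world$site[idx] - 1L
    L <- world$L
    x <- (s0 %% L + dx) %% L
    y <- (s0 %/% L + dy) %% L
    world$site[idx] <- x + L * y + 1L
  }
  world
}

cull_impl <- function(world, params, t_death) {
  n <- length(world$site)
  world$energy <- world$energy - params$eta
  dead <- world$energy < 0
  nd <- sum(dead)
  deaths <- list(
    strategy = world$is_c[dead],
    birth_time = world$birth[dead],
    death_time = rep.int(t_death, nd),
    deaths_C = sum(world$is_c[dead]),
    deaths_D = nd - sum(world$is_c[dead]),
    residual = sum(world$energy[dead]),
    n_at_cull = n,
    immigration = FALSE,
    immigrant_energy = 0
  )
  if (nd > 0L) {
    keep <- !dead
    world$id <- world$id[keep]
    world$is_c <- world$is_c[keep]
    world$energy <- world$energy[keep]
    world$site <- world$site[keep]
    world$birth <- world$birth[keep]
    world$kappa <- world$kappa[keep]
    world$payoff <- world$payoff[keep]
  }
  if (length(world$site) == 0L) {
    # extinction rescue: one immigrant with a uniform random strategy
    world$id <- world$next_id
    world$next_id <- world$next_id + 1L
    world$is_c <- stats::runif(1) < 0.5
    world$energy <- params$init_energy
    world$site <- sample.int(world$n_sites, 1L)
    world$birth <- t_death
    world$kappa <- 0
    world$payoff <- 0
    deaths$immigration <- TRUE
    deaths$immigrant_energy <- params$init_energy
  }
  world$deaths <- deaths
  world
}

regen_impl <- function(world, params) {
  world$stock <- world$stock + params$lambda
  world
}

step_impl <- function(world, params, ledger = FALSE) {
  t_new <- world$t + 1L
  if (ledger) e_start <- sum(world$energy) + sum(world$stock)
  world <- gather_impl(world, params)
  world <- reproduce_impl(world, params, t_birth = t_new)
  world <- move_impl(world, params)
  world <- cull_impl(world, params, t_death = t_new)
  world <- regen_impl(world, params)
  world$t <- t_new
  n <- length(world$site)
  n_c <- sum(world$is_c)
  g <- world$gather
  d <- world$deaths
  rho_c <- n_c / world$n_sites
  rho_d <- (n - n_c) / world$n_sites
  rho <- rho_c + rho_d
  rec <- c(
    t = t_new, N_C = n_c, N_D = n - n_c,
    rho = rho, rho_C = rho_c, rho_D = rho_d,
    m = if (rho > 0) rho_c / rho else 0,
    payoff_C = g$payoff_C, payoff_D = g$payoff_D,
    basal_C = g$basal_C, basal_D = g$basal_D,
    births_C = world$births$by_parent_C, births_D = world$births$by_parent_D,
    deaths_C = d$deaths_C, deaths_D = d$deaths_D,
    mean_energy = if (n > 0) sum(world$energy) / n else NA_real_,
    immigration = as.numeric(d$immigration),
    N_C_gather = g$N_C, N_D_gather = g$N_D
  )
  if (ledger) {
    rec <- c(rec,
             energy_start = e_start,
             energy_end = sum(world$energy) + sum(world$stock),
             game_production = (params$r - 1) * params$cost * g$n_C_played,
             basal_inflow = params$lambda * world$n_sites,
             metabolic = params$eta * d$n_at_cull,
             residual_dead = d$residual,
             immigrant_energy = d$immigrant_energy)
  }
  world$record <- rec
  world
}

# --- exported stage wrappers (spec module surface) --------------------------

#' Resource gathering and game stage
#'
#' Each occupied site's entire standing basal stock is split equally among
#' its occupants (the stock is set to zero; unoccupied sites keep
#' accumulating), and every site's occupants play one round of the public
#' goods game. Each agent's energy increases by its basal share plus its
#' game payoff. No births, deaths or moves occur here.
#'
#' @param world A world from [init_world()].
#' @param params The matching [sim_params()] record.
#' @return The updated world; per-agent shares and payoffs are stored in
#'   `world$kappa` / `world$payoff` and per-strategy means in `world$gather`.
#' @export
stage_gather_and_play <- function(world, params) {
  rng_restore(world)
  rng_save(gather_impl(world, params))
}

#' Reproduction stage
#'
#' Every agent whose energy strictly exceeds the threshold `d` divides once:
#' parent and offspring each keep half the energy, the offspring is placed on
#' the parent's site with the parent's strategy, flipped with probability
#' `nu`. Offspring are full agents immediately (they move and pay the
#' metabolic cost in the same step).
#'
#' @inheritParams stage_gather_and_play
#' @return The updated world; `world$births` records parent/child ids and
#'   child strategies for this stage.
#' @export
stage_reproduce <- function(world, params) {
  rng_restore(world)
  rng_save(reproduce_impl(world, params, t_birth = world$t + 1L))
}

#' Movement stage
#'
#' Independently, each agent (newborns included) relocates with probability
#' `q`: on the Moore lattice to one of its 8 neighbours chosen uniformly
#' (periodic boundaries); in the mixed population to a site chosen uniformly
#' among all `L^2` sites (the current one included).
#'
#' @inheritParams stage_gather_and_play
#' @return The updated world.
#' @export
stage_move <- function(world, params) {
  rng_restore(world)
  rng_save(move_impl(world, params))
}

#' Metabolism and death stage
#'
#' Every agent pays the metabolic cost `eta`; agents whose energy is then
#' strictly below zero die and are removed, each emitting a lifespan event.
#' If the population is left empty, a single immigrant with a uniform random
#' strategy, a uniform random site and energy `init_energy` rescues it.
#'
#' @inheritParams stage_gather_and_play
#' @return The updated world; `world$deaths` holds the death records and the
#'   immigration flag.
#' @export
stage_metabolize_and_cull <- function(world, params) {
  rng_restore(world)
  rng_save(cull_impl(world, params, t_death = world$t + 1L))
}

#' Resource regeneration stage
#'
#' Every site's basal stock increases by `lambda`; nothing else changes.
#'
#' @inheritParams stage_gather_and_play
#' @return The updated world.
#' @export
stage_regenerate <- function(world, params) {
  rng_restore(world)
  rng_save(regen_impl(world, params))
}

#' Advance the world by one full time step
#'
#' Applies the five stages in their fixed order — gather + play, reproduce,
#' move, metabolize + cull, regenerate — and increments `t`. Per-strategy
#' payoff and basal means in the step record average over the agents alive
#' at the gather stage; birth counts are attributed to the parent's strategy.
#'
#' @inheritParams stage_gather_and_play
#' @param ledger If `TRUE`, the step record additionally carries the energy
#'   bookkeeping terms (total energy before/after, game production, basal
#'   inflow, metabolic drain, residual energy removed with the dead,
#'   immigrant energy) for conservation checks.
#' @return A list with elements `world`, `record` (named numeric vector) and
#'   `deaths` (a tibble of lifespan events for this step).
#' @export
step_world <- function(world, params, ledger = FALSE) {
  rng_restore(world)
  world <- rng_save(step_impl(world, params, ledger = ledger))
  d <- world$deaths
  deaths <- tibble::tibble(
    strategy = ifelse(d$strategy, "C", "D"),
    birth_time = d$birth_time,
    death_time = d$death_time,
    lifespan = d$death_time - d$birth_time
  )
  list(world = world, record = world$record, deaths = deaths)
}

#' Run a full simulation
#'
#' Executes `params$steps` time steps from [init_world()], recording one row
#' per step plus every death event. Fully reproducible: the same parameters
#' and seed give bitwise-identical output.
#'
#' @inheritParams init_world
#' @param snapshot_every If a positive integer, per-site cooperator/defector
#'   count grids are stored every that many steps.
#' @param ledger If `TRUE`, per-step energy bookkeeping terms are included in
#'   the time series (see [step_world()]).
#' @param progress_every If a positive integer, a progress line (step and
#'   population size) is written to stderr every that many steps.
#' @return An object of class `"ecoflow_sim"`: a list with
#'   \describe{
#'     \item{steps}{tibble, one row per step (densities, fraction of
#'       cooperators `m`, per-strategy mean payoffs and basal gains, birth and
#'       death counts, mean energy, immigration flag).}
#'     \item{lifespans}{tibble of death events: strategy, birth_time,
#'       death_time, lifespan.}
#'     \item{snapshots}{list of per-site count grids (or `NULL`).}
#'     \item{params}{the parameter record.}
#'   }
#' @examples
#' \donttest{
#' sim <- run_sim(sim_params(r = 3, L = 30, steps = 200, burn_in = 100,
#'                           nu = 1e-3, seed = 42))
#' glance(sim)
#' }
#' @export
run_sim <- function(params, init_coop_frac = 0, snapshot_every = NULL,
                    ledger = FALSE, progress_every = NULL) {
  world <- init_world(params, init_coop_frac = init_coop_frac)
  rng_restore(world)
  T_ <- params$steps
  ncol_rec <- if (ledger) 26L else 19L
  recs <- matrix(NA_real_, nrow = T_, ncol = ncol_rec)
  death_strat <- vector("list", T_)
  death_birth <- vector("list", T_)
  snaps <- if (!is.null(snapshot_every)) list() else NULL
  for (t in seq_len(T_)) {
    world <- step_impl(world, params, ledger = ledger)
    recs[t, ] <- world$record
    if (length(world$deaths$birth_time)) {
      death_strat[[t]] <- world$deaths$strategy
      death_birth[[t]] <- world$deaths$birth_time
    }
    if (!is.null(snapshot_every) && t %% snapshot_every == 0L) {
      snaps[[length(snaps) + 1L]] <- snapshot_grid(world)
    }
    if (!is.null(progress_every) && t %% progress_every == 0L) {
      message(sprintf("[ecoflow] step %d/%d: N=%d (C: %d)",
                      t, T_, length(world$site), sum(world$is_c)))
    }
  }
  world <- rng_save(world)
  colnames(recs) <- names(world$record)
  steps <- tibble::as_tibble(recs)
  steps$t <- as.integer(steps$t)
  db <- unlist(death_birth, use.names = FALSE)
  if (is.null(db)) db <- integer(0)
  dt <- rep.int(seq_len(T_), vapply(death_birth, length, 1L))
  ds <- unlist(death_strat, use.names = FALSE)
  if (is.null(ds)) ds <- logical(0)
  lifespans <- tibble::tibble(
    strategy = ifelse(ds, "C", "D"),
    birth_time = db,
    death_time = dt,
    lifespan = dt - db
  )
  structure(list(steps = steps, lifespans = lifespans, snapshots = snaps,
                 params = params, final_world = world),
            class = "ecoflow_sim")
}

snapshot_grid <- function(world) {
  n_c <- tabulate(world$site[world$is_c], nbins = world$n_sites)
  n_all <- tabulate(world$site, nbins = world$n_sites)
  list(t = world$t,
       n_C = matrix(n_c, world$L, world$L, byrow = TRUE),
       n_D = matrix(n_all - n_c, world$L, world$L, byrow = TRUE))
}

#' @export
print.ecoflow_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("<ecoflow_sim> %d steps, %s topology, L=%d\n",
              p$steps, p$topology, p$L))
  cat(sprintf("  lambda=%g eta=%g d=%g r=%g cost=%g nu=%g q=%g seed=%d\n",
              p$lambda, p$eta, p$d, p$r, p$cost, p$nu, p$q, p$seed))
  last <- x$steps[nrow(x$steps), ]
  cat(sprintf("  final: N=%d (C: %d, D: %d), rho=%.3f, m=%.3f\n",
              last$N_C + last$N_D, last$N_C, last$N_D, last$rho, last$m))
  invisible(x)
}

#' Tidy a simulation into its per-step time series
#'
#' @param x An `"ecoflow_sim"` object.
#' @param ... Unused.
#' @return The per-step tibble (one row per time step).
#' @method tidy ecoflow_sim
#' @export
tidy.ecoflow_sim <- function(x, ...) x$steps

#' One-row summary of a simulation
#'
#' Time-averaged observables over the post-burn-in window; see
#' [summarize_run()].
#'
#' @param x An `"ecoflow_sim"` object.
#' @param ... Passed to [summarize_run()].
#' @return A one-row tibble.
#' @method glance ecoflow_sim
#' @export
glance.ecoflow_sim <- function(x, ...) summarize_run(x, ...)
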