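#' Time-averaged summary of a simulation window
#'
#' Arithmetic time averages of the per-step observables over steps
#' `t > burn_in`: densities, fraction of cooperators `m`, per-strategy mean
#' game payoffs and basal gains, per-capita birth and death rates
#' (per-step counts divided by the strategy's population at the gather
#' stage, then time-averaged), mean lifespans of deaths occurring after the
#' burn-in, and an oscillation flag based on the coefficient of variation of
#' the cooperator density over the window.
#'
#' Steps on which a strategy is absent contribute nothing to that strategy's
#' payoff/basal/rate averages; a strategy absent from the entire window gets
#' rate 0 and is flagged in `absent_C` / `absent_D`.
#'
#' @param sim An `"ecoflow_sim"` object from [run_sim()], or a per-step
#'   tibble (in which case `lifespans` must be given separately).
#' @param lifespans Tibble of death events; taken from `sim` when omitted.
#' @param burn_in Steps to discard (default: the run's `burn_in` parameter).
#' @param osc_threshold Coefficient-of-variation cutoff above which the
#'   window is flagged as oscillating (default 0.15).
#' @return A one-row tibble of time-averaged observables.
#' @export
summarize_run <- function(sim, lifespans = NULL, burn_in = NULL,
                          osc_threshold = 0.15) {
  if (inherits(sim, "ecoflow_sim")) {
    steps <- sim$steps
    if (is.null(lifespans)) lifespans <- sim$lifespans
    if (is.null(burn_in)) burn_in <- sim$params$burn_in
  } else {
    steps <- sim
    if (is.null(burn_in)) burn_in <- 0L
    if (is.null(lifespans)) {
      lifespans <- tibble::tibble(strategy = character(0),
                                  birth_time = integer(0),
                                  death_time = integer(0),
                                  lifespan = integer(0))
    }
  }
  w <- dplyr::filter(steps, .data$t > burn_in)
  if (nrow(w) == 0L) stop("empty averaging window: burn_in >= run length",
                          call. = FALSE)
  rate <- function(count, denom) {
    ok <- denom > 0
    if (!any(ok)) return(0)
    mean(count[ok] / denom[ok])
  }
  mean_present <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  cv <- if (mean(w$rho_C) > 0) stats::sd(w$rho_C) / mean(w$rho_C) else 0
  ls_w <- dplyr::filter(lifespans, .data$death_time > burn_in)
  tau <- function(s) {
    x <- ls_w$lifespan[ls_w$strategy == s]
    if (length(x) == 0L) NA_real_ else mean(x)
  }
  tibble::tibble(
    t_start = burn_in + 1L, t_end = max(w$t), n_steps = nrow(w),
    rho = mean(w$rho), rho_C = mean(w$rho_C), rho_D = mean(w$rho_D),
    m = mean(w$m),
    payoff_C = mean_present(w$payoff_C), payoff_D = mean_present(w$payoff_D),
    basal_C = mean_present(w$basal_C), basal_D = mean_present(w$basal_D),
    b_C = rate(w$births_C, w$N_C_gather),
    b_D = rate(w$births_D, w$N_D_gather),
    death_rate_C = rate(w$deaths_C, w$N_C_gather),
    death_rate_D = rate(w$deaths_D, w$N_D_gather),
    lifespan_C = tau("C"), lifespan_D = tau("D"),
    absent_C = all(w$N_C_gather == 0), absent_D = all(w$N_D_gather == 0),
    oscillation_metric = cv, oscillation = cv > osc_threshold
  )
}

#' Lifespan distribution with exponential-tail fit
#'
#' Unit-age histogram of the lifespans of one strategy's deaths after the
#' burn-in, with the decay rate of the distribution's exponential tail
#' fitted by least squares on log counts over the upper half of the occupied
#' bins (bins with at least `min_tail_count` deaths). At least 30 death
#' events are required for a tail fit; below that the histogram is returned
#' with `tail_decay_rate = NA` and `tail_fitted = FALSE`.
#'
#' @param lifespans Tibble of death events (as in [run_sim()] output).
#' @param strategy `"C"` or `"D"`.
#' @param burn_in Only deaths with `death_time > burn_in` are counted.
#' @param min_tail_count Minimum bin count for a bin to enter the tail fit.
#' @return An object of class `"ecoflow_lifespan"`: list with `strategy`,
#'   `hist` (tibble of `age`, `count`), `n`, `tail_decay_rate` (per step;
#'   positive means decaying), `tail_fitted`.
#' @export
lifespan_distribution <- function(lifespans, strategy, burn_in = 0,
                                  min_tail_count = 5) {
  x <- lifespans$lifespan[lifespans$strategy == strategy &
                            lifespans$death_time > burn_in]
  n <- length(x)
  if (n == 0L) {
    return(structure(list(strategy = strategy,
                          hist = tibble::tibble(age = integer(0),
                                                count = integer(0)),
                          n = 0L, tail_decay_rate = NA_real_,
                          tail_fitted = FALSE),
                     class = "ecoflow_lifespan"))
  }
  ages <- seq.int(min(x), max(x))
  counts <- tabulate(x - min(x) + 1L, nbins = length(ages))
  hist <- tibble::tibble(age = ages, count = counts)
  rate <- NA_real_
  fitted <- FALSE
  occ <- hist[hist$count >= min_tail_count, ]
  if (n >= 30L && nrow(occ) >= 4L) {
    upper <- occ[occ$age >= stats::median(occ$age), ]
    if (nrow(upper) >= 3L && length(unique(upper$age)) >= 3L) {
      fit <- stats::lm(log(count) ~ age, data = upper)
      rate <- -unname(stats::coef(fit)[2])
      fitted <- TRUE
    }
  }
  structure(list(strategy = strategy, hist = hist, n = n,
                 tail_decay_rate = rate, tail_fitted = fitted),
            class = "ecoflow_lifespan")
}

#' @export
print.ecoflow_lifespan <- function(x, ...) {
  cat(sprintf("<ecoflow_lifespan> strategy %s: %d deaths", x$strategy, x$n))
  if (x$tail_fitted) cat(sprintf(", tail decay rate %.4f/step", x$tail_decay_rate))
  cat("\n")
  invisible(x)
}

#' @method tidy ecoflow_lifespan
#' @export
tidy.ecoflow_lifespan <- function(x, ...) x$hist

#' Classify the dynamical phase from replicate simulations
#'
#' Runs the engine once per seed, time-averages each run, and classifies
#' the point: cooperation is "present" when the mean fraction of cooperators
#' exceeds `m_min` in a majority of replicates; the phase is
#' `"full_cooperation"` when defectors are simultaneously at or below the
#' mutation-limited fraction (`1 - m < m_min`), `"coexistence"` otherwise,
#' and `"no_cooperation"` when cooperation is absent. Oscillation is flagged
#' by the replicate-median coefficient of variation of the cooperator
#' density.
#'
#' @param params An [sim_params()] record (its `seed` field is overridden
#'   per replicate).
#' @param seeds Integer vector of replicate seeds.
#' @param m_min Cooperation-presence cutoff on the time-averaged `m`
#'   (default 0.05).
#' @param osc_threshold Passed to [summarize_run()].
#' @return A one-row tibble: `phase`, `oscillation`, `m_mean`, `cv_median`,
#'   `n_replicates`, plus a nested `replicates` tibble of per-seed summaries.
#' @export
classify_phase_sim <- function(params, seeds, m_min = 0.05,
                               osc_threshold = 0.15) {
  if (length(seeds) < 1L) stop("at least one replicate seed required",
                               call. = FALSE)
  reps <- purrr::map_dfr(seeds, function(s) {
    p <- params
    p$seed <- as.integer(s)
    sm <- summarize_run(run_sim(p), osc_threshold = osc_threshold)
    dplyr::mutate(sm, seed = s, .before = 1)
  })
  coop <- mean(reps$m > m_min) > 0.5
  full <- coop && mean((1 - reps$m) < m_min) > 0.5
  phase <- if (!coop) "no_cooperation"
           else if (full) "full_cooperation"
           else "coexistence"
  tibble::tibble(
    phase = phase,
    oscillation = stats::median(reps$oscillation_metric) > osc_threshold,
    m_mean = mean(reps$m),
    cv_median = stats::median(reps$oscillation_metric),
    n_replicates = length(seeds),
    replicates = list(reps)
  )
}
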