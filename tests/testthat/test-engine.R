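test_that("worlds initialise as all-defector populations on random sites", {
  p <- base_params(L = 100, steps = 10)
  w <- init_world(p)
  expect_equal(length(w$site), 100L)
  expect_false(any(w$is_c))
  expect_true(all(w$site >= 1 & w$site <= 100^2))
  expect_true(all(w$energy == p$init_energy))
  expect_equal(w$t, 0L)
  expect_equal(sum(w$stock), 0)
  # same seed, same placement; different seed, different placement
  w2 <- init_world(p)
  expect_identical(w$site, w2$site)
  p3 <- base_params(L = 100, steps = 10, seed = 2L)
  expect_false(identical(init_world(p3)$site, w$site))
  # degenerate size and mixed-start override
  w1 <- init_world(base_params(steps = 10, init_pop = 1))
  expect_equal(length(w1$site), 1L)
  wm <- init_world(base_params(steps = 10), init_coop_frac = 0.5)
  expect_equal(sum(wm$is_c), 50L)
})

test_that("gathering splits the entire site stock equally and banks payoffs", {
  p <- base_params(L = 2, steps = 10, init_pop = 3, r = 3)
  w <- init_world(p)
  w$site <- c(1L, 1L, 1L)
  w$is_c <- c(TRUE, FALSE, FALSE)
  w$stock <- c(0.6, 0, 1.2, 0)
  e0 <- w$energy
  w <- stage_gather_and_play(w, p)
  expect_equal(w$kappa, rep(0.2, 3))
  expect_equal(w$stock, c(0, 0, 1.2, 0))  # unvisited stock keeps accumulating
  # one cooperator among three: pot r*c shared, cooperator pays c
  expect_equal(w$payoff, c(0.1, 0.1, 0.1) - c(0.1, 0, 0))
  expect_equal(w$energy, e0 + w$kappa + w$payoff)
  # energy added to agents = consumed stock + net game production
  expect_equal(sum(w$energy - e0), 0.6 + (p$r - 1) * p$cost * 1,
               tolerance = 1e-12)
})

test_that("reproduction divides strictly above threshold, halving energy", {
  p <- base_params(L = 5, steps = 10, init_pop = 3, nu = 0)
  w <- init_world(p)
  w$energy <- c(2.5, 2.0, 1.0)  # d = 2: only the first divides
  w <- stage_reproduce(w, p)
  expect_equal(length(w$energy), 4L)
  expect_equal(w$energy, c(1.25, 2.0, 1.0, 1.25))
  expect_equal(w$site[4], w$site[1])       # child on parent's site
  expect_equal(w$birth[4], w$t + 1L)
  expect_equal(w$births$by_parent_D, 1L)
  # forced mutation flips every child
  p1 <- base_params(L = 5, steps = 10, init_pop = 2, nu = 1)
  w1 <- init_world(p1)
  w1$energy <- c(3, 3)
  w1 <- stage_reproduce(w1, p1)
  expect_equal(w1$is_c, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("movement respects q and the topology's neighbourhoods", {
  p0 <- base_params(L = 10, steps = 10, q = 0)
  w0 <- init_world(p0)
  expect_identical(stage_move(w0, p0)$site, w0$site)

  # q = 1 on the Moore lattice: every agent lands on one of its 8 neighbours
  pl <- base_params(L = 5, steps = 10, init_pop = 1, q = 1,
                    topology = "lattice_moore")
  wl <- init_world(pl)
  wl$site <- 1L  # corner (0, 0) exercises the periodic wrap
  neigh <- c()
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    neigh <- c(neigh, (dx %% 5) + 5 * (dy %% 5) + 1)
  }
  seen <- replicate(60, {
    wl <<- stage_move(wl, pl)
    s <- wl$site
    wl$site <<- 1L
    s
  })
  expect_true(all(seen %in% neigh))
  expect_gt(length(unique(seen)), 4)  # actually explores the neighbourhood

  # q = 1 mixed: destinations uniform over all sites (chi-square sanity)
  pm <- base_params(L = 10, steps = 10, init_pop = 100000, q = 1)
  wm <- init_world(pm)
  wm <- stage_move(wm, pm)
  counts <- tabulate(wm$site, nbins = 100)
  chi <- chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
})

test_that("metabolism kills strictly below zero and rescues extinction", {
  p <- base_params(L = 5, steps = 10, init_pop = 2, lambda = 0)
  w <- init_world(p)
  w$energy <- c(0.3, 0.4)  # eta = 0.4: first dies at -0.1, second holds at 0.0
  w <- stage_metabolize_and_cull(w, p)
  expect_equal(length(w$energy), 1L)
  expect_equal(w$energy, 0)
  expect_equal(w$deaths$deaths_D, 1L)
  expect_equal(w$deaths$death_time - w$deaths$birth_time, 1L)

  # total extinction brings one immigrant with founder energy
  w2 <- init_world(base_params(L = 5, steps = 10, init_pop = 3, lambda = 0))
  w2$energy <- rep(0.1, 3)
  w2 <- stage_metabolize_and_cull(w2, p)
  expect_equal(length(w2$energy), 1L)
  expect_true(w2$deaths$immigration)
  expect_equal(w2$energy, p$init_energy)
})

test_that("regeneration adds lambda to every site and nothing else", {
  p <- base_params(L = 4, steps = 10)
  w <- init_world(p)
  w$stock <- runif(16)
  s0 <- w$stock
  e0 <- w$energy
  w <- stage_regenerate(w, p)
  expect_equal(w$stock, s0 + p$lambda)
  expect_identical(w$energy, e0)
  expect_equal(sum(w$stock) - sum(s0), p$lambda * 16, tolerance = 1e-12)
})

test_that("an isolated agent decays by eta per step and dies on schedule", {
  # lambda = 0, lone defector: payoff 0, so energy is pure decay from 1.0
  p <- sim_params(lambda = 0, eta = 0.4, d = 2, r = 2, cost = 0.1, nu = 0,
                  q = 0, L = 5, steps = 5, burn_in = 0, seed = 1,
                  init_pop = 1, init_energy = 1.0)
  w <- init_world(p)
  st <- step_world(w, p)
  expect_equal(st$world$energy, 0.6)
  st <- step_world(st$world, p)
  expect_equal(st$world$energy, 0.2, tolerance = 1e-12)
  st <- step_world(st$world, p)  # 0.2 - 0.4 < 0: dies, rescue immigrant
  expect_equal(nrow(st$deaths), 1L)
  expect_equal(st$deaths$lifespan, 3L)
  expect_equal(st$record[["immigration"]], 1)
})

test_that("runs are bitwise reproducible and stage records are consistent", {
  p <- base_params(L = 20, steps = 150, burn_in = 50, nu = 1e-3)
  s1 <- run_sim(p)
  s2 <- run_sim(p)
  expect_identical(s1$steps, s2$steps)
  expect_identical(s1$lifespans, s2$lifespans)
  expect_equal(s1$steps$rho, s1$steps$rho_C + s1$steps$rho_D)
  expect_equal(s1$steps$m * s1$steps$rho, s1$steps$rho_C)
  expect_true(all(s1$steps$N_C + s1$steps$N_D >= 1))
})

test_that("without mutation or immigration the strategy set never grows", {
  p <- base_params(L = 20, steps = 300, burn_in = 50, nu = 0, r = 4)
  s <- run_sim(p)
  expect_true(all(s$steps$N_C == 0))
  expect_equal(sum(s$steps$immigration), 0)
})

test_that("per-step energy bookkeeping balances to relative 1e-9", {
  p <- base_params(L = 15, steps = 300, burn_in = 50, nu = 1e-3, r = 3)
  s <- run_sim(p, ledger = TRUE)
  st <- s$steps
  delta <- st$energy_end - st$energy_start
  rhs <- st$basal_inflow + st$game_production - st$metabolic -
    st$residual_dead + st$immigrant_energy
  expect_lt(max(abs(delta - rhs) / pmax(abs(st$energy_end), 1)), 1e-9)
})

test_that("surviving agents and site stocks never go negative", {
  p <- base_params(L = 15, steps = 200, burn_in = 50, nu = 1e-3, r = 4,
                   q = 0.3, topology = "lattice_moore")
  s <- run_sim(p)
  w <- s$final_world
  expect_true(all(w$energy >= 0))
  expect_true(all(w$stock >= 0))
})
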