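cfg <- scenario_config()

test_that("initial state colonises exactly the sources at capacity", {
  net <- chain_network(c(625, 625))
  st <- init_state(net, sources = 1)
  expect_equal(st$t, 0L)
  expect_equal(unname(st$biomass), c(100, 0, 0))
  expect_equal(unname(st$is_source), c(TRUE, FALSE, FALSE))
  empty <- init_state(net, sources = integer(0))
  expect_true(all(empty$biomass == 0) && !any(empty$is_source))
  expect_error(init_state(net, sources = 99), "unknown patch")
  res <- run_simulation(net, sources = c(1, 3), cfg)
  expect_equal(unname(res$first_colonised[c("1", "3")]), c(0L, 0L))
})

test_that("one step delivers capped, mortality-thinned, share-weighted arrivals", {
  # single neighbour at C = 625: 10 emitted, share 1, survival 0.5 -> 5
  net <- chain_network(625)
  st <- sim_step(init_state(net, 1), net, cfg)
  expect_equal(unname(st$biomass[2]), 5)
  expect_equal(st$t, 1L)
  # two neighbours at C = 250 and 750: weights 0.8/0.4 -> shares 2/3, 1/3
  star <- toy_network(data.frame(from = c(1, 1), to = c(2, 3),
                                 cost = c(250, 750)), K = c(100, 100, 100))
  st2 <- sim_step(init_state(star, 1), star, cfg)
  expect_equal(unname(st2$biomass[2]), 10 * (2 / 3) * 0.8)
  expect_equal(unname(st2$biomass[3]), 10 * (1 / 3) * 0.4)
  # isolated source: nothing changes but the clock
  lone <- toy_network(data.frame(from = integer(0), to = integer(0),
                                 cost = numeric(0))[0, ], K = 100)
  st3 <- sim_step(init_state(lone, 1), lone, cfg)
  expect_equal(st3$t, 1L)
  expect_equal(unname(st3$biomass), 100)
})

test_that("arrivals at source habitats are discarded and sources stay at K", {
  net <- chain_network(625)
  st <- init_state(net, c(1, 2))
  st1 <- sim_step(st, net, cfg)
  expect_equal(unname(st1$biomass), c(100, 100))
})

test_that("chain colonisation times match the hand-iterated oracle", {
  # S - A - B, both edges 625: A gains 5/step -> colonised at t = 2;
  # A then splits between S and B, delivering 10 * 1/2 * 0.5 = 2.5/step
  # to B -> B at t = 6 (hand iteration of the step rule)
  net <- chain_network(c(625, 625))
  res <- run_simulation(net, sources = 1, cfg)
  expect_equal(unname(res$first_colonised), c(0L, 2L, 6L))
  # deterministic
  res2 <- run_simulation(net, sources = 1, cfg)
  expect_identical(res$first_colonised, res2$first_colonised)
})

test_that("unreachable patches stay uncolonised for the whole cap", {
  net <- toy_network(data.frame(from = 1, to = 2, cost = 625),
                     K = c(100, 100, 100)) # patch 3 isolated
  res <- run_simulation(net, sources = 1, cfg)
  expect_true(is.na(res$first_colonised[["3"]]))
  expect_equal(res$steps_run, cfg$sim_max_steps)
})

test_that("colonisation is monotone and emissions never exceed the cap", {
  net <- random_instance(8, seed = 21)
  pre <- colonet:::sim_precompute(net, cfg)
  st <- init_state(net, c(1, 5))
  for (i in 1:30) {
    st_next <- colonet:::sim_step_fast(st, pre, cfg)
    # once a source, always a source
    expect_true(all(st_next$is_source[st$is_source]))
    # per-step arrival at any patch bounded by the sum over source
    # neighbours of S_DIS * K * survival (patches crossing the
    # threshold jump to K under instant growth, so compare only those
    # still below it)
    gain <- st_next$biomass - st$biomass
    for (v in which(!st$is_source & !st_next$is_source)) {
      e <- net$edges
      nb <- rbind(e[e$from == v, c("to", "cost")],
                  setNames(e[e$to == v, c("from", "cost")], c("to", "cost")))
      bound <- sum(cfg$S_DIS * net$patches$K[nb$to] *
                     (1 - nb$cost / net$C_max) * st$is_source[nb$to])
      expect_lte(gain[v], bound + 1e-9)
    }
    st <- st_next
  }
})

test_that("logistic growth ramps emission instead of jumping to K", {
  cfgl <- scenario_config(growth = "logistic", growth_rate = 0.5)
  net <- chain_network(c(625, 625))
  ri <- run_simulation(net, 1, cfg)
  rl <- run_simulation(net, 1, cfgl)
  # the ramp can only delay downstream colonisation
  expect_gte(rl$first_colonised[["3"]], ri$first_colonised[["3"]])
  expect_equal(rl$first_colonised[["2"]], ri$first_colonised[["2"]])
})

test_that("simulation results write to CSV", {
  net <- chain_network(c(625, 625))
  res <- run_simulation(net, 1, cfg, record_trajectory = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(res, f, ft)
  tab <- read.csv(f)
  expect_equal(tab$first_colonised_step, c(0L, 2L, 6L))
  expect_true(nrow(read.csv(ft)) > 0)
})
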