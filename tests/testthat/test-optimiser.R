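cfg <- scenario_config()

test_that("path fill time evaluates the per-edge ceiling formula", {
  net <- chain_network(c(625, 625))
  expect_equal(path_fill_time(c(1, 2, 3), net, cfg), 4L) # 2 + 2
  expect_equal(path_fill_time(1, net, cfg), 0L)
  expect_error(path_fill_time(c(1, 3), net, cfg), "not network neighbours")
  # ceiling behaviour: survival 0.5, rate 5, threshold 10.1 -> 3 steps
  cfg2 <- scenario_config(T_SH = 10.1)
  one <- chain_network(625)
  expect_equal(path_fill_time(c(1, 2), one, cfg2), 3L)
  # tail capacity matters: a weaker upstream patch slows the hop it
  # feeds (rate 2.5 -> 4 steps) but not the next one (rate 5 -> 2)
  het <- chain_network(c(625, 625), K = c(50, 100, 100))
  expect_equal(path_fill_time(c(1, 2, 3), het, cfg), 6L)
})

test_that("the time horizon is min(TH1, TH2, block) with sane edge cases", {
  net <- chain_network(c(625, 625))
  hz <- choose_time_horizon(net, sources = 1, dest = 3, cfg)
  expect_equal(hz$TH1, 4L)
  expect_true(is.na(hz$TH2)) # single connected source
  expect_equal(hz$T, 4L)
  # the block caps large bounds
  slow <- chain_network(rep(0.88 * 1250, 4)) # per-hop fill 9, TH1 = 36
  hz2 <- choose_time_horizon(slow, 1, 5, cfg)
  expect_equal(hz2$TH1, 36L)
  expect_equal(hz2$T, 30L)
  # destination that is a source
  hz3 <- choose_time_horizon(net, sources = c(1, 3), dest = 3, cfg)
  expect_equal(hz3$T, 0L)
  # unreachable destination
  iso <- toy_network(data.frame(from = 1, to = 2, cost = 625),
                     K = c(100, 100, 100))
  hz4 <- choose_time_horizon(iso, sources = 1, dest = 3, cfg)
  expect_false(hz4$reachable)
  # TH2 can undercut TH1 through integer rounding; both are upper bounds
  two <- toy_network(data.frame(from = c(1, 2), to = c(3, 3),
                                cost = c(250, 500)),
                     K = c(26, 100, 100))
  hz5 <- choose_time_horizon(two, sources = c(1, 2), dest = 3, cfg)
  expect_equal(hz5$TH1, 5L)  # nearest by cost: patch 1, rate 2.08
  expect_equal(hz5$TH2, 2L)  # patch 2: rate 6 -> 2 steps
  expect_equal(hz5$T, 2L)
})

test_that("horizon escalation recovers optima between 31 and 45", {
  # chain with per-hop fill 9 over 4 hops: optimum 36 forces exactly one
  # escalation past the 30-layer block
  slow <- chain_network(rep(0.88 * 1250, 4))
  res <- minimum_colonisation_time(slow, 1, 5, cfg, compute_route = FALSE)
  expect_equal(res$t_star, 36L)
  expect_equal(res$T_used, 36L) # min(TH1 = 36, 60)
})

test_that("chain optima equal TH1 and the schedule enumeration oracle", {
  set.seed(5)
  for (k in 2:5) {
    costs <- runif(k - 1, 0.3, 0.9) * 1250
    K <- runif(k, 0.5, 1) * 100
    net <- chain_network(costs, K = K)
    res <- minimum_colonisation_time(net, 1, k, cfg,
                                     compute_route = FALSE)
    th1 <- path_fill_time(seq_len(k), net, cfg)
    expect_equal(res$t_star, th1)
    expect_equal(res$t_star, chain_min_time_enum(net, cfg))
  }
})

test_that("optimum never exceeds TH1 and never the simulation time", {
  # randomized dominance check; the acceptance suite runs a larger sweep
  for (s in 1:8) {
    net <- random_instance(10, seed = 100 + s)
    set.seed(s)
    srcs <- sample(net$patches$id, 2)
    dest <- sample(setdiff(net$patches$id, srcs), 1)
    res <- minimum_colonisation_time(net, srcs, dest, cfg,
                                     compute_route = FALSE)
    hz <- res$horizons[[1]]
    expect_lte(res$t_star, min(hz$TH1, hz$TH2, na.rm = TRUE))
    sim <- run_simulation(net, srcs, cfg)
    t_sim <- sim$first_colonised[[as.character(dest)]]
    if (!is.na(t_sim)) expect_lte(res$t_star, t_sim)
  }
})

test_that("pruning the expansion does not change the optimum", {
  for (s in c(31, 32)) {
    net <- random_instance(12, seed = s, p = 0.15)
    srcs <- c(1, 2)
    dest <- 12
    a <- minimum_colonisation_time(net, srcs, dest, cfg, prune = TRUE,
                                   compute_route = FALSE)
    b <- minimum_colonisation_time(net, srcs, dest, cfg, prune = FALSE,
                                   compute_route = FALSE)
    expect_equal(a$t_star, b$t_star)
  }
})

test_that("scale equivariance: scaling T_SH and K together preserves t*", {
  net <- chain_network(c(400, 800), K = c(90, 70, 100))
  base <- minimum_colonisation_time(net, 1, 3, cfg, compute_route = FALSE)
  cfg2 <- scenario_config(T_SH = cfg$T_SH * 3, K_max = cfg$K_max * 3)
  net2 <- net
  net2$patches$K <- net$patches$K * 3
  net2 <- colonet:::new_habitat_network(net2$patches, net2$edges,
                                        net2$C_max)
  scaled <- minimum_colonisation_time(net2, 1, 3, cfg2,
                                      compute_route = FALSE)
  expect_equal(scaled$t_star, base$t_star)
})

test_that("monotonicity: extra sources or edges never slow colonisation", {
  net <- chain_network(c(700, 700, 700))
  base <- minimum_colonisation_time(net, 1, 4, cfg,
                                    compute_route = FALSE)$t_star
  more_src <- minimum_colonisation_time(net, c(1, 3), 4, cfg,
                                        compute_route = FALSE)$t_star
  expect_lte(more_src, base)
  shortcut <- toy_network(rbind(net$edges,
                                data.frame(from = 1, to = 4, cost = 900)),
                          K = net$patches$K)
  with_edge <- minimum_colonisation_time(shortcut, 1, 4, cfg,
                                         compute_route = FALSE)$t_star
  expect_lte(with_edge, base)
  # raising the threshold never speeds it up
  cfg_hi <- scenario_config(T_SH = 20)
  expect_gte(minimum_colonisation_time(net, 1, 4, cfg_hi,
                                       compute_route = FALSE)$t_star,
             base)
})

test_that("routes decompose the optimal flows into time-increasing paths", {
  net <- chain_network(c(625, 625))
  res <- minimum_colonisation_time(net, 1, 3, cfg)
  rt <- res$route
  expect_gt(length(rt$paths), 0)
  total <- 0
  for (p in rt$paths) {
    expect_true(all(diff(p$times) > 0))
    expect_equal(p$patches[length(p$patches)], 3)
    expect_equal(p$patches[1], 1) # starts at the source injection
    total <- total + p$amount
  }
  expect_gte(total, cfg$T_SH - 1e-6)
  expect_lte(rt$residual, 1e-6)
  # trivial route when the destination is a source
  res0 <- minimum_colonisation_time(net, c(1, 3), 3, cfg)
  expect_equal(res0$t_star, 0L)
})

test_that("multiple destinations use the max per-destination horizon", {
  net <- chain_network(c(625, 625, 625))
  res <- minimum_colonisation_time(net, 1, c(3, 4), cfg,
                                   compute_route = FALSE)
  # both ends must be sources in one layer: the far end dominates
  expect_equal(res$t_star, 6L)
})
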