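test_that("patch selection samples the right number of aquatic cells", {
  cfg <- scenario_config()
  lc <- matrix(1L, 20, 20)
  streams <- matrix(FALSE, 20, 20); streams[10, 1:20] <- TRUE
  streams[1:10, 10] <- TRUE # 29 aquatic cells
  ras <- build_cost_raster(lc, streams, cfg)
  p <- select_patches(ras, cfg, seed = 1)
  expect_equal(nrow(p), floor(0.10 * sum(ras$aquatic)))
  expect_true(all(ras$aquatic[cbind(p$row, p$col)]))
  expect_true(all(p$quality > 0 & p$quality <= 1))
  expect_equal(p$K, p$quality * cfg$K_max)
  # fraction 1 selects every aquatic cell
  cfg1 <- scenario_config(habitat_fraction = 1)
  expect_equal(nrow(select_patches(ras, cfg1, seed = 1)), sum(ras$aquatic))
  # determinism
  expect_identical(select_patches(ras, cfg, seed = 9),
                   select_patches(ras, cfg, seed = 9))
  # no aquatic cells
  expect_error(select_patches(uniform_raster(5, 5), cfg), "aquatic")
})

test_that("least-cost distance matches closed forms and brute force", {
  cfg <- scenario_config()
  ras <- uniform_raster(1, 6, cfg)
  # straight run of n steps through uniform cost c costs n * c
  expect_equal(least_cost_distance(ras, c(1, 1), c(1, 6)), 5 * 50)
  expect_equal(least_cost_distance(ras, c(1, 3), c(1, 3)), 0)
  # 3x3 uniform grid, opposite corners: two diagonal moves win
  ras9 <- uniform_raster(3, 3, cfg)
  expect_equal(least_cost_distance(ras9, c(1, 1), c(3, 3)),
               2 * sqrt(2) * 50)
  # brute-force equivalence on small heterogeneous grids
  set.seed(42)
  for (k in 1:3) {
    cost <- matrix(sample(c(25, 50, 75, 100), 12, TRUE), 3, 4)
    ras_h <- structure(list(rows = 3, cols = 4,
                            landcover = matrix(1L, 3, 4), cost = cost,
                            aquatic = matrix(FALSE, 3, 4)),
                       class = "cost_raster")
    expect_equal(least_cost_distance(ras_h, c(1, 1), c(3, 4)),
                 brute_force_lcd(cost, c(1, 1), c(3, 4)))
  }
  # symmetry
  expect_equal(least_cost_distance(ras9, c(1, 2), c(3, 1)),
               least_cost_distance(ras9, c(3, 1), c(1, 2)))
})

test_that("least-cost distance obeys the triangle inequality", {
  cfg <- scenario_config()
  set.seed(7)
  cost <- matrix(sample(c(25, 50, 75, 100), 36, TRUE), 6, 6)
  ras <- structure(list(rows = 6, cols = 6, landcover = matrix(1L, 6, 6),
                        cost = cost, aquatic = matrix(FALSE, 6, 6)),
                   class = "cost_raster")
  cells <- list(c(1, 1), c(3, 4), c(6, 6), c(2, 6), c(5, 2))
  for (a in cells) for (b in cells) for (m in cells) {
    expect_lte(least_cost_distance(ras, a, b),
               least_cost_distance(ras, a, m) +
                 least_cost_distance(ras, m, b) + 1e-9)
  }
})

test_that("network edges exist exactly below the C_max budget", {
  cfg <- scenario_config()
  # 31 uniform-agriculture cells apart: cost 1500 >= 1250, no edge
  ras <- uniform_raster(1, 40, cfg)
  far <- data.frame(id = 1:2, row = 1L, col = c(1L, 31L),
                    quality = 1, K = 100)
  expect_equal(nrow(build_network(far, ras, cfg)$edges), 0)
  # 10 cells apart: cost 500 < 1250, one edge at that cost
  near <- data.frame(id = 1:2, row = 1L, col = c(1L, 11L),
                     quality = 1, K = 100)
  net <- build_network(near, ras, cfg)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$cost, 500)
  # single patch: empty edge set
  one <- data.frame(id = 1L, row = 1L, col = 5L, quality = 1, K = 100)
  expect_equal(nrow(build_network(one, ras, cfg)$edges), 0)
})

test_that("generated networks keep every edge strictly below C_max", {
  cfg <- scenario_config(seed = 4)
  ras <- generate_landscape(cfg, 60, 60)
  p <- select_patches(ras, cfg)
  net <- build_network(p, ras, cfg)
  expect_true(all(net$edges$cost > 0))
  expect_true(all(net$edges$cost < cfg$C_max))
  expect_true(all(1 - net$edges$cost / cfg$C_max > 0))
  # symmetric storage: one row per unordered pair, no self loops
  expect_true(all(net$edges$from < net$edges$to))
})

test_that("network IO round-trips through GraphML and CSV", {
  net <- chain_network(c(300, 700), K = c(80, 60, 100))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$patches$id, net$patches$id)
  expect_equal(back$patches$K, net$patches$K)
  expect_equal(back$edges$cost, net$edges$cost)
  expect_equal(back$C_max, net$C_max)
  pre <- withr::local_tempfile()
  write_network_csv(net, pre)
  nodes <- read.csv(paste0(pre, "_nodes.csv"))
  expect_equal(nodes$K, net$patches$K)
})
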