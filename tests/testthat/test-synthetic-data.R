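short_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_fish = 4, duration_days = 0.5, rng_seed = 42), list(...))
  do.call(sim_config, args)
}

test_that("the temperature field stratifies in summer and mixes in winter", {
  # surface colder in mid-winter than mid-summer
  expect_lt(temperature_field(0, 20), temperature_field(0, 200))
  # monotone non-increasing with depth in the summer regime
  z <- seq(0, 7, by = 0.25)
  expect_true(all(diff(temperature_field(z, 200)) <= 0))
  # isothermal winter column: <= 0.5 deg C spread over 0-7 m
  expect_lt(diff(range(temperature_field(z, 20))), 0.5)
  expect_error(temperature_field(-1, 100), "negative")
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_population(short_cfg())
  s2 <- simulate_population(short_cfg())
  expect_identical(s1$fixes, s2$fixes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_population(short_cfg(rng_seed = 43))
  expect_false(identical(s1$fixes, s3$fixes))
})

test_that("all fixes lie inside the lake and displacements are speed-bounded", {
  cfg <- short_cfg(jitter_sd = 0)   # jitter off: test the movement bound
  sim <- simulate_population(cfg)
  lk <- cfg$lake
  expect_true(all(in_lake(sim$fixes$x_m, sim$fixes$y_m, lk)))
  vmax <- 1.5 * max(cfg$speed_day, cfg$speed_night)
  for (f in unique(sim$fixes$fish_id)) {
    fx <- sim$fixes[fish_id == f]
    disp <- sqrt(diff(fx$x_m)^2 + diff(fx$y_m)^2)
    steps <- diff(fx$timestamp) / cfg$burst_interval
    expect_true(all(disp <= vmax * cfg$burst_interval * steps + 1e-9))
  }
  # jittered fixes still respect the shoreline
  simj <- simulate_population(short_cfg())
  expect_true(all(in_lake(simj$fixes$x_m, simj$fixes$y_m, lk)))
})

test_that("group memberships partition the population at every instant", {
  cfg <- short_cfg(n_groups = 3, group_switch_timescale_h = 2)
  sim <- simulate_population(cfg)
  tr <- sim$truth
  for (f in unique(tr$fish_id)) {
    seg <- tr[fish_id == f][order(t_start)]
    expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])  # gap-free
    expect_true(all(seg$group %in% 1:3))
  }
  # probe a few instants: exactly one membership per fish
  probes <- as.numeric(cfg$start) + c(0, 3600, 40000)
  for (tp in probes) {
    memb <- tr[t_start <= tp & t_end > tp]
    expect_equal(nrow(memb), cfg$n_fish)
    expect_equal(anyDuplicated(memb$fish_id), 0L)
  }
})

test_that("perfect detection emits exactly one fix per burst", {
  cfg <- short_cfg(detection_yield_base = 1,
                   detection_yield_summer_day_penalty = 0)
  sim <- simulate_population(cfg)
  per_fish <- sim$fixes[, .N, by = fish_id]
  expect_equal(per_fish$N,
               rep(cfg$duration_days * 86400 / cfg$burst_interval, cfg$n_fish))
})

test_that("a single fish yields no pairs and no contacts downstream", {
  cfg <- short_cfg(n_fish = 1)
  sim <- simulate_population(cfg)
  traj <- resample_median(sim$fixes)
  ds <- pairwise_distances(traj)
  expect_equal(nrow(ds$pairs), 0)
  ev <- detect_contacts(ds, NULL)
  expect_equal(nrow(ev), 0)
})

test_that("stronger attraction tightens a single group monotonically", {
  nn_median <- function(attr) {
    cfg <- sim_config(n_fish = 6, duration_days = 1, rng_seed = 7,
                      n_groups = 1, attraction_strength = attr,
                      group_radius = 15, detection_yield_base = 1,
                      detection_yield_summer_day_penalty = 0, jitter_sd = 0)
    sim <- simulate_population(cfg)
    tp <- sim$true_paths
    sub <- seq(1, length(tp$time), by = 60)  # 5-min probes
    nn <- sapply(sub, function(s) {
      dm <- dist(cbind(tp$x[s, ], tp$y[s, ]))
      median(apply(as.matrix(dm) + diag(Inf, 6), 1, min))
    })
    median(nn[-seq_len(length(nn) %/% 4)])  # drop the burn-in quarter
  }
  vals <- c(nn_median(0), nn_median(0.8), nn_median(2.5))
  expect_true(all(diff(vals) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(burst_interval = 7), "divide")
  expect_error(sim_config(detection_yield_base = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(attraction_strength = -1), ">= 0")
  expect_error(sim_config(speed_day = c(winter = NA, transition = 1, summer = 1)),
               "non-finite")
  tiny <- lake_polygon(c(0, 30, 30, 0), c(0, 0, 30, 30), 52.9, 13.5)
  expect_error(sim_config(n_fish = 30, lake = tiny), "too small")
})
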