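test_that("spatial entropy matches hand-computed occupancy distributions", {
  # all time in one cell
  expect_equal(spatial_entropy(rep(1, 50), rep(1, 50)), 0)
  # equal time in 4 cells -> ln 4
  x <- c(5, 15, 5, 15); y <- c(5, 5, 15, 15)
  expect_equal(spatial_entropy(rep(x, 10), rep(y, 10)), log(4))
  # fractions (1/2, 1/4, 1/4): -sum(c log c) = 1.0397
  x3 <- c(5, 5, 15, 25); y3 <- rep(5, 4)
  expect_equal(spatial_entropy(x3, y3), -(0.5 * log(0.5) + 0.5 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(round(spatial_entropy(x3, y3), 4), 1.0397)
})

test_that("entropy is bounded by log occupied cells and grows under splitting", {
  set.seed(5)
  x <- runif(300, 0, 100); y <- runif(300, 0, 100)
  S <- spatial_entropy(x, y)
  n_cells <- nrow(unique(cbind(floor(x / 10), floor(y / 10))))
  expect_gte(S, 0)
  expect_lte(S, log(n_cells) + 1e-12)
  # point masses are translation invariant under a grid shift by whole cells
  expect_equal(spatial_entropy(x + 10, y - 20), S)
  # splitting one cell's occupancy across more cells cannot lower entropy
  expect_gte(spatial_entropy(x, y, cell_size = 5), S - 1e-12)
})

test_that("entropy of zero valid bins is flagged missing, not zero", {
  expect_true(is.na(spatial_entropy(numeric(0), numeric(0))))
  expect_true(is.na(spatial_entropy(NA_real_, NA_real_)))
})

test_that("distance from shore matches circle geometry and brute force", {
  th <- seq(0, 2 * pi, length.out = 481)[-481]
  circle <- lake_polygon(100 * cos(th), 100 * sin(th), lat = 52.995, lon = 13.58)
  # centre of a radius-100 circle -> ~100 (polygonised ring is slightly inside)
  expect_equal(distance_from_shore(0, 0, circle), 100, tolerance = 1e-3)
  # a vertex lies on the boundary -> 0
  expect_equal(distance_from_shore(circle$x[1], circle$y[1], circle), 0)

  sq <- square_lake(2)  # unit-square-ish lake [0,2]^2
  expect_equal(distance_from_shore(1, 0.25, sq), 0.25)
  # brute force over a densely sampled boundary
  set.seed(3)
  px <- runif(20, 0.1, 1.9); py <- runif(20, 0.1, 1.9)
  tt <- seq(0, 1, length.out = 4001)
  bx <- c(2 * tt, rep(2, 4001), 2 - 2 * tt, rep(0, 4001))
  by <- c(rep(0, 4001), 2 * tt, rep(2, 4001), 2 - 2 * tt)
  for (i in seq_along(px)) {
    ref <- min(sqrt((bx - px[i])^2 + (by - py[i])^2))
    expect_equal(distance_from_shore(px[i], py[i], sq), ref, tolerance = 1e-5)
  }
  expect_error(distance_from_shore(5, 5, sq), "outside")
})

test_that("speed is displacement over 15 s with gaps propagated", {
  x <- c(0, 7.5, 15, NA, 30, 37.5)
  tr <- make_traj(x = x, y = rep(0, 6))
  v <- unname(speed_series(tr)[, 1])
  expect_true(is.na(v[1]))             # no predecessor
  expect_equal(v[2], 0.5)              # 7.5 m / 15 s
  expect_equal(v[3], 0.5)
  expect_true(is.na(v[4]))             # missing bin
  expect_true(is.na(v[5]))             # bin after a gap undefined
  expect_equal(v[6], 0.5)
  # stationary fish
  expect_equal(unname(speed_series(make_traj(x = rep(3, 4),
                                             y = rep(4, 4)))[-1, 1]),
               rep(0, 3))
})

test_that("dyad statistics reproduce hand-computed tau and p values", {
  ov <- data.frame(sunrise = 0, sunset = 1500 * 15)
  cal <- classify_diel(0, 1500, lat = 52.995, lon = 13.5822, override = ov)
  # events of 60 s (4 bins) and 120 s (8 bins) separated by a 10-min gap
  d <- rep(20, 1500)
  d[101:104] <- 5            # event 1: bins 101..104
  d[145:152] <- 5            # event 2: starts 40 bins later; gap 600 s
  ds <- make_ds(d)
  ev <- detect_contacts(ds, cal)
  expect_equal(nrow(ev), 2)
  st <- dyad_stats(ev, ds, cal)
  expect_equal(st$tau_pos, mean(c(60, 120)))
  expect_equal(st$tau_neg, 600)
  expect_equal(st$p_n, 12 / 1500)
  # pair in contact every detected bin -> p = 1
  ds1 <- make_ds(rep(5, 100))
  ev1 <- detect_contacts(ds1, classify_diel(0, 100, 52.995, 13.5822,
                                            override = data.frame(sunrise = 0, sunset = 1e6)))
  st1 <- dyad_stats(ev1, ds1, classify_diel(0, 100, 52.995, 13.5822,
                                            override = data.frame(sunrise = 0, sunset = 1e6)))
  expect_equal(st1$p_n, 1)
  # no events -> p = 0, taus undefined
  ds0 <- make_ds(rep(20, 100))
  st0 <- dyad_stats(detect_contacts(ds0, cal), ds0, cal)
  expect_equal(st0$p_n, 0)
  expect_true(is.na(st0$tau_pos))
  expect_true(is.na(st0$tau_neg))
})

test_that("pooled population p equals total active over total detected bins", {
  set.seed(21)
  tr <- make_traj(x = matrix(runif(500 * 5, 0, 40), 500),
                  y = matrix(runif(500 * 5, 0, 40), 500))
  tr$x[sample(length(tr$x), 300)] <- NA
  tr$valid <- !is.na(tr$x)
  ov <- data.frame(sunrise = 0, sunset = 500 * 15)
  cal <- classify_diel(0, 500, 52.995, 13.5822, override = ov)
  ds <- impute_gaps(pairwise_distances(tr, use_depth = FALSE))
  ev <- detect_contacts(ds, cal)
  st <- dyad_stats(ev, ds, cal)
  pm <- population_means(st)
  # independent totals straight from the matrices
  act <- matrix(FALSE, 500, nrow(ds$pairs))
  for (e in seq_len(nrow(ev))) {
    p <- match(ev$pair[e], ds$pairs$pair)
    act[(ev$start[e] / 15 + 1):(ev$end[e] / 15), p] <- TRUE
  }
  det <- ds$status > 0
  expect_equal(pm$p_pooled, sum(act & det) / sum(det))
})
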