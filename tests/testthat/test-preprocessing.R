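test_that("median resampling recovers a constant position at full yield", {
  fx <- data.table::data.table(
    fish_id = "f01", timestamp = seq(0, 595, by = 5),
    x_m = 10, y_m = 20, depth_m = 1)
  tr <- resample_median(fx, t0 = 0, n_bins = 40)
  expect_true(all(tr$valid))
  expect_equal(unname(tr$x[, 1]), rep(10, 40))
  expect_equal(unname(tr$y[, 1]), rep(20, 40))
})

test_that("median filter suppresses a single outlier in the 30 s window", {
  # bin 0 window [-15, 15) holds fixes at t = 0, 5, 10 with x = 0, 0, 100
  fx <- data.table::data.table(
    fish_id = "f01", timestamp = c(0, 5, 10),
    x_m = c(0, 0, 100), y_m = 0, depth_m = 0)
  tr <- resample_median(fx, t0 = 0, n_bins = 1)
  expect_equal(unname(tr$x[1, 1]), 0)
})

test_that("every second 5 s fix dropped still fills all 15 s bins", {
  # enumerate window membership over a 60 s toy series: surviving fixes at
  # t = 0, 10, 20, ... each 30 s window [15k-15, 15k+15) contains >= 1
  tt <- seq(0, 55, by = 5)
  keep <- tt[seq(1, length(tt), by = 2)]
  fx <- data.table::data.table(fish_id = "f01", timestamp = keep,
                               x_m = keep, y_m = 0, depth_m = 0)
  tr <- resample_median(fx, t0 = 0, n_bins = 4)
  expect_true(all(tr$valid))
  # window containment, computed independently per bin
  for (b in 0:3) {
    w <- keep[keep >= 15 * b - 15 & keep < 15 * b + 15]
    expect_equal(unname(tr$x[b + 1, 1]), median(w))
  }
})

test_that("resampling an already-regular constant series is idempotent", {
  fx <- data.table::data.table(fish_id = "f01", timestamp = seq(0, 585, by = 15),
                               x_m = 5, y_m = 7, depth_m = 2)
  tr1 <- resample_median(fx, t0 = 0, n_bins = 40)
  fx2 <- data.table::data.table(fish_id = "f01",
                                timestamp = traj_times(tr1)[tr1$valid[, 1]],
                                x_m = tr1$x[tr1$valid[, 1], 1],
                                y_m = tr1$y[tr1$valid[, 1], 1],
                                depth_m = tr1$depth[tr1$valid[, 1], 1])
  tr2 <- resample_median(fx2, t0 = 0, n_bins = 40)
  expect_equal(tr2$x, tr1$x)
  expect_equal(tr2$valid, tr1$valid)
})

test_that("conflicting duplicate fixes are rejected", {
  fx <- data.table::data.table(fish_id = "f01", timestamp = c(0, 0),
                               x_m = c(1, 2), y_m = 0, depth_m = 0)
  expect_error(resample_median(fx, t0 = 0, n_bins = 1), "conflicting")
  fx2 <- data.table::data.table(fish_id = "f01", timestamp = c(0, 0),
                                x_m = c(1, 1), y_m = 0, depth_m = 0)
  expect_silent(resample_median(fx2, t0 = 0, n_bins = 1))
})

test_that("pairwise distances follow the 3-4-5 triangle and missingness rules", {
  tr <- make_traj(x = cbind(c(0, 0, NA), c(3, 3, 3)),
                  y = cbind(c(0, 0, 0), c(4, 4, 4)))
  ds <- pairwise_distances(tr)
  expect_equal(ds$d[1, 1], 5)
  expect_true(is.na(ds$d[3, 1]))     # either bin missing -> missing
  expect_equal(ds$status[, 1], c(1L, 1L, 0L))
})

test_that("36 trajectories give 630 pair series and distances are symmetric", {
  set.seed(1)
  n <- 36
  tr <- make_traj(x = matrix(runif(10 * n, 0, 100), 10),
                  y = matrix(runif(10 * n, 0, 100), 10))
  ds <- pairwise_distances(tr)
  expect_equal(nrow(ds$pairs), n * (n - 1) / 2)
  # symmetry: swapping two fish leaves the pair distance unchanged
  tr2 <- tr
  tr2$x <- tr$x[, c(2, 1, 3:n)]; tr2$y <- tr$y[, c(2, 1, 3:n)]
  tr2$depth <- tr$depth[, c(2, 1, 3:n)]; tr2$valid <- tr$valid[, c(2, 1, 3:n)]
  tr2$fish <- tr$fish  # same labels, swapped data
  ds2 <- pairwise_distances(tr2)
  expect_equal(ds2$d[, 1], ds$d[, 1])
})

test_that("3-D distances include depth and the 2-D flag drops it", {
  tr <- make_traj(x = cbind(0, 3), y = cbind(0, 4),
                  depth = cbind(0, 12))
  expect_equal(pairwise_distances(tr)$d[1, 1], 13)
  expect_equal(pairwise_distances(tr, use_depth = FALSE)$d[1, 1], 5)
})

test_that("gap imputation is linear, bounded at 30 min inclusive", {
  # 15 min gap between 8 m and 12 m: 59 missing bins, midpoint -> 10 m
  d <- rep(NA_real_, 61); d[1] <- 8; d[61] <- 12
  ds <- impute_gaps(make_ds(d))
  expect_equal(ds$d[31, 1], 10)
  expect_equal(ds$status[31, 1], 2L)
  expect_false(anyNA(ds$d[, 1]))

  # exactly 30 min between measured values (119 NA bins): imputed
  d30 <- rep(NA_real_, 121); d30[1] <- 8; d30[121] <- 12
  expect_false(anyNA(impute_gaps(make_ds(d30))$d))

  # 31 min: untouched
  d31 <- rep(NA_real_, 125); d31[1] <- 8; d31[125] <- 12
  expect_equal(sum(is.na(impute_gaps(make_ds(d31))$d)), 123)

  # leading/trailing runs never imputed
  dlead <- c(NA, NA, 5, NA, NA)
  expect_equal(sum(is.na(impute_gaps(make_ds(dlead))$d)), 4)
})

test_that("imputed values stay within the flanking measured values", {
  set.seed(42)
  for (rep in 1:20) {
    d <- runif(200, 0, 50)
    d[sample(2:199, 80)] <- NA
    ds <- impute_gaps(make_ds(d))
    imp <- which(ds$status[, 1] == 2L)
    for (i in imp) {
      lo <- max(which(!is.na(d[1:(i - 1)])))
      hi <- i + min(which(!is.na(d[(i + 1):200])))
      expect_true(ds$d[i, 1] >= min(d[lo], d[hi]) - 1e-9)
      expect_true(ds$d[i, 1] <= max(d[lo], d[hi]) + 1e-9)
    }
  }
})

test_that("imputation matches the zoo reference implementation", {
  skip_if_not_installed("zoo")
  set.seed(7)
  d <- matrix(runif(3000, 0, 30), 1000, 3)
  d[sample(length(d), 1200)] <- NA
  tr <- make_traj(x = matrix(0, 1000, 3), y = matrix(0, 1000, 3))
  ds <- structure(list(pairs = data.table::data.table(
    pair = c("p1", "p2", "p3"), a = "x", b = "y"),
    t0 = 0, dt = 15, n_bins = 1000, d = d,
    status = matrix(ifelse(is.na(d), 0L, 1L), 1000)), class = "dist_series")
  got <- impute_gaps(ds)$d
  ref <- apply(d, 2, zoo::na.approx, na.rm = FALSE, maxgap = 119)
  expect_equal(got, matrix(ref, 1000), ignore_attr = TRUE)
})
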