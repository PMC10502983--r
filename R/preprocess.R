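#' Resample burst fixes to a regular 15 s grid with a 30 s median filter
#'
#' Each 15 s bin takes the coordinate-wise median of all fixes falling in the
#' centred, half-open window `[t - 15, t + 15)` around the bin start `t`.
#' Bins whose window holds no fix are flagged invalid (never dropped), so the
#' grid is strictly increasing and gap-free.
#'
#' @param fixes fix table (`fish_id`, `timestamp` epoch seconds or POSIXct,
#'   `x_m`, `y_m`, `depth_m`, optional `temp_c`), any number of fish.
#' @param t0 start of the first bin; defaults to the earliest fix rounded
#'   down to a multiple of `dt`.
#' @param n_bins number of bins; defaults to cover the last fix.
#' @param dt bin width, seconds.
#' @return An object of class `traj_set`: list with `fish` (ids), `t0`, `dt`,
#'   `n_bins`, matrices `x`, `y`, `depth`, `temp` (bins x fish) and logical
#'   `valid` of the same shape.
#' @export
resample_median <- function(fixes, t0 = NULL, n_bins = NULL, dt = 15) {
  fx <- data.table::as.data.table(fixes)
  stopifnot(all(c("fish_id", "timestamp", "x_m", "y_m", "depth_m") %in% names(fx)))
  fx <- data.table::copy(fx)
  fx[, timestamp := as.numeric(timestamp)]
  if (!("temp_c" %in% names(fx))) fx[, temp_c := NA_real_]
  dup <- fx[, .N, by = .(fish_id, timestamp)][N > 1L]
  if (nrow(dup) > 0) {
    conf <- unique(fx[dup, on = c("fish_id", "timestamp")],
                   by = c("fish_id", "timestamp", "x_m", "y_m", "depth_m"))
    if (nrow(conf) > nrow(dup))
      stop("duplicate (fish, timestamp) fixes with conflicting coordinates")
    fx <- unique(fx, by = c("fish_id", "timestamp"))
  }
  if (is.null(t0)) t0 <- floor(min(fx$timestamp) / dt) * dt
  t0 <- as.numeric(t0)
  if (is.null(n_bins)) n_bins <- floor((max(fx$timestamp) - t0) / dt) + 1L
  n_bins <- as.integer(n_bins)

  # each fix falls in exactly the two centred windows around the two nearest
  # bin starts; per-window coordinate-wise medians computed in C++
  fish <- sort(unique(fx$fish_id))
  data.table::setorder(fx, fish_id, timestamp)
  med <- median_bins_cpp(fx$timestamp, match(fx$fish_id, fish),
                         fx$x_m, fx$y_m, fx$depth_m, fx$temp_c,
                         t0, dt, n_bins, length(fish))
  x <- med$x; y <- med$y; depth <- med$depth; temp <- med$temp
  dimnames(x) <- dimnames(y) <- dimnames(depth) <- dimnames(temp) <-
    list(NULL, fish)
  valid <- !is.na(x)
  structure(list(fish = fish, t0 = t0, dt = dt, n_bins = n_bins,
                 x = x, y = y, depth = depth, temp = temp, valid = valid),
            class = "traj_set")
}

#' Bin start times of a trajectory set
#' @param traj a `traj_set`.
#' @return numeric epoch seconds, length `n_bins`.
#' @export
traj_times <- function(traj) traj$t0 + traj$dt * (seq_len(traj$n_bins) - 1)

#' Pairwise inter-fish distance series
#'
#' Euclidean distance per 15 s bin for every unordered fish pair; a bin is
#' missing unless both trajectories are valid there. Distances are 3-D
#' (x, y, depth) by default; set `use_depth = FALSE` for 2-D.
#'
#' @param traj a `traj_set` (all fish share its grid by construction).
#' @param use_depth include the depth axis (default `TRUE`).
#' @return An object of class `dist_series`: list with `pairs` (data.table
#'   `pair`, `a`, `b`), `t0`, `dt`, `n_bins`, matrix `d` (bins x pairs) and
#'   integer `status` matrix (0 = missing, 1 = measured, 2 = imputed).
#' @export
pairwise_distances <- function(traj, use_depth = TRUE) {
  stopifnot(inherits(traj, "traj_set"))
  nf <- length(traj$fish)
  if (nf < 2) {
    pairs <- data.table::data.table(pair = character(0), a = character(0),
                                    b = character(0))
    return(structure(list(pairs = pairs, t0 = traj$t0, dt = traj$dt,
                          n_bins = traj$n_bins,
                          d = matrix(NA_real_, traj$n_bins, 0),
                          status = matrix(0L, traj$n_bins, 0)),
                     class = "dist_series"))
  }
  cmb <- utils::combn(nf, 2)
  d <- dist_cpp(traj$x, traj$y, traj$depth, use_depth)
  a <- traj$fish[cmb[1, ]]; b <- traj$fish[cmb[2, ]]
  pairs <- data.table::data.table(pair = paste(a, b, sep = "|"), a = a, b = b)
  status <- matrix(0L, traj$n_bins, ncol(d))
  status[!is.na(d)] <- 1L
  structure(list(pairs = pairs, t0 = traj$t0, dt = traj$dt,
                 n_bins = traj$n_bins, d = d, status = status),
            class = "dist_series")
}

#' Linearly impute short gaps in distance series
#'
#' Interior missing runs whose flanking measured values are at most
#' `max_gap_min` apart in time are linearly interpolated and flagged imputed
#' (status 2); longer runs and leading/trailing runs are left missing. The
#' bound is inclusive: a gap of exactly `max_gap_min` minutes is imputed.
#'
#' @param ds a `dist_series`.
#' @param max_gap_min maximum imputable gap, minutes (default 30).
#' @return the `dist_series` with imputed values filled in.
#' @export
impute_gaps <- function(ds, max_gap_min = 30) {
  stopifnot(inherits(ds, "dist_series"))
  if (ncol(ds$d) == 0) return(ds)
  # flanking measured bins <= max_gap_min apart <=> NA run <= maxgap bins
  maxgap <- as.integer(round(max_gap_min * 60 / ds$dt)) - 1L
  filled <- impute_linear_cpp(ds$d, ds$status, maxgap)
  ds$d <- filled$d
  ds$status <- filled$status
  ds
}
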