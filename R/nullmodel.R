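#' Draw whole-day time shifts for the null model
#'
#' Each fish gets an independent shift drawn uniformly from
#' `{0, ..., max_shift_days}` whole days. Shifting by whole days preserves
#' the time-of-day (and, under a monthly wrap, the seasonal regime) of every
#' fix while breaking inter-individual timing.
#'
#' @param fish character vector of fish ids.
#' @param max_shift_days largest shift (default 6, i.e. shifts from a week).
#' @return named integer vector of day shifts.
#' @export
draw_day_shifts <- function(fish, max_shift_days = 6) {
  stats::setNames(sample.int(max_shift_days + 1L, length(fish),
                             replace = TRUE) - 1L, fish)
}

#' Probability that two fish receive the same shift
#'
#' With shifts uniform on `{0, ..., k-1}`, a pair shares its shift with
#' probability `k (1/k)^2 = 1/k` (1/7 for the default week), so a pair's
#' mutual timing survives the shuffle with that probability.
#'
#' @param n_shifts number of distinct shifts (default 7).
#' @return the analytic probability.
#' @export
same_shift_pair_prob <- function(n_shifts = 7) n_shifts * (1 / n_shifts)^2

#' Circularly time-shift trajectories by whole days
#'
#' Rotates each fish's series (coordinates, depth, temperature and validity
#' pattern move together) forward by its shift, wrapping within the analysis
#' window, so the value at time `t` comes from `t - shift` (mod window).
#'
#' @param traj a `traj_set`.
#' @param shifts named integer day shifts from [draw_day_shifts()].
#' @return the shifted `traj_set`.
#' @export
shuffle_trajectories <- function(traj, shifts) {
  stopifnot(inherits(traj, "traj_set"), all(traj$fish %in% names(shifts)))
  n <- traj$n_bins
  if (n * traj$dt < 7 * 86400)
    warning("analysis window shorter than 7 days: shift space is degenerate")
  bins_per_day <- as.integer(round(86400 / traj$dt))
  out <- traj
  for (f in seq_along(traj$fish)) {
    s_bins <- (as.integer(shifts[[traj$fish[f]]]) * bins_per_day) %% n
    if (s_bins == 0) next
    idx <- c((n - s_bins + 1):n, 1:(n - s_bins))  # source index per target bin
    for (field in c("x", "y", "depth", "temp", "valid"))
      out[[field]][, f] <- traj[[field]][idx, f]
  }
  out
}

#' Effect sizes of social attraction
#'
#' Ratio of a statistic in the real data to the same statistic in the
#' shuffled data, per window and diel period, for interaction counts and
#' average local clustering. A ratio is NA (flagged, never infinite) when the
#' shuffled statistic is zero.
#'
#' @param real_events,shuffled_events event tables processed by the identical
#'   contact pipeline.
#' @param windows data.frame/list with `start`, `end` (epoch seconds); a
#'   single window may be given as `c(start, end)`.
#' @param periods diel periods (default day and night).
#' @param nodes node set used for both networks.
#' @return data.table `window_start`, `window_end`, `period`, `metric`,
#'   `real`, `shuffled`, `ratio`.
#' @export
effect_sizes <- function(real_events, shuffled_events, windows,
                         periods = c("day", "night"), nodes = NULL) {
  if (is.numeric(windows) && length(windows) == 2)
    windows <- data.frame(start = windows[1], end = windows[2])
  windows <- as.data.frame(windows)
  if (is.null(nodes))
    nodes <- sort(unique(c(real_events$a, real_events$b,
                           shuffled_events$a, shuffled_events$b)))
  res <- list()
  for (w in seq_len(nrow(windows))) {
    for (per in periods) {
      nr <- aggregate_network(real_events, windows$start[w], windows$end[w],
                              per, nodes, provenance = "real")
      ns <- aggregate_network(shuffled_events, windows$start[w], windows$end[w],
                              per, nodes, provenance = "shuffled")
      cnt_r <- sum(nr$edges$weight_count); cnt_s <- sum(ns$edges$weight_count)
      cl_r <- avg_local_clustering(nr); cl_s <- avg_local_clustering(ns)
      res[[length(res) + 1]] <- data.table::data.table(
        window_start = windows$start[w], window_end = windows$end[w],
        period = per,
        metric = c("interaction_count", "clustering"),
        real = c(cnt_r, cl_r), shuffled = c(cnt_s, cl_s),
        ratio = c(if (cnt_s > 0) cnt_r / cnt_s else NA_real_,
                  if (isTRUE(cl_s > 0)) cl_r / cl_s else NA_real_))
    }
  }
  data.table::rbindlist(res)
}

#' Run the shuffled pipeline alongside the real one
#'
#' Convenience wrapper: shifts the trajectories, recomputes distances,
#' imputation and contacts with the identical settings, and returns the
#' shuffled event table. Several replicates can be requested; the paper-style
#' single replicate is the default, and multi-replicate output carries a
#' `replicate` column (an extension flagged in the run metadata).
#'
#' @param traj a `traj_set` (real data).
#' @param diel matching `diel_calendar`.
#' @param n_replicates number of independent shuffles.
#' @param threshold,merge_gap_s,min_duration_s,max_gap_min contact settings.
#' @param use_depth 3-D (default) or 2-D distances.
#' @return list of `events` (data.table with `replicate`) and `shifts`
#'   (list of the shift vectors used).
#' @export
shuffled_contacts <- function(traj, diel, n_replicates = 1, threshold = 10,
                              merge_gap_s = 300, min_duration_s = 30,
                              max_gap_min = 30, use_depth = TRUE) {
  evs <- vector("list", n_replicates)
  shifts <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sh <- draw_day_shifts(traj$fish)
    st <- shuffle_trajectories(traj, sh)
    ds <- impute_gaps(pairwise_distances(st, use_depth = use_depth),
                      max_gap_min = max_gap_min)
    ev <- detect_contacts(ds, diel, threshold = threshold,
                          merge_gap_s = merge_gap_s,
                          min_duration_s = min_duration_s)
    ev[, replicate := r]
    evs[[r]] <- ev
    shifts[[r]] <- sh
  }
  list(events = data.table::rbindlist(evs), shifts = shifts)
}
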