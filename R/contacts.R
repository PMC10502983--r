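#' Threshold a distance series into link activity
#'
#' A bin is active iff the pair's distance is strictly below the threshold
#' and the bin is not missing (measured or imputed both count).
#'
#' @param ds a `dist_series`.
#' @param threshold proximity threshold in metres (default 10, strict `<`).
#' @return logical matrix (bins x pairs) of link activity.
#' @export
threshold_series <- function(ds, threshold = 10) {
  stopifnot(inherits(ds, "dist_series"))
  if (threshold <= 0) stop("threshold must be positive")
  act <- !is.na(ds$d) & ds$d < threshold & ds$status > 0L
  act
}

#' Merge and filter a binary activity series into contact events
#'
#' Maximal runs of active bins become candidate events; candidates whose
#' inter-gap is shorter than `merge_gap_s` are merged (a gap of
#' `merge_gap_s` or more starts a new event, and merged gap time counts
#' inside the event span); events supported by a single active bin are then
#' removed, as are events spanning less than `min_duration_s` (two
#' consecutive bins at the 15 s grid).
#'
#' @param active logical vector of per-bin link activity.
#' @param t0 epoch seconds of the first bin start.
#' @param dt bin width (s).
#' @param merge_gap_s gaps strictly shorter than this merge (default 300).
#' @param min_duration_s minimum event span (default 30).
#' @return data.table with `start`, `end` (epoch s; end exclusive,
#'   `end = start of last bin + dt`), `duration_s` (= end - start, so merged
#'   gaps count), `n_bins` (active bins supporting the event).
#' @export
merge_and_filter <- function(active, t0 = 0, dt = 15, merge_gap_s = 300,
                             min_duration_s = 30) {
  active <- as.logical(active)
  active[is.na(active)] <- FALSE
  empty <- data.table::data.table(start = numeric(0), end = numeric(0),
                                  duration_s = numeric(0), n_bins = integer(0))
  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_s <- starts[r$values]; run_e <- ends[r$values]   # 1-based bin indices
  # merge runs separated by < merge_gap_s of inactive time
  gap_bins <- if (length(run_s) > 1) run_s[-1] - run_e[-length(run_e)] - 1L else integer(0)
  new_event <- c(TRUE, gap_bins * dt >= merge_gap_s)
  runs <- data.table::data.table(s = run_s, e = run_e, ev = cumsum(new_event))
  agg <- runs[, .(s = min(s), e = max(e), n = sum(e - s + 1L)), by = ev]
  out <- data.table::data.table(
    start = t0 + (agg$s - 1) * dt,
    end = t0 + agg$e * dt,
    n_bins = as.integer(agg$n))
  out[, duration_s := end - start]
  out <- out[n_bins >= 2L & duration_s >= min_duration_s]
  out[, .(start, end, duration_s, n_bins)]
}

#' Detect contact events for every pair
#'
#' Runs [threshold_series()] and [merge_and_filter()] over all pairs and
#' labels each event with the diel period and solar day of its start bin
#' (events spanning a boundary are not split).
#'
#' @param ds a `dist_series` (imputed or not).
#' @param diel a `diel_calendar` on the same grid, or `NULL` to label all
#'   events `"all"`.
#' @param threshold proximity threshold (m).
#' @param merge_gap_s,min_duration_s see [merge_and_filter()].
#' @return data.table `pair`, `a`, `b`, `start`, `end`, `duration_s`,
#'   `n_bins`, `period`, `solar_day`.
#' @export
detect_contacts <- function(ds, diel = NULL, threshold = 10,
                            merge_gap_s = 300, min_duration_s = 30) {
  stopifnot(inherits(ds, "dist_series"))
  if (threshold <= 0) stop("threshold must be positive")
  gap_bins <- as.integer(ceiling(merge_gap_s / ds$dt))
  raw <- events_cpp(ds$d, ds$status, threshold, gap_bins, min_active = 2L)
  out <- data.table::data.table(
    pair = ds$pairs$pair[raw$pair], a = ds$pairs$a[raw$pair],
    b = ds$pairs$b[raw$pair],
    start = ds$t0 + (raw$s_bin - 1) * ds$dt,
    end = ds$t0 + raw$e_bin * ds$dt,
    n_bins = raw$n_bins)
  out[, duration_s := end - start]
  out <- out[duration_s >= min_duration_s]
  if (nrow(out) == 0)
    return(data.table::data.table(pair = character(0), a = character(0),
                                  b = character(0), start = numeric(0),
                                  end = numeric(0), duration_s = numeric(0),
                                  n_bins = integer(0), period = character(0),
                                  solar_day = integer(0)))
  start_bin <- as.integer(round((out$start - ds$t0) / ds$dt)) + 1L
  if (is.null(diel)) {
    out[, period := "all"]
    out[, solar_day := NA_integer_]
  } else {
    stopifnot(inherits(diel, "diel_calendar"),
              diel$t0 == ds$t0, diel$dt == ds$dt, diel$n_bins >= ds$n_bins)
    out[, period := diel$period[start_bin]]
    out[, solar_day := diel$solar_day[start_bin]]
  }
  data.table::setorder(out, pair, start)
  out[, .(pair, a, b, start, end, duration_s, n_bins, period, solar_day)]
}
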