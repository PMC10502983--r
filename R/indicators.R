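#' Spatial entropy of an occupancy distribution
#'
#' Shannon entropy (natural log) of the fraction of time an individual spent
#' in each cell of a square grid: `S = -sum_m c_m log c_m`, with `c_m` the
#' fraction of valid bins in cell `m`. The grid is anchored at `origin`
#' (by convention the lake bounding-box corner), cells are
#' `cell_size x cell_size` metres.
#'
#' @param x,y coordinates of valid bins (m); must be non-empty.
#' @param cell_size cell edge (m), default 10.
#' @param origin numeric length-2 grid anchor.
#' @return entropy in nats (`>= 0`, `<=` log of occupied cell count).
#' @export
spatial_entropy <- function(x, y, cell_size = 10, origin = c(0, 0)) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) return(NA_real_)
  cell <- paste(floor((x - origin[1]) / cell_size),
                floor((y - origin[2]) / cell_size))
  c_m <- tabulate(factor(cell)) / length(x)
  -sum(c_m * log(c_m))
}

#' Per-bin speed series
#'
#' Displacement between consecutive valid bins divided by the bin width;
#' undefined (NA) for the first bin and for any bin following an invalid bin.
#'
#' @param traj a `traj_set`.
#' @param use_depth include the depth axis in the displacement (default
#'   `FALSE`: horizontal swimming speed).
#' @return numeric matrix (bins x fish) of speeds in m/s.
#' @export
speed_series <- function(traj, use_depth = FALSE) {
  stopifnot(inherits(traj, "traj_set"))
  n <- traj$n_bins
  pad <- function(m) rbind(NA_real_, m[-n, , drop = FALSE])
  dx <- traj$x - pad(traj$x)
  dy <- traj$y - pad(traj$y)
  disp2 <- dx * dx + dy * dy
  if (use_depth) {
    dz <- traj$depth - pad(traj$depth)
    disp2 <- disp2 + dz * dz
  }
  sqrt(disp2) / traj$dt
}

#' Daily individual behavioural indicators
#'
#' For each fish, solar day (sunrise-to-sunrise, so nights are not split at
#' midnight) and diel period: mean temperature `T_i`, mean distance from
#' shore `d_i`, spatial entropy `S_i`, mean speed `v_i` and mean depth `h_i`,
#' over valid bins only. Summaries with zero valid bins are NA, never zero.
#'
#' @param traj a `traj_set`.
#' @param diel a `diel_calendar` on the same grid.
#' @param lake a `lake` object (for `d_i`; entropy cells are anchored at its
#'   bounding-box corner).
#' @param cell_size entropy cell edge (m).
#' @return data.table `fish_id`, `solar_day`, `period`, `n_bins`, `T_i`,
#'   `d_i`, `S_i`, `v_i`, `h_i`.
#' @export
daily_indicators <- function(traj, diel, lake, cell_size = 10) {
  stopifnot(inherits(traj, "traj_set"), inherits(diel, "diel_calendar"),
            diel$t0 == traj$t0, diel$dt == traj$dt,
            diel$n_bins >= traj$n_bins)
  nb <- traj$n_bins
  origin <- c(min(lake$x), min(lake$y))
  v <- speed_series(traj)
  shore <- matrix(NA_real_, nb, length(traj$fish))
  for (f in seq_along(traj$fish)) {
    ok <- traj$valid[, f]
    if (any(ok))
      shore[ok, f] <- distance_from_shore(traj$x[ok, f], traj$y[ok, f],
                                          lake, check = FALSE)
  }
  res <- vector("list", length(traj$fish))
  key <- paste(diel$solar_day[seq_len(nb)], diel$period[seq_len(nb)])
  for (f in seq_along(traj$fish)) {
    dtf <- data.table::data.table(
      solar_day = diel$solar_day[seq_len(nb)],
      period = diel$period[seq_len(nb)],
      ok = traj$valid[, f],
      x = traj$x[, f], y = traj$y[, f],
      temp = traj$temp[, f], depth = traj$depth[, f],
      v = v[, f], shore = shore[, f])
    res[[f]] <- dtf[ok == TRUE,
      .(fish_id = traj$fish[f], n_bins = .N,
        T_i = mean(temp), d_i = mean(shore),
        S_i = spatial_entropy(x, y, cell_size, origin),
        v_i = mean(v, na.rm = TRUE), h_i = mean(depth)),
      by = .(solar_day, period)]
  }
  out <- data.table::rbindlist(res)
  data.table::setcolorder(out, c("fish_id", "solar_day", "period"))
  data.table::setorder(out, fish_id, solar_day, period)
  out[]
}

#' Daily dyadic social indicators
#'
#' For each pair, solar day and diel period: mean interaction duration
#' `tau_pos` (s), mean time between consecutive interactions `tau_neg` (s),
#' and interaction probability `p_n` — over the bins in which the pair is
#' detected (distance status not missing), the fraction falling inside a
#' contact event span. Pairs with no detected bins in a stratum are omitted;
#' `tau_pos`/`tau_neg` are NA where no (or only one) event exists.
#'
#' @param events output of [detect_contacts()] (with diel labels).
#' @param ds the `dist_series` the events came from.
#' @param diel the `diel_calendar` used for labelling.
#' @return data.table `pair`, `solar_day`, `period`, `n_detected`,
#'   `n_active`, `p_n`, `tau_pos`, `tau_neg`, `n_events`.
#' @export
dyad_stats <- function(events, ds, diel) {
  stopifnot(inherits(ds, "dist_series"), inherits(diel, "diel_calendar"))
  nb <- ds$n_bins
  sd_bin <- diel$solar_day[seq_len(nb)]
  per_bin <- diel$period[seq_len(nb)]

  # per-bin activity (inside an event span) per pair
  act <- matrix(FALSE, nb, nrow(ds$pairs))
  if (nrow(events) > 0) {
    pidx <- match(events$pair, ds$pairs$pair)
    sb <- pmax(1L, as.integer(round((events$start - ds$t0) / ds$dt)) + 1L)
    eb <- pmin(nb, as.integer(round((events$end - ds$t0) / ds$dt)))
    for (e in seq_len(nrow(events))) act[sb[e]:eb[e], pidx[e]] <- TRUE
  }

  res <- vector("list", nrow(ds$pairs))
  for (p in seq_len(nrow(ds$pairs))) {
    det <- ds$status[, p] > 0L
    if (!any(det)) { res[[p]] <- NULL; next }
    base <- data.table::data.table(solar_day = sd_bin, period = per_bin,
                                   det = det, on_ = act[, p])
    tab <- base[det == TRUE,
                .(n_detected = .N, n_active = sum(on_), p_n = mean(on_)),
                by = .(solar_day, period)]
    tab[, pair := ds$pairs$pair[p]]
    res[[p]] <- tab
  }
  out <- data.table::rbindlist(res)
  if (is.null(out) || nrow(out) == 0)
    return(data.table::data.table(pair = character(0), solar_day = integer(0),
                                  period = character(0), n_detected = integer(0),
                                  n_active = integer(0), p_n = numeric(0),
                                  tau_pos = numeric(0), tau_neg = numeric(0),
                                  n_events = integer(0)))

  # event-level summaries per pair x solar day x period
  if (nrow(events) > 0) {
    ev <- data.table::copy(events)
    data.table::setorder(ev, pair, period, start)
    ev[, gap_s := start - data.table::shift(end), by = .(pair, solar_day, period)]
    evs <- ev[, .(tau_pos = mean(duration_s),
                  tau_neg = if (.N > 1) mean(gap_s, na.rm = TRUE) else NA_real_,
                  n_events = .N),
              by = .(pair, solar_day, period)]
    out <- merge(out, evs, by = c("pair", "solar_day", "period"), all.x = TRUE)
  } else {
    out[, `:=`(tau_pos = NA_real_, tau_neg = NA_real_, n_events = 0L)]
  }
  out[is.na(n_events), n_events := 0L]
  data.table::setcolorder(out, c("pair", "solar_day", "period"))
  data.table::setorder(out, pair, solar_day, period)
  out[]
}

#' Population averages of daily indicators
#'
#' Arithmetic mean over individuals (or pairs) with defined values, per solar
#' day and diel period; undefined values are excluded, never zero-filled.
#' For dyadic tables a pooled interaction probability
#' (total active pair-bins / total detected pair-bins) is also returned as
#' `p_pooled`.
#'
#' @param daily a table from [daily_indicators()] or [dyad_stats()].
#' @return data.table of per-day, per-period population means.
#' @export
population_means <- function(daily) {
  dtb <- data.table::as.data.table(daily)
  if ("p_n" %in% names(dtb)) {
    out <- dtb[, .(p = mean(p_n, na.rm = TRUE),
                   p_pooled = sum(n_active) / sum(n_detected),
                   tau_pos = mean(tau_pos, na.rm = TRUE),
                   tau_neg = mean(tau_neg, na.rm = TRUE),
                   n_pairs = .N),
               by = .(solar_day, period)]
  } else {
    out <- dtb[, .(T_i = mean(T_i, na.rm = TRUE), d_i = mean(d_i, na.rm = TRUE),
                   S_i = mean(S_i, na.rm = TRUE), v_i = mean(v_i, na.rm = TRUE),
                   h_i = mean(h_i, na.rm = TRUE), n_fish = .N),
               by = .(solar_day, period)]
  }
  data.table::setorder(out, solar_day, period)
  out[]
}
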