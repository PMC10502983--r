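#' Read a fix table from CSV
#'
#' Validates the schema (`fish_id`, `timestamp` ISO-8601 UTC, `x_m`, `y_m`,
#' `depth_m`, optional `temp_c`), parses timestamps, drops rows with
#' unparseable timestamps, non-finite coordinates or negative depth (logged
#' with counts), and returns a time-sorted table.
#'
#' @param path CSV path.
#' @return data.table with numeric epoch-second timestamps and an attribute
#'   `n_dropped` (named counts of dropped rows).
#' @export
read_fixes <- function(path) {
  fx <- data.table::fread(path)
  if (nrow(fx) == 0) stop("empty fix file: ", path)
  req <- c("fish_id", "timestamp", "x_m", "y_m", "depth_m")
  miss <- setdiff(req, names(fx))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!("temp_c" %in% names(fx))) fx[, temp_c := NA_real_]
  ts <- fx$timestamp
  if (inherits(ts, c("POSIXct", "IDate", "Date"))) {
    ts <- as.numeric(as.POSIXct(ts, tz = "UTC"))
  } else if (!is.numeric(ts)) {
    ch <- as.character(ts)
    ts <- as.numeric(as.POSIXct(ch, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    plain <- is.na(ts)
    if (any(plain))
      ts[plain] <- as.numeric(strptime(ch[plain], "%Y-%m-%d %H:%M:%OS",
                                       tz = "UTC"))
  }
  bad_ts <- !is.finite(ts)
  bad_xy <- !is.finite(fx$x_m) | !is.finite(fx$y_m)
  bad_depth <- !is.finite(fx$depth_m) | fx$depth_m < 0
  drop <- bad_ts | bad_xy | bad_depth
  n_dropped <- c(timestamp = sum(bad_ts), coords = sum(bad_xy & !bad_ts),
                 depth = sum(bad_depth & !bad_ts & !bad_xy))
  if (any(drop))
    message("read_fixes: dropped ", sum(drop), " bad row(s) [",
            paste(names(n_dropped), n_dropped, sep = "=", collapse = ", "), "]")
  fx[, timestamp := ts]
  fx <- fx[!drop]
  if (nrow(fx) == 0) stop("no valid rows in fix file: ", path)
  data.table::setkey(fx, fish_id, timestamp)
  data.table::setattr(fx, "n_dropped", n_dropped)
  fx[]
}

#' Write / read weighted edge lists
#'
#' Plain-CSV round-trippable serialisation of aggregated networks.
#'
#' @param nets list of `agg_network`s.
#' @param path CSV path.
#' @name edge_list_io
#' @export
write_edge_lists <- function(nets, path) {
  rows <- lapply(nets, function(n) {
    e <- if (nrow(n$edges) > 0) data.table::copy(n$edges) else
      data.table::data.table(a = NA_character_, b = NA_character_,
                             weight_count = NA_integer_,
                             weight_seconds = NA_real_)
    e[, `:=`(window_start = n$window[1], window_end = n$window[2],
             period = n$period, provenance = n$provenance)]
    e
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' @param nodes node set to attach to each re-read network.
#' @rdname edge_list_io
#' @export
read_edge_lists <- function(path, nodes) {
  tb <- data.table::fread(path)
  keys <- unique(tb[, .(window_start, window_end, period, provenance)])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i]
    e <- tb[k, on = names(k)][!is.na(a),
                              .(a, b, weight_count, weight_seconds)]
    structure(list(nodes = nodes, edges = e,
                   window = c(k$window_start, k$window_end),
                   period = k$period, provenance = k$provenance),
              class = "agg_network")
  })
}

#' Run configuration for the full pipeline
#'
#' Bundles the analysis constants: 10 m proximity threshold, 30 s minimum
#' duration, 5 min merge gap, 30 min imputation bound, 10 m entropy cells,
#' 0-6 day shifts. Serialised verbatim into the run manifest for provenance.
#'
#' @param sim a [sim_config()] (simulated input), or `NULL` when reading
#'   fixes from `fix_csv`.
#' @param fix_csv path to a fix CSV (ignored when `sim` is given).
#' @param lake a `lake` object (required with `fix_csv`).
#' @param threshold_m,min_duration_s,merge_gap_min,impute_max_min,cell_m,max_shift_days
#'   pipeline constants.
#' @param use_depth 3-D (default) or 2-D proximity.
#' @param ladder_h timescale ladder (hours).
#' @param timescale_period diel stratum for the timescale curve.
#' @param seed analysis seed (shuffles + community detection).
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, fix_csv = NULL, lake = NULL,
                       threshold_m = 10, min_duration_s = 30,
                       merge_gap_min = 5, impute_max_min = 30, cell_m = 10,
                       max_shift_days = 6, use_depth = TRUE,
                       ladder_h = ladder_durations(),
                       timescale_period = "all",
                       seed = 1L, out_dir = tempfile("shoalnet_run_")) {
  if (is.null(sim) && is.null(fix_csv)) stop("need sim config or fix_csv")
  if (!is.null(fix_csv) && is.null(sim) && is.null(lake))
    stop("a lake polygon is required with CSV input (distance from shore, d_i, needs it)")
  th <- c(threshold_m, min_duration_s, merge_gap_min, impute_max_min, cell_m)
  if (any(th <= 0)) stop("all thresholds must be positive")
  structure(list(sim = sim, fix_csv = fix_csv,
                 lake = if (!is.null(sim)) sim$lake else lake,
                 threshold_m = threshold_m, min_duration_s = min_duration_s,
                 merge_gap_min = merge_gap_min, impute_max_min = impute_max_min,
                 cell_m = cell_m, max_shift_days = max_shift_days,
                 use_depth = use_depth, ladder_h = ladder_h,
                 timescale_period = timescale_period,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) fixes, resample, build distance series, impute, detect
#' contacts, compute individual and dyadic indicators, aggregate monthly
#' day/night networks, run the day-shift null model and effect sizes, and —
#' when the data span at least 28 days — the timescale analysis on the first
#' 28 days. Writes all tables as CSV plus a machine-readable JSON manifest
#' (config echo, seeds, row counts, file hashes); deterministic under fixed
#' seeds.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all intermediate objects and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_population(config$sim))
    fixes <- sim$fixes
  } else {
    fixes <- stage("read_fixes", read_fixes(config$fix_csv))
  }
  lake <- config$lake

  set.seed(config$seed)
  traj <- stage("resample", resample_median(fixes))
  diel <- stage("diel", classify_diel(traj$t0, traj$n_bins, lake$lat, lake$lon,
                                      dt = traj$dt))
  ds <- stage("distances",
              impute_gaps(pairwise_distances(traj, use_depth = config$use_depth),
                          max_gap_min = config$impute_max_min))
  events <- stage("contacts",
                  detect_contacts(ds, diel, threshold = config$threshold_m,
                                  merge_gap_s = config$merge_gap_min * 60,
                                  min_duration_s = config$min_duration_s))
  ind <- stage("indicators", daily_indicators(traj, diel, lake,
                                              cell_size = config$cell_m))
  dyads <- stage("dyad_stats", dyad_stats(events, ds, diel))
  nets <- stage("networks", monthly_networks(events, nodes = traj$fish))

  shuf <- stage("null_model",
                shuffled_contacts(traj, diel, n_replicates = 1,
                                  threshold = config$threshold_m,
                                  merge_gap_s = config$merge_gap_min * 60,
                                  min_duration_s = config$min_duration_s,
                                  max_gap_min = config$impute_max_min,
                                  use_depth = config$use_depth))
  span <- c(traj$t0, traj$t0 + traj$n_bins * traj$dt)
  eff <- stage("effect_sizes",
               effect_sizes(events, shuf$events, windows = span,
                            periods = c("day", "night", "all"),
                            nodes = traj$fish))

  curve <- NULL
  if (traj$n_bins * traj$dt >= 28 * 86400) {
    curve <- stage("timescales",
                   timescale_curve(events, shuf$events, month_start = traj$t0,
                                   period = config$timescale_period,
                                   nodes = traj$fish,
                                   durations_h = config$ladder_h,
                                   seed = config$seed))
  }

  ## --- outputs
  od <- config$out_dir
  paths <- c(contacts = file.path(od, "contact_events.csv"),
             indicators = file.path(od, "daily_indicators.csv"),
             dyads = file.path(od, "dyad_indicators.csv"),
             edges = file.path(od, "monthly_edge_lists.csv"),
             effects = file.path(od, "effect_sizes.csv"))
  data.table::fwrite(events, paths["contacts"])
  data.table::fwrite(ind, paths["indicators"])
  data.table::fwrite(dyads, paths["dyads"])
  write_edge_lists(nets$network, paths["edges"])
  data.table::fwrite(eff, paths["effects"])
  if (!is.null(curve)) {
    paths <- c(paths, timescales = file.path(od, "timescale_curve.csv"))
    data.table::fwrite(curve, paths["timescales"])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("shoalnet")),
    config = serialize_config(config),
    shifts = lapply(shuf$shifts, as.list),
    n_fixes = nrow(fixes), n_bins = traj$n_bins, n_fish = length(traj$fish),
    n_pairs = nrow(ds$pairs), n_events = nrow(events),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      names(paths))))
  manifest_path <- file.path(od, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(fixes = fixes, sim = sim, traj = traj, diel = diel, ds = ds,
                 events = events, indicators = ind, dyads = dyads,
                 networks = nets, shuffled = shuf, effects = eff,
                 curve = curve, manifest = manifest,
                 manifest_path = manifest_path))
}

# config echo for the manifest: everything scalar/vector, lake as WKT,
# schedule by name
serialize_config <- function(config) {
  out <- list(threshold_m = config$threshold_m,
              min_duration_s = config$min_duration_s,
              merge_gap_min = config$merge_gap_min,
              impute_max_min = config$impute_max_min,
              cell_m = config$cell_m, max_shift_days = config$max_shift_days,
              use_depth = config$use_depth,
              ladder_h = as.integer(config$ladder_h),
              timescale_period = config$timescale_period,
              seed = config$seed,
              lake_wkt = lake_to_wkt(config$lake),
              lake_lat = config$lake$lat, lake_lon = config$lake$lon,
              fix_csv = config$fix_csv)
  if (!is.null(config$sim)) {
    s <- config$sim
    out$sim <- list(n_fish = s$n_fish, duration_days = s$duration_days,
                    burst_interval = s$burst_interval, n_groups = s$n_groups,
                    group_switch_timescale_h = s$group_switch_timescale_h,
                    attraction_strength = s$attraction_strength,
                    group_radius = s$group_radius,
                    speed_day = as.list(s$speed_day),
                    speed_night = as.list(s$speed_night),
                    offshore_bias_day = s$offshore_bias_day,
                    littoral_bias_night = s$littoral_bias_night,
                    detection_yield_base = s$detection_yield_base,
                    detection_off_mean_min = s$detection_off_mean_min,
                    detection_yield_summer_day_penalty = s$detection_yield_summer_day_penalty,
                    jitter_sd = s$jitter_sd, depth_sd = s$depth_sd,
                    start = format(s$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    rng_seed = s$rng_seed)
  }
  out
}
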