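#' Window-duration ladder for the timescale analysis
#'
#' Durations (hours) partitioning a 672 h (28-day) month from one 4-week
#' window down to 672 one-hour windows. Strict halving from 672 h cannot
#' reach 1 h through integers, so the ladder uses divisors of 672.
#'
#' @return integer vector of durations in hours, longest first.
#' @export
ladder_durations <- function() c(672L, 336L, 168L, 84L, 48L, 24L, 12L, 6L, 3L, 1L)

#' Split a 28-day month into equal contiguous windows
#'
#' @param month_start start of the 28-day window (epoch seconds or POSIXct).
#' @param durations_h ladder of window durations (hours); each must divide 672.
#' @param total_h total window length in hours; must be 672.
#' @return named list (one element per duration) of data.tables with `start`,
#'   `end` (half-open windows); at each level `n_slices * duration = 672 h`.
#' @export
split_ladder <- function(month_start, durations_h = ladder_durations(),
                         total_h = 672) {
  if (total_h != 672) stop("the month window must be exactly 672 h (28 days)")
  if (any(672 %% durations_h != 0)) stop("durations must divide 672 h")
  t0 <- as.numeric(month_start)
  out <- lapply(durations_h, function(d) {
    n <- 672L %/% d
    s <- t0 + (seq_len(n) - 1) * d * 3600
    data.table::data.table(start = s, end = s + d * 3600)
  })
  names(out) <- as.character(durations_h)
  out
}

#' Excess (above-background) interaction network
#'
#' Edge weight is the real interaction count minus the null-model count,
#' clamped at zero (one-sided: negative excess means no social signal);
#' zero-weight edges are dropped.
#'
#' @param real,null `agg_network`s over the same window and period.
#' @return an `agg_network` with provenance `"excess"`.
#' @export
excess_network <- function(real, null) {
  stopifnot(inherits(real, "agg_network"), inherits(null, "agg_network"))
  if (!isTRUE(all.equal(real$window, null$window)) ||
      !identical(real$period, null$period))
    stop("mismatched windows or periods")
  m <- merge(real$edges, null$edges, by = c("a", "b"), all = TRUE,
             suffixes = c("_r", "_n"))
  for (cn in c("weight_count_r", "weight_count_n", "weight_seconds_r",
               "weight_seconds_n"))
    m[is.na(get(cn)), (cn) := 0]
  m[, weight_count := pmax(0, weight_count_r - weight_count_n)]
  m[, weight_seconds := pmax(0, weight_seconds_r - weight_seconds_n)]
  edges <- m[weight_count > 0, .(a, b, weight_count, weight_seconds)]
  structure(list(nodes = real$nodes, edges = edges, window = real$window,
                 period = real$period, provenance = "excess"),
            class = "agg_network")
}

#' Map-equation community detection
#'
#' Two-level Infomap (igraph implementation) on the weighted undirected
#' network, with a fixed seed for reproducibility. Isolated nodes form
#' singleton communities and are never counted toward the >= 3-member tally.
#'
#' @param net an `agg_network`.
#' @param seed RNG seed for the (stochastic) search.
#' @param min_size community size threshold for the count (default 3).
#' @return list of class `community_partition`: `membership` (named integer),
#'   `n_communities` (with `>= min_size` members), `sizes`.
#' @export
detect_communities <- function(net, seed = 42L, min_size = 3L) {
  stopifnot(inherits(net, "agg_network"))
  if (nrow(net$edges) == 0) {
    memb <- stats::setNames(seq_along(net$nodes), net$nodes)
    return(structure(list(membership = memb, n_communities = 0L,
                          sizes = rep(1L, length(net$nodes))),
                     class = "community_partition"))
  }
  g <- as_igraph(net, weighted = TRUE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cm <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                                nb.trials = 5)
  memb <- igraph::membership(cm)
  sizes <- as.integer(table(memb))
  structure(list(membership = memb,
                 n_communities = sum(sizes >= min_size),
                 sizes = sizes),
            class = "community_partition")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Community-persistence curve across aggregation timescales
#'
#' For each ladder duration, slices the 28-day month into equal windows,
#' builds the real and null networks per slice, subtracts the background
#' ([excess_network()]), runs [detect_communities()], and records the mean
#' and standard error (across slices holding at least one edge) of the number
#' of communities with >= 3 members, plus the mean percentage of realized
#' links.
#'
#' @param real_events,null_events event tables from the identical pipeline.
#' @param month_start start of the 28-day window.
#' @param period `"day"`, `"night"` or `"all"`.
#' @param nodes node set.
#' @param durations_h ladder (hours).
#' @param seed community-detection seed.
#' @return data.table of class `timescale_curve`: `duration_h`, `n_slices`,
#'   `n_slices_used`, `mean_communities`, `sem_communities`,
#'   `pct_realized_links`.
#' @export
timescale_curve <- function(real_events, null_events, month_start,
                            period = "all", nodes, durations_h = ladder_durations(),
                            seed = 42L) {
  slabs <- split_ladder(month_start, durations_h)
  n_possible <- length(nodes) * (length(nodes) - 1) / 2
  t0 <- as.numeric(month_start)
  prep <- function(ev) {
    ev <- data.table::as.data.table(ev)[start >= t0 & start < t0 + 672 * 3600]
    if (period != "all") { per <- period; ev <- ev[period == per] }
    ev
  }
  rev_ <- prep(real_events); nev <- prep(null_events)
  res <- vector("list", length(slabs))
  for (li in seq_along(slabs)) {
    wins <- slabs[[li]]
    dsec <- as.integer(names(slabs))[li] * 3600
    # per-slice pair counts, real minus null, clamped at zero
    cr <- rev_[, .(w_r = .N, s_r = sum(duration_s)),
               by = .(a, b, slice = floor((start - t0) / dsec))]
    cn <- nev[, .(w_n = .N, s_n = sum(duration_s)),
              by = .(a, b, slice = floor((start - t0) / dsec))]
    m <- merge(cr, cn, by = c("a", "b", "slice"), all = TRUE)
    m[is.na(w_r), `:=`(w_r = 0L, s_r = 0)]
    m[is.na(w_n), `:=`(w_n = 0L, s_n = 0)]
    m[, `:=`(weight_count = pmax(0L, w_r - w_n),
             weight_seconds = pmax(0, s_r - s_n))]
    m <- m[weight_count > 0]
    counts <- integer(nrow(wins)); edges <- integer(nrow(wins))
    if (nrow(m) > 0) {
      for (sl in unique(m$slice)) {
        ex <- structure(list(nodes = nodes,
                             edges = m[slice == sl,
                                       .(a, b, weight_count, weight_seconds)],
                             window = c(wins$start[sl + 1], wins$end[sl + 1]),
                             period = period, provenance = "excess"),
                        class = "agg_network")
        edges[sl + 1] <- nrow(ex$edges)
        counts[sl + 1] <- detect_communities(ex, seed = seed)$n_communities
      }
    }
    used <- edges > 0
    res[[li]] <- data.table::data.table(
      duration_h = as.integer(names(slabs)[li]),
      n_slices = nrow(wins), n_slices_used = sum(used),
      mean_communities = mean(counts),
      sem_communities = if (nrow(wins) > 1) sd(counts) / sqrt(nrow(wins)) else NA_real_,
      pct_realized_links = 100 * mean(edges) / n_possible)
  }
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "class", c("timescale_curve", class(out)))
  out
}

#' Social-memory timescale from a community-persistence curve
#'
#' The window duration at which the mean community count is maximal; ties are
#' broken toward the longest duration (the longest aggregation that does not
#' disintegrate the communities).
#'
#' @param curve a `timescale_curve`.
#' @return duration in hours, or NA if all counts are zero.
#' @export
memory_timescale <- function(curve) {
  stopifnot(all(c("duration_h", "mean_communities") %in% names(curve)))
  if (all(curve$mean_communities == 0)) return(NA_integer_)
  mx <- max(curve$mean_communities)
  max(curve$duration_h[curve$mean_communities == mx])
}
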