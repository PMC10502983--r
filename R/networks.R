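#' Aggregate contact events into a weighted network
#'
#' Edge weight is the number of the pair's events starting inside the
#' half-open window `[window_start, window_end)` whose diel label matches
#' `period`; total contact seconds are carried alongside.
#'
#' @param events table from [detect_contacts()].
#' @param window_start,window_end window bounds (epoch seconds or POSIXct).
#' @param period `"day"`, `"night"` or `"all"` (no filter).
#' @param nodes node (fish id) set; defaults to ids appearing in `events`.
#' @param provenance free label (`"real"`, `"shuffled"`, `"excess"`).
#' @return object of class `agg_network`: list with `nodes`, `edges`
#'   (data.table `a`, `b`, `weight_count`, `weight_seconds`), `window`,
#'   `period`, `provenance`.
#' @export
aggregate_network <- function(events, window_start, window_end, period = "all",
                              nodes = NULL, provenance = "real") {
  window_start <- as.numeric(window_start); window_end <- as.numeric(window_end)
  if (window_end <= window_start) stop("empty window")
  ev <- data.table::as.data.table(events)
  if (is.null(nodes)) nodes <- sort(unique(c(ev$a, ev$b)))
  sel <- ev[start >= window_start & start < window_end]
  if (period != "all") {
    per <- period
    sel <- sel[period == per]
  }
  edges <- if (nrow(sel) == 0) {
    data.table::data.table(a = character(0), b = character(0),
                           weight_count = integer(0), weight_seconds = numeric(0))
  } else {
    sel[, .(weight_count = .N, weight_seconds = sum(duration_s)), by = .(a, b)]
  }
  structure(list(nodes = nodes, edges = edges[],
                 window = c(window_start, window_end), period = period,
                 provenance = provenance),
            class = "agg_network")
}

#' Convert an aggregated network to an igraph graph
#' @param net an `agg_network`.
#' @param weighted attach `weight_count` as edge weight.
#' @return an igraph undirected graph including isolated nodes.
#' @export
as_igraph <- function(net, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges[, .(a, b)], directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (weighted && nrow(net$edges) > 0)
    igraph::E(g)$weight <- net$edges$weight_count
  g
}

#' Average local clustering coefficient
#'
#' Mean over nodes of triangles-through-node / (degree choose 2) on the
#' binarized graph (Watts-Strogatz local clustering). Nodes of degree < 2
#' contribute 0 by default; set `low_degree_zero = FALSE` to exclude them
#' from the average instead.
#'
#' @param net an `agg_network` (or igraph graph).
#' @param low_degree_zero count degree-<2 nodes as 0 (default) or drop them.
#' @return value in `[0, 1]`; NA for graphs with fewer than 3 nodes.
#' @export
avg_local_clustering <- function(net, low_degree_zero = TRUE) {
  g <- if (inherits(net, "agg_network")) as_igraph(net, weighted = FALSE) else net
  if (igraph::vcount(g) < 3) return(NA_real_)
  lc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (low_degree_zero) {
    lc[!is.finite(lc)] <- 0
    mean(lc)
  } else {
    lc <- lc[is.finite(lc)]
    if (length(lc) == 0) NA_real_ else mean(lc)
  }
}

#' Monthly day/night aggregated networks
#'
#' Splits the event table by calendar month and diel period and aggregates
#' each stratum into a weighted network.
#'
#' @param events table from [detect_contacts()].
#' @param nodes node set (fish ids).
#' @param periods diel periods to aggregate (default day and night).
#' @return data.table `month`, `period`, `network` (list column of
#'   `agg_network`), `clustering`, `n_interactions`.
#' @export
monthly_networks <- function(events, nodes, periods = c("day", "night")) {
  ev <- data.table::as.data.table(events)
  ev[, month := format(as.POSIXct(start, origin = "1970-01-01", tz = "UTC"), "%Y-%m")]
  months <- sort(unique(ev$month))
  grid <- data.table::CJ(month = months, period = periods)
  nets <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m0 <- as.numeric(as.POSIXct(paste0(grid$month[i], "-01"), tz = "UTC"))
    m1 <- as.numeric(seq(as.POSIXct(paste0(grid$month[i], "-01"), tz = "UTC"),
                         by = "1 month", length.out = 2)[2])
    nets[[i]] <- aggregate_network(ev, m0, m1, period = grid$period[i],
                                   nodes = nodes)
  }
  grid[, network := nets]
  grid[, clustering := vapply(nets, avg_local_clustering, numeric(1))]
  grid[, n_interactions := vapply(nets, function(n) sum(n$edges$weight_count),
                                  numeric(1))]
  grid[]
}
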