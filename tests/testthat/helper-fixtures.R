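# Small in-code fixtures shared across tests.

# a traj_set built directly from coordinate matrices (bins x fish)
make_traj <- function(x, y, depth = NULL, temp = NULL, t0 = 0, dt = 15,
                      fish = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(depth)) depth <- matrix(0, nrow(x), ncol(x))
  if (is.null(temp)) temp <- matrix(NA_real_, nrow(x), ncol(x))
  if (is.null(fish)) fish <- sprintf("f%02d", seq_len(ncol(x)))
  colnames(x) <- colnames(y) <- colnames(depth) <- colnames(temp) <- fish
  structure(list(fish = fish, t0 = t0, dt = dt, n_bins = nrow(x),
                 x = x, y = y, depth = as.matrix(depth),
                 temp = as.matrix(temp), valid = !is.na(x)),
            class = "traj_set")
}

# a dist_series with one pair from a plain distance vector (NA = missing)
make_ds <- function(d, t0 = 0, dt = 15, a = "f01", b = "f02") {
  d <- matrix(as.numeric(d), ncol = 1)
  status <- matrix(ifelse(is.na(d), 0L, 1L), ncol = 1)
  structure(list(pairs = data.table::data.table(
                   pair = paste(a, b, sep = "|"), a = a, b = b),
                 t0 = t0, dt = dt, n_bins = nrow(d), d = d, status = status),
            class = "dist_series")
}

# an agg_network from an edge data.frame (a, b, w)
make_net <- function(edges, nodes = NULL, window = c(0, 3600), period = "all") {
  e <- data.table::as.data.table(edges)
  if (!("weight_count" %in% names(e))) data.table::setnames(e, "w", "weight_count")
  if (!("weight_seconds" %in% names(e))) e[, weight_seconds := weight_count * 30]
  if (is.null(nodes)) nodes <- sort(unique(c(e$a, e$b)))
  structure(list(nodes = nodes, edges = e, window = window, period = period,
                 provenance = "real"),
            class = "agg_network")
}

# a small square test lake with the study site's solar coordinates
square_lake <- function(side = 200) {
  lake_polygon(c(0, side, side, 0), c(0, 0, side, side),
               lat = 52.995, lon = 13.5822)
}

# brute-force average local clustering by exhaustive triangle counting
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) { vals[i] <- 0; next }
    tri <- 0
    for (u in seq_along(nb)) for (v in seq_len(u - 1L))
      if (adj[nb[u], nb[v]] > 0) tri <- tri + 1
    vals[i] <- tri / (k * (k - 1) / 2)
  }
  mean(vals)
}

# brute-force contact events: explicit bin-by-bin interval scan
contact_oracle <- function(active, t0 = 0, dt = 15, merge_gap_s = 300,
                           min_duration_s = 30) {
  events <- list()
  cur_start <- NA; cur_last <- NA; cur_n <- 0
  for (i in seq_along(active)) {
    if (!isTRUE(active[i])) next
    if (is.na(cur_start)) {
      cur_start <- i; cur_last <- i; cur_n <- 1
    } else if ((i - cur_last - 1) * dt < merge_gap_s) {
      cur_last <- i; cur_n <- cur_n + 1
    } else {
      events[[length(events) + 1]] <- c(cur_start, cur_last, cur_n)
      cur_start <- i; cur_last <- i; cur_n <- 1
    }
  }
  if (!is.na(cur_start))
    events[[length(events) + 1]] <- c(cur_start, cur_last, cur_n)
  out <- do.call(rbind, events)
  if (is.null(out)) return(data.table::data.table(
    start = numeric(0), end = numeric(0), duration_s = numeric(0),
    n_bins = integer(0)))
  res <- data.table::data.table(
    start = t0 + (out[, 1] - 1) * dt, end = t0 + out[, 2] * dt,
    duration_s = (out[, 2] - out[, 1] + 1) * dt, n_bins = as.integer(out[, 3]))
  res[n_bins >= 2L & duration_s >= min_duration_s]
}
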