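#' Lake polygon helpers
#'
#' A lake is represented as a list with a planar polygon ring (metric
#' coordinates, metres) and the geographic coordinates used for solar
#' geometry. The ring is stored open (first vertex not repeated) and must be
#' simple (non-self-intersecting).
#'
#' @param x,y numeric vertex coordinates of the ring, in order.
#' @param lat,lon geographic latitude/longitude of the site in decimal
#'   degrees, used only for day/night classification.
#' @return An object of class `lake` with elements `x`, `y`, `lat`, `lon`.
#' @export
lake_polygon <- function(x, y, lat, lon) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            is.finite(lat), is.finite(lon), abs(lat) <= 90, abs(lon) <= 360)
  # drop an explicitly closed ring's repeated last vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  if (!is_simple_ring(x, y)) stop("lake polygon must be simple (non-self-intersecting)")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "lake")
}

#' Default study lake
#'
#' An elliptical ~25 ha lake (semi-axes 350 m and 230 m) at the latitude and
#' longitude of a north-German lowland lake, matching the scale of the system
#' the simulator emulates.
#'
#' @param n_vertices number of polygon vertices.
#' @return A `lake` object.
#' @export
default_lake <- function(n_vertices = 48) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  lake_polygon(350 * cos(th), 230 * sin(th), lat = 52.9950, lon = 13.5822)
}

# segment-intersection based simplicity check; O(n^2), rings are small
is_simple_ring <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent segments share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      if (ccw(a[1], a[2], b[1], b[2], b[3], b[4]) != ccw(a[3], a[4], b[1], b[2], b[3], b[4]) &&
          ccw(a[1], a[2], a[3], a[4], b[1], b[2]) != ccw(a[1], a[2], a[3], a[4], b[3], b[4]))
        return(FALSE)
    }
  }
  TRUE
}

#' Polygon area (shoelace formula)
#' @param lake a `lake` object.
#' @return area in square metres.
#' @export
lake_area <- function(lake) {
  x <- lake$x; y <- lake$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Lake centroid (vertex mean; adequate for near-convex outlines)
#' @keywords internal
lake_centroid <- function(lake) c(mean(lake$x), mean(lake$y))

#' Test whether points fall inside the lake polygon
#'
#' Even-odd ray casting; points on (or within 1e-7 m of) the boundary count
#' as inside.
#'
#' @param px,py point coordinates (m).
#' @param lake a `lake` object.
#' @return logical vector.
#' @export
in_lake <- function(px, py, lake) {
  px <- as.numeric(px); py <- as.numeric(py)
  # points within the inscribed circle around the centroid are inside for free
  ctr <- lake_centroid(lake)
  rmin <- point_ring_distance(ctr[1], ctr[2], lake$x, lake$y)
  ins <- (px - ctr[1])^2 + (py - ctr[2])^2 < (0.999 * rmin)^2
  rest <- which(!ins)
  if (length(rest) > 0)
    ins[rest] <- in_ring_cpp(px[rest], py[rest], lake$x, lake$y)
  out <- which(!ins)
  if (length(out) > 0)
    ins[out] <- point_ring_distance(px[out], py[out], lake$x, lake$y) < 1e-7
  ins
}

#' Minimum distance from points to the lake shore
#'
#' Euclidean distance from each point to the nearest point on the polygon
#' boundary. Points must lie inside the lake.
#'
#' @param px,py point coordinates (m).
#' @param lake a `lake` object.
#' @param check if `TRUE` (default) error on points outside the polygon.
#' @return numeric vector of distances (m).
#' @export
distance_from_shore <- function(px, py, lake, check = TRUE) {
  stopifnot(length(px) == length(py))
  if (length(px) == 0L) return(numeric(0))
  if (check && !all(in_lake(px, py, lake)))
    stop("distance_from_shore: point(s) outside the lake polygon")
  point_ring_distance(px, py, lake$x, lake$y)
}

# vectorised min distance from points to a closed ring, one segment at a time
point_ring_distance <- function(px, py, rx, ry) {
  n <- length(rx)
  x2 <- c(rx[-1], rx[1]); y2 <- c(ry[-1], ry[1])
  dmin <- rep(Inf, length(px))
  for (s in seq_len(n)) {
    ax <- rx[s]; ay <- ry[s]
    vx <- x2[s] - ax; vy <- y2[s] - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

#' Sample points uniformly inside the lake
#' @keywords internal
sample_in_lake <- function(n, lake) {
  xs <- numeric(0); ys <- numeric(0)
  bx <- range(lake$x); by <- range(lake$y)
  while (length(xs) < n) {
    m <- max(2 * (n - length(xs)), 16L)
    cx <- runif(m, bx[1], bx[2]); cy <- runif(m, by[1], by[2])
    ok <- in_lake(cx, cy, lake)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Read a lake polygon from WKT or GeoJSON
#'
#' Accepts a `POLYGON ((x y, ...))` WKT file/string or a GeoJSON file holding
#' a Polygon geometry (optionally wrapped in a Feature). Only the outer ring
#' is used.
#'
#' @param path path to the file, or a WKT string.
#' @param lat,lon site coordinates for solar geometry (decimal degrees).
#' @return A `lake` object.
#' @export
read_lake <- function(path, lat, lon) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "\n") else path
  if (!grepl("^\\s*\\{", txt)) {
    if (!grepl("POLYGON", txt, ignore.case = TRUE))
      stop("expected a WKT POLYGON or GeoJSON object")
    ring <- sub(".*POLYGON[[:space:]Zz]*\\(\\(([^)]*)\\).*", "\\1", txt)
    pts <- strsplit(trimws(strsplit(ring, ",")[[1]]), "[[:space:]]+")
    xy <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
  } else {
    g <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
    geom <- if (!is.null(g$geometry)) g$geometry else g
    if (!identical(tolower(geom$type), "polygon")) stop("GeoJSON geometry must be a Polygon")
    co <- geom$coordinates
    xy <- if (is.array(co)) co[1, , ] else co[[1]]
    xy <- matrix(as.numeric(xy), ncol = ncol(xy))
  }
  if (anyNA(xy)) stop("could not parse polygon coordinates")
  lake_polygon(xy[, 1], xy[, 2], lat = lat, lon = lon)
}

#' Serialise a lake polygon to WKT
#' @param lake a `lake` object.
#' @return a WKT `POLYGON` string (ring closed).
#' @export
lake_to_wkt <- function(lake) {
  x <- c(lake$x, lake$x[1]); y <- c(lake$y, lake$y[1])
  sprintf("POLYGON ((%s))", paste(sprintf("%.3f %.3f", x, y), collapse = ", "))
}
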