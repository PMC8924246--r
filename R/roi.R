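#' Region of interest (ROI) polygons
#'
#' An ROI is a simple (non-self-intersecting) polygon in nm, typically drawn
#' around a nucleus on the rendered STORM image. All spatial statistics are
#' restricted to an ROI; boundary points count as inside.
#'
#' @param x,y numeric vertex coordinates (nm), in order, without repeating
#'   the first vertex at the end.
#' @return an object of class `roi` with elements `x`, `y` and `area` (nm^2).
#' @examples
#' r <- roi_polygon(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' r$area
#' @export
roi_polygon <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3)
    stopf("an ROI needs at least 3 vertices", class = "nucleopol_geometry_error")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stopf("ROI vertices must be finite", class = "nucleopol_geometry_error")
  a <- polygon_area(x, y)
  if (a <= 0)
    stopf("degenerate ROI polygon (zero area)", class = "nucleopol_geometry_error")
  if (!polygon_is_simple(x, y))
    stopf("ROI polygon is self-intersecting", class = "nucleopol_geometry_error")
  structure(list(x = x, y = y, area = a), class = "roi")
}

#' Rectangular ROI helper
#'
#' @param width,height side lengths in nm.
#' @param origin lower-left corner, `c(x, y)` in nm.
#' @return an `roi` object.
#' @examples
#' roi_rect(10000, 10000)  # a 10 x 10 um nucleus-scale square
#' @export
roi_rect <- function(width, height = width, origin = c(0, 0)) {
  roi_polygon(origin[1] + c(0, width, width, 0),
              origin[2] + c(0, 0, height, height))
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI polygon: %d vertices, area %.4g nm^2 (%.3g um^2)\n",
              length(x$x), x$area, x$area / 1e6))
  invisible(x)
}

# shoelace area, positive regardless of orientation
polygon_area <- function(x, y) {
  j <- c(length(x), seq_len(length(x) - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_is_simple <- function(x, y) {
  m <- length(x)
  seg <- cbind(x, y, x[c(2:m, 1)], y[c(2:m, 1)])
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      # adjacent edges share a vertex; skip
      if (j == i + 1 || (i == 1 && j == m)) next
      if (segments_cross(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test which points fall inside an ROI
#'
#' Boundary points (including vertices) count as inside.
#'
#' @param x,y numeric point coordinates (nm).
#' @param roi an [roi_polygon()] object.
#' @return logical vector.
#' @export
points_in_roi <- function(x, y, roi) {
  stopifnot(inherits(roi, "roi"))
  vx <- roi$x; vy <- roi$y
  m <- length(vx)
  n <- length(x)
  inside <- rep(FALSE, n)
  on_bound <- rep(FALSE, n)
  tol <- 1e-9
  jprev <- m
  for (i in seq_len(m)) {
    x1 <- vx[jprev]; y1 <- vy[jprev]; x2 <- vx[i]; y2 <- vy[i]
    # even-odd crossing
    cross <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross & !is.na(cross))
    # boundary: zero cross product and within segment bbox
    cp <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    ob <- abs(cp) <= tol * max(seglen, 1) &
      x >= pmin(x1, x2) - tol & x <= pmax(x1, x2) + tol &
      y >= pmin(y1, y2) - tol & y <= pmax(y1, y2) + tol
    on_bound <- on_bound | ob
    jprev <- i
  }
  inside | on_bound
}

# uniform points inside an ROI polygon by rejection from the bounding box
runif_in_roi <- function(n, roi) {
  xs <- numeric(0); ys <- numeric(0)
  bx <- range(roi$x); by <- range(roi$y)
  frac <- roi$area / ((bx[2] - bx[1]) * (by[2] - by[1]))
  while (length(xs) < n) {
    m <- max(16, ceiling((n - length(xs)) / max(frac, 0.05)))
    cx <- runif(m, bx[1], bx[2]); cy <- runif(m, by[1], by[2])
    keep <- points_in_roi(cx, cy, roi)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Read an ROI from a vertex CSV or GeoJSON-style file
#'
#' CSV files need columns `x_nm` and `y_nm`; `.json`/`.geojson` files need a
#' polygon `coordinates` array (first ring used, closing vertex dropped).
#'
#' @param path file path.
#' @return an `roi` object.
#' @export
read_roi <- function(path) {
  if (!file.exists(path))
    stopf("ROI file not found: %s", path, class = "nucleopol_io_error")
  if (grepl("\\.(json|geojson)$", path, ignore.case = TRUE)) {
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    coords <- g$coordinates %||% g$geometry$coordinates
    if (is.null(coords))
      stopf("no polygon coordinates in %s", path, class = "nucleopol_io_error")
    ring <- if (is.list(coords)) coords[[1]] else coords[1, , ]
    ring <- matrix(as.numeric(ring), ncol = 2)
    m <- nrow(ring)
    if (m > 3 && all(ring[1, ] == ring[m, ])) ring <- ring[-m, , drop = FALSE]
    roi_polygon(ring[, 1], ring[, 2])
  } else {
    d <- read.csv(path, check.names = FALSE)
    if (!all(c("x_nm", "y_nm") %in% names(d)))
      stopf("ROI CSV needs columns x_nm, y_nm", class = "nucleopol_format_error")
    roi_polygon(d$x_nm, d$y_nm)
  }
}
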