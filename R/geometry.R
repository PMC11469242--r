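#' FAZ boundary polygon
#'
#' Constructs the closed, simple polygon that represents a segmented foveal
#' avascular zone (FAZ) boundary in micrometer coordinates. Coordinates follow
#' the image convention: x grows rightwards, y grows downwards, origin at the
#' raster top-left. The vertex order is normalised so that the shoelace signed
#' area is positive; the closing edge (last vertex back to the first) is
#' implicit.
#'
#' @param x,y numeric vectors of vertex coordinates in micrometers. `x` may
#'   also be a two-column matrix or a `faz_polygon`, in which case `y` is
#'   ignored.
#' @return an object of class `faz_polygon`: a list with numeric fields `x`
#'   and `y`.
#' @examples
#' p <- faz_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(p)
#' @export
faz_polygon <- function(x, y = NULL) {
  if (inherits(x, "faz_polygon")) return(x)
  if (is.matrix(x) && is.null(y)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) parameter_error("x and y must have equal length")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) invalid_polygon_error("a polygon needs at least 3 vertices")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    invalid_polygon_error("polygon vertices must be finite")
  if (shoelace(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  if (abs(shoelace(x, y)) <= 0)
    invalid_polygon_error("polygon has zero area (degenerate vertex set)")
  structure(list(x = x, y = y), class = "faz_polygon")
}

#' @export
print.faz_polygon <- function(x, ...) {
  cat(sprintf("<faz_polygon> %d vertices, area %.1f um^2, perimeter %.1f um\n",
              length(x$x), polygon_area(x), polygon_perimeter(x)))
  invisible(x)
}

# signed shoelace area; positive for the normalised vertex order
shoelace <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area
#'
#' Shoelace area of the FAZ polygon in square micrometers.
#'
#' @param p a [faz_polygon()]
#' @return area in um^2
#' @export
polygon_area <- function(p) {
  p <- faz_polygon(p)
  abs(shoelace(p$x, p$y))
}

#' Polygon perimeter
#'
#' Sum of consecutive vertex distances including the closing edge, in
#' micrometers.
#'
#' @inheritParams polygon_area
#' @return perimeter in um
#' @export
polygon_perimeter <- function(p) {
  p <- faz_polygon(p)
  xn <- c(p$x[-1], p$x[1]); yn <- c(p$y[-1], p$y[1])
  sum(sqrt((xn - p$x)^2 + (yn - p$y)^2))
}

#' Polygon centroid
#'
#' Area centroid (first region moments / area) of the polygon interior.
#'
#' @inheritParams polygon_area
#' @return numeric length-2 vector `c(x, y)` in um
#' @export
polygon_centroid <- function(p) {
  p <- faz_polygon(p)
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Convex hull of a polygon
#'
#' @inheritParams polygon_area
#' @return a `faz_polygon` holding the hull vertices
#' @export
convex_hull <- function(p) {
  p <- faz_polygon(p)
  idx <- grDevices::chull(p$x, p$y)
  if (length(idx) < 3)
    invalid_polygon_error("vertex set is collinear; hull is degenerate")
  faz_polygon(p$x[idx], p$y[idx])
}

#' Second-moment equivalent ellipse
#'
#' The ellipse whose second central region moments match those of the polygon
#' interior (the usual particle-analysis definition that underlies the "major
#' axis" of roundness). Axis lengths are *full* axes, not semi-axes.
#'
#' Region moments are evaluated in closed form over the polygon with Green's
#' theorem; the semi-axes are `2*sqrt(lambda)` for the eigenvalues `lambda` of
#' the normalised covariance of the interior, which reproduces the axes of an
#' exact ellipse.
#'
#' @inheritParams polygon_area
#' @return a list with `major_axis_um`, `minor_axis_um`, `theta_rad`
#'   (orientation of the major axis, in `[0, pi)`).
#' @export
equivalent_ellipse <- function(p) {
  p <- faz_polygon(p)
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) <= 0) invalid_polygon_error("zero-area polygon")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # second moments about the origin (integrals of x^2, y^2, xy over the region)
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # normalised central covariance of the interior
  mxx <- sxx / a - cx^2
  myy <- syy / a - cy^2
  mxy <- sxy / a - cx * cy
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  semi <- 2 * sqrt(lam)
  v <- ev$vectors[, 1]
  theta <- atan2(v[2], v[1]) %% pi
  list(major_axis_um = 2 * semi[1], minor_axis_um = 2 * semi[2],
       theta_rad = theta)
}

#' Convert a binary mask to a FAZ polygon
#'
#' Extracts the outer boundary of the largest foreground component as a
#' sub-pixel iso-contour at level 0.5 (so staircase pixel edges do not inflate
#' the perimeter), fills interior holes by construction (only the outer contour
#' is kept), and scales vertices to micrometers. Pixel centers sit at
#' `(col - 0.5, row - 0.5)` pixel units from the top-left origin.
#'
#' @param mask a logical or 0/1 numeric matrix, `mask[row, col]`, top-left
#'   origin; or a `faz_mask` from [read_faz_mask()].
#' @param pixel_size_um micrometers per pixel (isotropic). Ignored when `mask`
#'   is a `faz_mask` carrying its own scale.
#' @param min_component_px smallest foreground component (in pixels,
#'   approximated by the iso-contour area) considered a FAZ candidate.
#' @param smooth_window half-width (in vertices) of a circular moving-average
#'   applied to the extracted contour. On binary rasters the 0.5 iso-contour
#'   still chamfers in half-pixel steps; a short smoothing window removes the
#'   residual staircase so perimeter-based metrics match a vector boundary of
#'   the same shape. `0` disables smoothing.
#' @return a [faz_polygon()] in micrometer coordinates
#' @export
mask_to_polygon <- function(mask, pixel_size_um = default_pixel_size_um(),
                            min_component_px = 16, smooth_window = 2L) {
  if (inherits(mask, "faz_mask")) {
    pixel_size_um <- mask$pixel_size_um
    mask <- mask$pixels
  }
  if (!is.matrix(mask)) parameter_error("mask must be a matrix")
  if (pixel_size_um <= 0) parameter_error("pixel_size_um must be positive")
  m <- (mask != 0) * 1
  if (!any(m == 1)) no_foreground_error("mask has no foreground pixels")
  # pad with background so components touching the border close properly
  nr <- nrow(m); nc <- ncol(m)
  mp <- matrix(0, nr + 2, nc + 2)
  mp[2:(nr + 1), 2:(nc + 1)] <- m
  # grid of pixel-center coordinates in pixel units (x = column, y = row)
  xs <- (0:(nc + 1)) - 0.5
  ys <- (0:(nr + 1)) - 0.5
  cl <- grDevices::contourLines(x = ys, y = xs, z = mp, levels = 0.5)
  if (!length(cl)) no_foreground_error("no iso-contour found at level 0.5")
  # contourLines' first coordinate runs over rows here; swap to (x, y) image axes
  areas_px <- vapply(cl, function(ct) abs(shoelace(ct$y, ct$x)), numeric(1))
  best <- which.max(areas_px)
  if (areas_px[best] < min_component_px)
    no_foreground_error(sprintf(
      "largest foreground component (~%.1f px) is below min_component_px = %d",
      areas_px[best], min_component_px))
  # warn about ignored separate components (contours not nested in the winner)
  if (length(cl) > 1) {
    outer <- cbind(cl[[best]]$y, cl[[best]]$x)
    outer <- rbind(outer, outer[1, ])
    for (i in seq_along(cl)[-best]) {
      pt <- cbind(cl[[i]]$y[1], cl[[i]]$x[1])
      if (!mgcv::in.out(outer, pt))
        warning(sprintf(
          "ignoring secondary foreground component (~%.1f px); largest kept",
          areas_px[i]), call. = FALSE)
    }
  }
  vx <- cl[[best]]$y; vy <- cl[[best]]$x
  if (vx[1] == vx[length(vx)] && vy[1] == vy[length(vy)]) {
    vx <- vx[-length(vx)]; vy <- vy[-length(vy)]
  }
  if (smooth_window > 0 && length(vx) > 4 * smooth_window + 4) {
    vx <- as.numeric(circular_smooth(vx, smooth_window))
    vy <- as.numeric(circular_smooth(vy, smooth_window))
  }
  faz_polygon(vx * pixel_size_um, vy * pixel_size_um)
}

#' Uniform arc-length boundary resampling
#'
#' Samples `n_points` positions at uniform arc-length spacing along a closed
#' boundary (FAZ polygon or ellipse). The traversal starts at the boundary
#' vertex whose direction from the centroid is nearest to angle zero (the
#' positive x axis), which makes the sampling deterministic.
#'
#' @param shape a [faz_polygon()] or [faz_ellipse()]
#' @param n_points number of samples, at least 8
#' @return a `faz_boundary_cloud`: an `n_points x 2` matrix with a `source`
#'   attribute (`"faz"` or `"ellipse"`)
#' @export
resample_boundary <- function(shape, n_points = 512) {
  if (n_points < 8) parameter_error("n_points must be at least 8")
  n_points <- as.integer(n_points)
  if (inherits(shape, "faz_ellipse")) {
    dense <- ellipse_points(shape, 4096L)
    src <- "ellipse"
    ctr <- c(shape$cx_um, shape$cy_um)
    x <- dense[, 1]; y <- dense[, 2]
  } else {
    p <- faz_polygon(shape)
    src <- "faz"
    ctr <- polygon_centroid(p)
    x <- p$x; y <- p$y
  }
  # rotate vertex order to start nearest angle 0 from the centroid
  ang <- atan2(y - ctr[2], x - ctr[1])
  s0 <- which.min(abs(ang))
  if (s0 > 1) {
    idx <- c(s0:length(x), 1:(s0 - 1))
    x <- x[idx]; y <- y[idx]
  }
  x <- c(x, x[1]); y <- c(y, y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) invalid_polygon_error("boundary has zero length")
  s <- L * (0:(n_points - 1)) / n_points
  px <- stats::approx(cum, x, xout = s, ties = "ordered")$y
  py <- stats::approx(cum, y, xout = s, ties = "ordered")$y
  structure(cbind(x = px, y = py), class = "faz_boundary_cloud", source = src)
}

# Euclidean distance from each point (rows of pts) to a closed polyline.
# Used for containment penalties and post-fit verification.
points_to_polygon_dist <- function(pts, p) {
  p <- faz_polygon(p)
  ax <- p$x; ay <- p$y
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  m <- nrow(pts)
  # t = clamp(((P-A).E)/|E|^2): m x k matrices
  dx <- outer(pts[, 1], ax, "-")
  dy <- outer(pts[, 2], ay, "-")
  tt <- (sweep(dx, 2, ex, "*") + sweep(dy, 2, ey, "*"))
  tt <- sweep(tt, 2, pmax(el2, .Machine$double.eps), "/")
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  qx <- dx - sweep(tt, 2, ex, "*")
  qy <- dy - sweep(tt, 2, ey, "*")
  d2 <- qx^2 + qy^2
  sqrt(do.call(pmin, lapply(seq_len(ncol(d2)), function(j) d2[, j])))
}

# logical: which points lie inside the (closed) polygon
points_in_polygon <- function(pts, p) {
  p <- faz_polygon(p)
  bnd <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
  mgcv::in.out(bnd, pts)
}
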