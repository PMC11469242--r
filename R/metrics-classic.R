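#' Classic FAZ shape descriptors
#'
#' The six established descriptors of FAZ morphology, evaluated on the
#' micrometer-scaled polygon:
#'
#' * area (um^2),
#' * circularity `4*pi*area / perimeter^2`,
#' * acircularity `perimeter / perimeter of the equal-area circle`,
#' * roundness `4*area / (pi * major_axis^2)` with the major axis of the
#'   second-moment equivalent ellipse,
#' * solidity `area / convex hull area`,
#' * convexity: ratio of the convex hull perimeter to the FAZ perimeter.
#'
#' Convexity conventions: the `"standard"` convention (hull perimeter / FAZ
#' perimeter, at most 1, decreasing with irregularity) is the default; the
#' `"ratio_faz_over_hull"` switch reports the reciprocal for pipelines that
#' define convexity the other way around. The choice is recorded in the
#' output of [compute_all()].
#'
#' @name classic_metrics
NULL

#' @rdname classic_metrics
#' @inheritParams polygon_area
#' @return `circularity()`: dimensionless value in `(0, 1]` up to
#'   discretization error
#' @export
circularity <- function(p) {
  a <- polygon_area(p)
  per <- polygon_perimeter(p)
  if (per <= 0) invalid_polygon_error("zero perimeter")
  4 * pi * a / per^2
}

#' @rdname classic_metrics
#' @export
acircularity <- function(p) {
  a <- polygon_area(p)
  if (a <= 0) invalid_polygon_error("zero area")
  polygon_perimeter(p) / (2 * sqrt(pi * a))
}

#' @rdname classic_metrics
#' @param ee optionally, a precomputed [equivalent_ellipse()] of `p`
#' @export
roundness <- function(p, ee = equivalent_ellipse(p)) {
  if (!is.finite(ee$major_axis_um) || ee$major_axis_um <= 0)
    invalid_polygon_error("degenerate equivalent ellipse")
  4 * polygon_area(p) / (pi * ee$major_axis_um^2)
}

#' @rdname classic_metrics
#' @export
solidity <- function(p) {
  h <- convex_hull(p)
  ha <- polygon_area(h)
  if (ha <= 0) invalid_polygon_error("degenerate hull")
  polygon_area(p) / ha
}

#' @rdname classic_metrics
#' @param convention `"standard"` (hull perimeter over FAZ perimeter, <= 1) or
#'   `"ratio_faz_over_hull"` (the reciprocal)
#' @export
convexity <- function(p, convention = c("standard", "ratio_faz_over_hull")) {
  convention <- match.arg(convention)
  h <- convex_hull(p)
  hp <- polygon_perimeter(h)
  pp <- polygon_perimeter(p)
  if (hp <= 0 || pp <= 0) invalid_polygon_error("degenerate hull")
  if (convention == "standard") hp / pp else pp / hp
}

#' @rdname classic_metrics
#' @param convexity_convention passed to [convexity()]
#' @return `classic_metrics()`: a one-row data.frame with columns `area_um2`,
#'   `perimeter_um`, `circularity`, `acircularity`, `roundness`, `solidity`,
#'   `convexity`
#' @export
classic_metrics <- function(p, convexity_convention = "standard") {
  p <- faz_polygon(p)
  data.frame(
    area_um2     = polygon_area(p),
    perimeter_um = polygon_perimeter(p),
    circularity  = circularity(p),
    acircularity = acircularity(p),
    roundness    = roundness(p),
    solidity     = solidity(p),
    convexity    = convexity(p, convexity_convention)
  )
}
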