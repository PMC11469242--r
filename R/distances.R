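#' Boundary point-cloud distances
#'
#' Hausdorff and Chamfer distances between two boundary point clouds, in
#' physical units (um for the Hausdorff distance, um^2 for the Chamfer
#' distance which averages *squared* nearest-point distances).
#'
#' @param A,B numeric matrices with two columns (x, y), e.g. from
#'   [resample_boundary()]
#' @name shape_distances
NULL

as_cloud <- function(A) {
  if (inherits(A, "faz_boundary_cloud")) return(unclass(A))
  A <- as.matrix(A)
  if (!is.numeric(A) || ncol(A) != 2 || nrow(A) < 1)
    parameter_error("a boundary cloud must be a non-empty 2-column matrix")
  A
}

# m x n matrix of squared pairwise distances
pairwise_sq <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
}

# for each row of A, squared distance to its nearest neighbour in B
nn_sq <- function(A, B) {
  d2 <- pairwise_sq(A, B)
  pmax(do.call(pmin, lapply(seq_len(ncol(d2)), function(j) d2[, j])), 0)
}

#' @rdname shape_distances
#' @return `directed_hausdorff()`: `max over a in A of min over b in B` of the
#'   Euclidean distance, in um
#' @export
directed_hausdorff <- function(A, B) {
  A <- as_cloud(A); B <- as_cloud(B)
  sqrt(max(nn_sq(A, B)))
}

#' @rdname shape_distances
#' @return `hausdorff()`: the symmetric Hausdorff distance, the greater of the
#'   two directed distances, in um
#' @export
hausdorff <- function(A, B) {
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' @rdname shape_distances
#' @param reduction how the two directed mean-squared distances are combined:
#'   `"mean_of_directions"` (default; symmetric, stays on the um^2 scale of a
#'   single direction), `"sum_of_directions"`, or `"forward_only"` (A to B)
#' @return `chamfer()`: averaged squared nearest-point distance in um^2
#' @export
chamfer <- function(A, B, reduction = c("mean_of_directions",
                                        "sum_of_directions", "forward_only")) {
  reduction <- match.arg(reduction)
  A <- as_cloud(A); B <- as_cloud(B)
  fwd <- mean(nn_sq(A, B))
  if (reduction == "forward_only") return(fwd)
  bwd <- mean(nn_sq(B, A))
  if (reduction == "sum_of_directions") fwd + bwd else (fwd + bwd) / 2
}

#' FAZ vs inner-ellipse boundary distances
#'
#' Resamples the FAZ polygon boundary and the fitted inner-ellipse boundary to
#' `n_points` each at uniform arc-length spacing and returns their Hausdorff
#' and Chamfer distances.
#'
#' @param p the [faz_polygon()]
#' @param fit a `faz_ie_fit` from [fit_inner_ellipse()]
#' @param n_points samples per boundary, at least 64 (default 512)
#' @param cd_reduction passed to [chamfer()]
#' @return a list with `hd_um`, `cd_um2`, `n_faz_points`, `n_ellipse_points`
#' @export
faz_ie_distances <- function(p, fit, n_points = 512,
                             cd_reduction = "mean_of_directions") {
  if (n_points < 64) parameter_error("n_points must be at least 64")
  if (!inherits(fit, "faz_ie_fit"))
    parameter_error("fit must come from fit_inner_ellipse()")
  A <- resample_boundary(faz_polygon(p), n_points)
  B <- resample_boundary(fit$ellipse, n_points)
  list(hd_um = hausdorff(A, B),
       cd_um2 = chamfer(A, B, cd_reduction),
       n_faz_points = nrow(A), n_ellipse_points = nrow(B))
}
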