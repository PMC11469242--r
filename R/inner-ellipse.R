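#' Ellipse object
#'
#' Center, semi-axes and rotation of an ellipse in micrometer image
#' coordinates. The constructor normalises so that `a_um >= b_um` and
#' `theta_rad` (rotation of the major axis) lies in `[0, pi)`.
#'
#' @param cx_um,cy_um center
#' @param a_um,b_um semi-axes (um), both positive
#' @param theta_rad rotation of the `a_um` axis
#' @return an object of class `faz_ellipse`
#' @export
faz_ellipse <- function(cx_um, cy_um, a_um, b_um, theta_rad = 0) {
  if (!all(is.finite(c(cx_um, cy_um, a_um, b_um, theta_rad))))
    parameter_error("ellipse parameters must be finite")
  if (a_um <= 0 || b_um <= 0) parameter_error("semi-axes must be positive")
  if (b_um > a_um) {
    tmp <- a_um; a_um <- b_um; b_um <- tmp
    theta_rad <- theta_rad + pi / 2
  }
  structure(list(cx_um = cx_um, cy_um = cy_um, a_um = a_um, b_um = b_um,
                 theta_rad = theta_rad %% pi),
            class = "faz_ellipse")
}

#' @export
print.faz_ellipse <- function(x, ...) {
  cat(sprintf(
    "<faz_ellipse> center (%.1f, %.1f) um, semi-axes %.1f x %.1f um, theta %.3f rad\n",
    x$cx_um, x$cy_um, x$a_um, x$b_um, x$theta_rad))
  invisible(x)
}

#' Ellipse area
#'
#' @param e a [faz_ellipse()]
#' @return `pi * a * b` in um^2
#' @export
ellipse_area <- function(e) pi * e$a_um * e$b_um

# n boundary points at uniform parameter spacing
ellipse_points <- function(e, n) {
  t <- 2 * pi * (0:(n - 1)) / n
  ct <- cos(e$theta_rad); st <- sin(e$theta_rad)
  u <- e$a_um * cos(t); v <- e$b_um * sin(t)
  cbind(e$cx_um + u * ct - v * st, e$cy_um + u * st + v * ct)
}

# run expr with a private, restored RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit the largest inscribed (inner) ellipse of a FAZ polygon
#'
#' Approximates the largest ellipse contained in the FAZ polygon — the proxy
#' for the pre-dropout, healthy FAZ — by penalised constrained optimisation.
#' The ellipse is parameterised as `(cx, cy, log a, log b, theta)` and the
#' area `pi*a*b` is maximised subject to (i) every one of `n_boundary_samples`
#' ellipse-boundary points lying inside the polygon within `tol_um`, and
#' (ii) the polygon centroid lying strictly inside the ellipse. Optimisation
#' is Nelder-Mead from the moment-equivalent ellipse shrunk by one half, plus
#' `n_restarts - 1` seeded jittered starts; after each solve the candidate is
#' shrunk radially (if needed) until the containment violation, measured on
#' 2048 boundary samples, is at most `tol_um`. Among candidates whose area
#' ties within 1e-6 relative, the one whose center is closest to the polygon
#' centroid wins, which makes the fit deterministic for a given seed.
#'
#' @param p a [faz_polygon()]
#' @param n_boundary_samples ellipse-boundary points used for the containment
#'   penalty during optimisation (default 256)
#' @param tol_um maximum tolerated outward excursion of the fitted ellipse
#'   boundary, in micrometers (default 0.5)
#' @param n_restarts number of multi-starts (default 8)
#' @param seed integer seed for the jittered restarts
#' @param centroid_fallback `"error"` (default): raise an error when the
#'   polygon centroid falls outside the polygon, violating the geometric
#'   assumption behind the fit; `"pole_of_inaccessibility"`: fall back to the
#'   interior point most distant from the boundary, with a warning.
#' @return a list of class `faz_ie_fit`: `ellipse` ([faz_ellipse()]),
#'   `containment_violation_um`, `n_restarts_used`, `converged`, and the
#'   anchor point `center_ref` used for the inside-ellipse constraint.
#' @export
fit_inner_ellipse <- function(p, n_boundary_samples = 256, tol_um = 0.5,
                              n_restarts = 8, seed = 1L,
                              centroid_fallback = c("error",
                                                    "pole_of_inaccessibility")) {
  p <- faz_polygon(p)
  centroid_fallback <- match.arg(centroid_fallback)
  ctr <- polygon_centroid(p)
  if (!points_in_polygon(rbind(ctr), p)) {
    if (centroid_fallback == "error")
      centroid_outside_error(
        "polygon centroid lies outside the polygon; the inner-ellipse model assumes an interior geometric center")
    ctr <- pole_of_inaccessibility(p)
    warning("polygon centroid outside polygon; using pole of inaccessibility",
            call. = FALSE)
  }

  A <- polygon_area(p)
  ee <- equivalent_ellipse(p)
  scale0 <- sqrt(A / pi)          # radius of the equal-area circle
  a0 <- ee$major_axis_um / 4      # equivalent semi-axes shrunk by 0.5
  b0 <- ee$minor_axis_um / 4
  # dimensionless parameters: center offset in units of scale0, log semi-axes
  # relative to scale0, rotation in radians -- keeps the simplex well scaled
  start0 <- c(0, 0, log(a0 / scale0), log(b0 / scale0), ee$theta_rad)

  par_to_ellipse <- function(par) {
    list(cx_um = ctr[1] + par[1] * scale0, cy_um = ctr[2] + par[2] * scale0,
         a_um = exp(par[3]) * scale0, b_um = exp(par[4]) * scale0,
         theta_rad = par[5])
  }
  # precomputed polygon geometry for the hot penalty path
  bnd <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
  eax <- p$x; eay <- p$y
  eex <- c(eax[-1], eax[1]) - eax; eey <- c(eay[-1], eay[1]) - eay
  eel2 <- pmax(eex^2 + eey^2, .Machine$double.eps)
  nk <- length(eax)
  dist_out <- function(pts) {   # distance of points to the boundary polyline
    m <- nrow(pts)
    # k x m layout: length-k edge vectors recycle down columns without sweep()
    dx <- matrix(pts[, 1], nk, m, byrow = TRUE) - eax
    dy <- matrix(pts[, 2], nk, m, byrow = TRUE) - eay
    tt <- (dx * eex + dy * eey) / eel2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- dx - tt * eex; qy <- dy - tt * eey
    d2 <- qx^2 + qy^2
    sqrt(vapply(seq_len(m), function(j) min(d2[, j]), numeric(1)))
  }
  obj <- function(par) {
    e <- par_to_ellipse(par)
    if (!is.finite(e$a_um) || !is.finite(e$b_um) ||
        e$a_um > 4 * scale0 || e$b_um > 4 * scale0) return(1e6)
    ep <- ellipse_points(e, n_boundary_samples)
    inside <- mgcv::in.out(bnd, ep)
    pen <- 0
    if (!all(inside)) {
      out <- which(!inside)
      # far-infeasible iterates do not need exact distances for every point
      if (length(out) > 64) {
        sub <- out[seq(1, length(out), length.out = 64)]
        d <- dist_out(ep[sub, , drop = FALSE]) *
          sqrt(length(out) / 64)          # keep the penalty mass comparable
      } else {
        d <- dist_out(ep[out, , drop = FALSE])
      }
      pen <- pen + sum((d / tol_um)^2)
    }
    # centroid strictly inside the ellipse: squared elliptic radius < 1
    ct <- cos(e$theta_rad); st <- sin(e$theta_rad)
    dx <- ctr[1] - e$cx_um; dy <- ctr[2] - e$cy_um
    g <- ((dx * ct + dy * st) / e$a_um)^2 + ((-dx * st + dy * ct) / e$b_um)^2
    if (g >= 1) pen <- pen + 1e8 * (g - 1 + 1e-3)^2
    -(e$a_um * e$b_um) / scale0^2 + 10 * pen
  }
  solve_from <- function(st, maxit, reltol) {
    tryCatch(
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
  }

  cands <- with_local_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      st <- start0
      if (i > 1) {
        st[1:2] <- st[1:2] + stats::rnorm(2, 0, 0.15)
        st[3:4] <- st[3:4] + stats::rnorm(2, 0, 0.3)
        st[5] <- st[5] + stats::runif(1, -pi / 4, pi / 4)
      }
      solve_from(st, maxit = 400, reltol = 1e-8)
    })
  })
  vals <- vapply(cands, function(f) if (is.null(f)) Inf else f$value,
                 numeric(1))
  if (all(!is.finite(vals)))
    fit_failed_error("inner-ellipse optimisation failed on all restarts")
  # polish: re-launch Nelder-Mead from the incumbent until it stops improving
  # (a fresh simplex routinely escapes premature stalls), then basin-hop with
  # small seeded perturbations -- near-circular shapes with noisy boundaries
  # otherwise strand the fit in a wrong-orientation basin
  inc <- cands[[which.min(vals)]]
  for (round in 1:5) {
    pol <- solve_from(inc$par, maxit = 800, reltol = 1e-11)
    if (is.null(pol)) break
    improved <- pol$value < inc$value - 1e-9
    inc <- pol
    if (!improved) break
  }
  inc <- with_local_seed(seed + 1L, {
    for (hop in 1:4) {
      st <- inc$par + c(stats::rnorm(2, 0, 0.05), stats::rnorm(2, 0, 0.1),
                        stats::runif(1, -pi / 3, pi / 3))
      pol <- solve_from(st, maxit = 400, reltol = 1e-10)
      if (!is.null(pol) && pol$value < inc$value - 1e-9) {
        pol2 <- solve_from(pol$par, maxit = 800, reltol = 1e-11)
        if (!is.null(pol2) && pol2$value < pol$value) pol <- pol2
        inc <- pol
      }
    }
    inc
  })
  cands <- c(cands, list(inc))

  best <- NULL
  for (fit in cands) {
    if (is.null(fit)) next
    ep <- par_to_ellipse(fit$par)
    e <- faz_ellipse(ep$cx_um, ep$cy_um, ep$a_um, ep$b_um, ep$theta_rad)
    e <- shrink_to_contain(e, p, tol_um)
    if (is.null(e)) next
    viol <- containment_violation(e, p)
    if (viol > tol_um) next
    area <- ellipse_area(e)
    d_ctr <- sqrt((e$cx_um - ctr[1])^2 + (e$cy_um - ctr[2])^2)
    if (is.null(best) || area > best$area * (1 + 1e-6) ||
        (area > best$area * (1 - 1e-6) && d_ctr < best$d_ctr)) {
      best <- list(e = e, area = area, d_ctr = d_ctr, viol = viol)
    }
  }
  if (is.null(best))
    fit_failed_error("inner-ellipse optimisation failed on all restarts")

  structure(list(ellipse = best$e,
                 containment_violation_um = best$viol,
                 n_restarts_used = n_restarts,
                 converged = TRUE,
                 center_ref = ctr),
            class = "faz_ie_fit")
}

# max outward excursion of the ellipse boundary, on 2048 samples
containment_violation <- function(e, p, n = 2048L) {
  ep <- ellipse_points(e, n)
  inside <- points_in_polygon(ep, p)
  if (all(inside)) return(0)
  max(points_to_polygon_dist(ep[!inside, , drop = FALSE], p))
}

# radially shrink both axes about the center until the violation is <= tol
shrink_to_contain <- function(e, p, tol_um, n = 2048L) {
  if (containment_violation(e, p, n) <= tol_um) return(e)
  lo <- 0.2; hi <- 1
  at <- function(s) faz_ellipse(e$cx_um, e$cy_um, s * e$a_um, s * e$b_um,
                                e$theta_rad)
  if (containment_violation(at(lo), p, n) > tol_um) return(NULL)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (containment_violation(at(mid), p, n) <= tol_um) lo <- mid else hi <- mid
  }
  at(lo)
}

# interior point maximising distance to the boundary (coarse grid refinement)
pole_of_inaccessibility <- function(p, n_grid = 64L) {
  p <- faz_polygon(p)
  gx <- seq(min(p$x), max(p$x), length.out = n_grid)
  gy <- seq(min(p$y), max(p$y), length.out = n_grid)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- points_in_polygon(pts, p)
  pts <- pts[inside, , drop = FALSE]
  if (!nrow(pts)) invalid_polygon_error("no interior grid point found")
  d <- points_to_polygon_dist(pts, p)
  as.numeric(pts[which.max(d), ])
}

#' Absolute inner-ellipse area difference (diff iE)
#'
#' The absolute difference between the FAZ polygon area and the area of its
#' fitted inner ellipse, in um^2. Because the fitted ellipse is contained in
#' the polygon this equals the area of the capillary-dropout excess.
#'
#' @param p the [faz_polygon()] the fit was produced from
#' @param fit a `faz_ie_fit` from [fit_inner_ellipse()]
#' @return nonnegative area difference in um^2
#' @export
diff_inner_ellipse <- function(p, fit) {
  if (!inherits(fit, "faz_ie_fit"))
    parameter_error("fit must come from fit_inner_ellipse()")
  abs(polygon_area(p) - ellipse_area(fit$ellipse))
}
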