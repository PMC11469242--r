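#' Synthetic FAZ shape with capillary-dropout protrusions
#'
#' Generates a FAZ-like closed shape: a base ellipse (the "healthy" FAZ)
#' plus `n_notches` smooth outward radial bumps that emulate local capillary
#' dropout, plus optional outward boundary noise. Dropout only ever enlarges
#' the avascular zone, so the generated polygon always contains the base
#' ellipse, and the true largest inscribed ellipse is at least the base
#' ellipse.
#'
#' Each bump follows a raised-cosine radial profile
#' `depth * (1 + cos(pi * d / w)) / 2` for angular distance `d <= w` from the
#' bump center, which keeps the boundary smooth and makes the planned excess
#' area available by quadrature; it is returned in `truth` for bookkeeping.
#' Bump centers are placed by seeded jitter around equally spaced angles so
#' that bumps never overlap.
#'
#' @param base_a_um,base_b_um semi-axes of the base ellipse (defaults 350 and
#'   280 um give a typical healthy FAZ area of about 0.31 mm^2)
#' @param base_theta_rad rotation of the base ellipse
#' @param n_notches number of dropout protrusions (0 for a healthy shape)
#' @param notch_depth_um radial depth of each protrusion (scalar or one per
#'   notch)
#' @param notch_width_rad angular half-width of each protrusion
#' @param boundary_noise_um scale of smooth outward boundary noise (0 = none)
#' @param seed integer seed; the same spec and seed reproduce the polygon
#'   bitwise
#' @param n_vertices polygon resolution (uniform in angle)
#' @param center_um shape center in image coordinates (default the center of
#'   the 6 x 6 mm grid)
#' @param raster if `TRUE`, also rasterise the shape into a binary mask at
#'   `pixel_size_um` on a `grid_px` square grid
#' @param pixel_size_um,grid_px raster geometry (defaults 6000/1024 um/px,
#'   1024 px)
#' @return a list with `polygon` ([faz_polygon()]), `mask` (a `faz_mask` or
#'   `NULL`), and `truth` (base ellipse as [faz_ellipse()] and
#'   `planned_excess_area_um2`)
#' @export
generate_shape <- function(base_a_um = 350, base_b_um = 280,
                           base_theta_rad = 0, n_notches = 0,
                           notch_depth_um = 0, notch_width_rad = 0.35,
                           boundary_noise_um = 0, seed = 1L,
                           n_vertices = 360L, center_um = c(3000, 3000),
                           raster = FALSE,
                           pixel_size_um = default_pixel_size_um(),
                           grid_px = 1024L) {
  if (base_a_um <= 0 || base_b_um <= 0) spec_error("base semi-axes must be positive")
  if (n_notches < 0 || any(notch_depth_um < 0) || boundary_noise_um < 0)
    spec_error("notch count/depth and noise must be nonnegative")
  if (n_notches > 0 && n_notches * 2 * notch_width_rad > 2 * pi)
    spec_error("notches cover more than the full circle; reduce count or width")
  depth <- rep_len(notch_depth_um, max(n_notches, 1))

  th <- 2 * pi * (0:(n_vertices - 1)) / n_vertices
  r_base <- ellipse_polar_radius(base_a_um, base_b_um, base_theta_rad, th)

  bump_total <- rep(0, n_vertices)
  notch_angles <- numeric(0)
  noise <- rep(0, n_vertices)
  with_local_seed(seed, {
    if (n_notches > 0) {
      anchors <- 2 * pi * (0:(n_notches - 1)) / n_notches +
        stats::runif(1, 0, 2 * pi)
      slack <- pi / n_notches - notch_width_rad   # >= 0 by the coverage check
      notch_angles <- (anchors +
        stats::runif(n_notches, -slack, slack)) %% (2 * pi)
      for (k in seq_len(n_notches)) {
        d <- angular_distance(th, notch_angles[k])
        in_bump <- d <= notch_width_rad
        bump_total[in_bump] <- bump_total[in_bump] +
          depth[k] * (1 + cos(pi * d[in_bump] / notch_width_rad)) / 2
      }
    }
    if (boundary_noise_um > 0) {
      raw <- stats::rnorm(n_vertices)
      w <- max(3L, round(n_vertices / 24))
      sm <- circular_smooth(raw, w)
      noise <- boundary_noise_um * abs(sm) / stats::sd(sm)
    }
  })

  r <- r_base + bump_total + noise
  poly <- faz_polygon(center_um[1] + r * cos(th), center_um[2] + r * sin(th))

  # planned excess area of the bumps alone, by fine quadrature of the
  # polar area integral 1/2 * ((r_base + bump)^2 - r_base^2) dtheta
  excess <- 0
  if (n_notches > 0) {
    tq <- 2 * pi * (0:16383) / 16384
    rb <- ellipse_polar_radius(base_a_um, base_b_um, base_theta_rad, tq)
    bq <- rep(0, length(tq))
    for (k in seq_len(n_notches)) {
      d <- angular_distance(tq, notch_angles[k])
      in_bump <- d <= notch_width_rad
      bq[in_bump] <- bq[in_bump] +
        depth[k] * (1 + cos(pi * d[in_bump] / notch_width_rad)) / 2
    }
    excess <- sum(((rb + bq)^2 - rb^2) / 2) * (2 * pi / 16384)
  }

  mask <- NULL
  if (raster) {
    mask <- rasterize_polar(r, th, center_um, pixel_size_um, grid_px)
  }
  list(polygon = poly, mask = mask,
       truth = list(base_ellipse = faz_ellipse(center_um[1], center_um[2],
                                               base_a_um, base_b_um,
                                               base_theta_rad),
                    planned_excess_area_um2 = excess,
                    notch_angles_rad = notch_angles))
}

# polar radius of a centered, rotated ellipse
ellipse_polar_radius <- function(a, b, theta0, th) {
  a * b / sqrt((b * cos(th - theta0))^2 + (a * sin(th - theta0))^2)
}

angular_distance <- function(th, th0) {
  d <- abs((th - th0) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

circular_smooth <- function(x, w) {
  n <- length(x)
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  stats::filter(c(x[(n - w + 1):n], x, x[1:w]), k, sides = 2)[(w + 1):(w + n)]
}

# star-convex rasterisation: pixel is foreground iff its radius from the
# shape center is at most the (angle-interpolated) boundary radius
rasterize_polar <- function(r, th, center_um, pixel_size_um, grid_px) {
  cx <- (1:grid_px - 0.5) * pixel_size_um
  px <- outer(rep(1, grid_px), cx) - center_um[1]   # x varies over columns
  py <- outer(cx, rep(1, grid_px)) - center_um[2]   # y varies over rows
  ang <- atan2(py, px) %% (2 * pi)
  rad <- sqrt(px^2 + py^2)
  rb <- stats::approx(c(th, 2 * pi), c(r, r[1]), xout = ang,
                      ties = "ordered")$y
  structure(list(pixels = matrix((rad <= rb) * 1L, grid_px, grid_px),
                 pixel_size_um = pixel_size_um),
            class = "faz_mask")
}

#' Synthetic cohort with zero-inflated Gensini severity
#'
#' Simulates a study cohort: per patient a Gensini score (GS) drawn from a
#' zero-inflated Poisson (structural zeros are the CAD-free patients), age,
#' sex and diabetes covariates, and per eye a FAZ shape whose dropout
#' irregularity grows monotonically with the GS. The left eye (OS) carries
#' the full effect; the right eye (OD) a damped one, mirroring the stronger
#' left-sided retinal involvement expected from the carotid anatomy.
#'
#' @param n_patients number of patients (two eyes each)
#' @param p_zero probability of a structural zero GS (default 0.34, the
#'   CAD-free fraction of a typical angiography cohort)
#' @param gs_mean Poisson mean of the diseased GS distribution
#' @param effect_map function mapping a GS value to a list with `n_notches`
#'   and `notch_depth_um`; must be monotone non-decreasing in GS
#' @param laterality_multiplier damping of the dropout depth in the right
#'   eye (default 0.6; 1 = no asymmetry)
#' @param boundary_noise_um outward boundary noise of every eye
#' @param seed integer seed
#' @return a list with `cohort` (a data.frame: patient_id, eye, age_y, sex,
#'   diabetes, gs, ternary, binary, n_notches, notch_depth_um, shape_seed)
#'   and `shapes` (a list of per-eye [generate_shape()] results, in row order)
#' @export
generate_cohort <- function(n_patients = 212, p_zero = 0.34, gs_mean = 35,
                            effect_map = default_effect_map,
                            laterality_multiplier = 0.6,
                            boundary_noise_um = 6, seed = 1L) {
  if (n_patients < 4) spec_error("need at least 4 patients")
  if (p_zero < 0 || p_zero > 1) spec_error("p_zero must be in [0, 1]")
  with_local_seed(seed, {
    zero <- stats::runif(n_patients) < p_zero
    gs <- ifelse(zero, 0, stats::rpois(n_patients, gs_mean))
    age <- round(pmin(90, pmax(30, stats::rnorm(n_patients, 55 + 0.08 * gs, 11))))
    sex <- as.integer(stats::runif(n_patients) <
                        stats::plogis(-0.1 + 0.02 * gs))   # 1 = male
    diabetes <- as.integer(stats::runif(n_patients) <
                             stats::plogis(-1.45 + 0.01 * gs))
    rows <- vector("list", 2 * n_patients)
    shapes <- vector("list", 2 * n_patients)
    grp <- severity_groups(gs)
    for (i in seq_len(n_patients)) {
      eff <- effect_map(gs[i])
      for (j in 1:2) {
        eye <- c("OD", "OS")[j]
        mult <- if (eye == "OS") 1 else laterality_multiplier
        depth <- eff$notch_depth_um * mult
        nn <- if (depth > 0) eff$n_notches else 0L
        shape_seed <- sample.int(.Machine$integer.max, 1)
        theta <- stats::runif(1, 0, pi)
        a_base <- stats::rnorm(1, 350, 25)
        b_base <- stats::rnorm(1, 280, 20)
        k <- (i - 1) * 2 + j
        shapes[[k]] <- generate_shape(
          base_a_um = a_base, base_b_um = min(b_base, a_base - 1),
          base_theta_rad = theta, n_notches = nn, notch_depth_um = depth,
          boundary_noise_um = boundary_noise_um, seed = shape_seed)
        rows[[k]] <- data.frame(
          patient_id = sprintf("P%04d", i), eye = eye,
          age_y = age[i], sex = sex[i], diabetes = diabetes[i],
          gs = gs[i], ternary = grp$ternary[i], binary = grp$binary[i],
          n_notches = nn, notch_depth_um = depth, shape_seed = shape_seed)
      }
    }
    list(cohort = do.call(rbind, rows), shapes = shapes)
  })
}

#' Default GS-to-dropout effect map
#'
#' Monotone non-decreasing map from a Gensini score to the dropout geometry
#' of one eye: the notch count grows stepwise (1 extra notch per 12 GS
#' points, capped at 8) and the notch depth linearly (10 um offset +
#' 0.8 um per GS point, capped at 110 um). A GS of 0 yields no dropout.
#'
#' @param gs nonnegative Gensini score
#' @return list with `n_notches` and `notch_depth_um`
#' @export
default_effect_map <- function(gs) {
  if (gs <= 0) return(list(n_notches = 0L, notch_depth_um = 0))
  list(n_notches = min(8L, 1L + as.integer(gs %/% 12)),
       notch_depth_um = min(110, 10 + 0.8 * gs))
}

#' Compute the nine FAZ biomarkers for generated shapes
#'
#' Convenience wrapper running the full metric suite (classic metrics, inner
#' ellipse, boundary distances) over the shapes of a [generate_cohort()]
#' result and binding them to the cohort table.
#'
#' @param cohort_result a list from [generate_cohort()]
#' @param eyes which eyes to process (default both)
#' @param n_restarts,n_points fit and resampling effort per eye; the default
#'   is reduced relative to [fit_inner_ellipse()] because cohort shapes are
#'   near-star-convex and the equivalent-ellipse start is reliable there
#' @param seed seed for the per-eye ellipse fits
#' @return the cohort data.frame with the metric columns appended (rows
#'   restricted to `eyes`)
#' @export
cohort_metrics <- function(cohort_result, eyes = c("OD", "OS"),
                           n_restarts = 2, n_boundary_samples = 128,
                           n_points = 256, seed = 1L) {
  tab <- cohort_result$cohort
  keep <- which(tab$eye %in% eyes)
  out <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    k <- keep[ii]
    p <- cohort_result$shapes[[k]]$polygon
    cm <- classic_metrics(p)
    fit <- fit_inner_ellipse(p, n_restarts = n_restarts,
                             n_boundary_samples = n_boundary_samples,
                             seed = seed)
    dd <- faz_ie_distances(p, fit, n_points = n_points)
    out[[ii]] <- cbind(tab[k, , drop = FALSE], cm,
                       data.frame(ie_area_um2 = ellipse_area(fit$ellipse),
                                  diff_ie_um2 = diff_inner_ellipse(p, fit),
                                  hd_um = dd$hd_um, cd_um2 = dd$cd_um2))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
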