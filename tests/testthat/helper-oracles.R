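# Independent oracles and fixture generators used across the test files.
# Every oracle is deliberately written by a different route than the package
# implementation it checks.

# signed area by fan triangulation from the first vertex (cross products),
# independent of the shoelace route
fan_area_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 2:(n - 1)) {
    s <- s + ((x[i] - x[1]) * (y[i + 1] - y[1]) -
              (x[i + 1] - x[1]) * (y[i] - y[1])) / 2
  }
  abs(s)
}

# gift-wrapping (Jarvis march) convex hull; returns hull vertex coordinates
gift_wrap_oracle <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur || j == nxt) next
      cr <- (x[nxt] - x[cur]) * (y[j] - y[cur]) -
            (y[nxt] - y[cur]) * (x[j] - x[cur])
      d_nxt <- (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2
      d_j <- (x[j] - x[cur])^2 + (y[j] - y[cur])^2
      if (cr < 0 || (abs(cr) < 1e-12 && d_j > d_nxt)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
  }
  cbind(x[hull], y[hull])
}

# exhaustive pairwise distance oracles
brute_directed_hausdorff <- function(A, B) {
  best <- -Inf
  for (i in seq_len(nrow(A))) {
    di <- Inf
    for (j in seq_len(nrow(B))) {
      di <- min(di, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    best <- max(best, di)
  }
  best
}
brute_hausdorff <- function(A, B) {
  max(brute_directed_hausdorff(A, B), brute_directed_hausdorff(B, A))
}
brute_chamfer <- function(A, B) {
  msq <- function(P, Q) {
    mean(vapply(seq_len(nrow(P)), function(i) {
      min(vapply(seq_len(nrow(Q)),
                 function(j) sum((P[i, ] - Q[j, ])^2), numeric(1)))
    }, numeric(1)))
  }
  (msq(A, B) + msq(B, A)) / 2
}

# random star-convex polygon around a center, smooth random radii
random_star_polygon <- function(seed, n_vertices = 48, r_mean = 250,
                                r_sd = 60, center = c(0, 0)) {
  set.seed(seed)
  th <- 2 * pi * (0:(n_vertices - 1)) / n_vertices
  raw <- stats::rnorm(n_vertices, 0, 1)
  k <- 5
  sm <- stats::filter(c(raw[(n_vertices - k + 1):n_vertices], raw, raw[1:k]),
                      rep(1 / (2 * k + 1), 2 * k + 1),
                      sides = 2)[(k + 1):(k + n_vertices)]
  r <- pmax(r_mean / 4, r_mean + r_sd * as.numeric(sm) / stats::sd(sm))
  faz_polygon(center[1] + r * cos(th), center[2] + r * sin(th))
}

# dense-grid brute-force largest-inscribed-ellipse oracle with exact
# containment check on every candidate's sampled boundary
grid_ie_oracle <- function(p, n_center = 5, n_axis = 12, n_theta = 6,
                           n_check = 90) {
  ctr <- polygon_centroid(p)
  rmax <- sqrt(max((p$x - ctr[1])^2 + (p$y - ctr[2])^2))
  off <- seq(-0.25, 0.25, length.out = n_center) * rmax
  axes <- seq(0.15, 1, length.out = n_axis) * rmax
  thetas <- seq(0, pi, length.out = n_theta + 1)[1:n_theta]
  tcheck <- 2 * pi * (0:(n_check - 1)) / n_check
  bnd <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
  best <- list(area = 0)
  for (dx in off) for (dy in off) {
    cx <- ctr[1] + dx; cy <- ctr[2] + dy
    if (!mgcv::in.out(bnd, cbind(cx, cy))) next
    for (th in thetas) {
      ct <- cos(th); st <- sin(th)
      for (a in axes) for (b in axes) {
        if (b > a) next
        if (pi * a * b <= best$area) next
        ex <- cx + a * cos(tcheck) * ct - b * sin(tcheck) * st
        ey <- cy + a * cos(tcheck) * st + b * sin(tcheck) * ct
        if (all(mgcv::in.out(bnd, cbind(ex, ey)))) {
          best <- list(area = pi * a * b, cx = cx, cy = cy, a = a, b = b,
                       theta = th)
        }
      }
    }
  }
  best
}

# dense rasterisation moments oracle for the equivalent ellipse
raster_moment_axes <- function(p, n_grid = 600) {
  gx <- seq(min(p$x), max(p$x), length.out = n_grid)
  gy <- seq(min(p$y), max(p$y), length.out = n_grid)
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  bnd <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
  inside <- mgcv::in.out(bnd, pts)
  xi <- pts[inside, 1]; yi <- pts[inside, 2]
  mxx <- mean((xi - mean(xi))^2)
  myy <- mean((yi - mean(yi))^2)
  mxy <- mean((xi - mean(xi)) * (yi - mean(yi)))
  lam <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
  c(major = 4 * sqrt(lam[1]), minor = 4 * sqrt(lam[2]))
}

# draw one cohort from the zero-inflated Poisson data-generating model
simulate_zip <- function(seed, n = 1000,
                         beta = c(2.2, 0.3, 0.01, 0.2, 0.1),
                         gamma = c(-0.6, -0.5, 0, 0, 0)) {
  set.seed(seed)
  m <- stats::rnorm(n); age <- stats::rnorm(n, 60, 10)
  sex <- stats::rbinom(n, 1, 0.5); dia <- stats::rbinom(n, 1, 0.25)
  X <- cbind(1, m, age - 60, sex, dia)
  mu <- exp(X %*% beta); pz <- stats::plogis(X %*% gamma)
  y <- ifelse(stats::runif(n) < pz, 0, stats::rpois(n, mu))
  data.frame(gs = y, age_y = age - 60, sex = sex, diabetes = dia, cd = m)
}

# exact point-to-polygon-edge distance, written as an explicit loop
point_to_edges_oracle <- function(pts, p) {
  n <- length(p$x)
  vapply(seq_len(nrow(pts)), function(i) {
    best <- Inf
    for (j in seq_len(n)) {
      jj <- if (j == n) 1 else j + 1
      ax <- p$x[j]; ay <- p$y[j]
      ex <- p$x[jj] - ax; ey <- p$y[jj] - ay
      t <- ((pts[i, 1] - ax) * ex + (pts[i, 2] - ay) * ey) /
        max(ex^2 + ey^2, 1e-300)
      t <- min(max(t, 0), 1)
      best <- min(best, sqrt((pts[i, 1] - ax - t * ex)^2 +
                             (pts[i, 2] - ay - t * ey)^2))
    }
    best
  }, numeric(1))
}

# regular n-gon approximating a circle
circle_polygon <- function(r, n = 256, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1)) / n
  faz_polygon(center[1] + r * cos(th), center[2] + r * sin(th))
}

# discretized axis-aligned ellipse
ellipse_polygon <- function(a, b, n = 360, center = c(0, 0), theta = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  u <- a * cos(th); v <- b * sin(th)
  faz_polygon(center[1] + u * cos(theta) - v * sin(theta),
              center[2] + u * sin(theta) + v * cos(theta))
}

# random simple (possibly concave) polygon: star-convex with rough radii
random_polygon <- function(seed, n_vertices = 24) {
  set.seed(seed)
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, 40, 260)
  faz_polygon(r * cos(th), r * sin(th))
}
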