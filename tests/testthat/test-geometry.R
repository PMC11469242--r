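test_that("polygon area and perimeter match closed forms and oracles", {
  sq <- faz_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1.0)
  expect_equal(polygon_perimeter(sq), 4.0)

  circ <- circle_polygon(100, 256)
  expect_lt(abs(polygon_area(circ) - pi * 100^2) / (pi * 100^2), 1e-3)
  expect_lt(abs(polygon_perimeter(circ) - 2 * pi * 100) / (2 * pi * 100), 1e-3)

  for (seed in 1:10) {
    p <- random_polygon(seed)
    expect_equal(polygon_area(p), fan_area_oracle(p$x, p$y),
                 tolerance = 1e-9)
  }

  # orientation invariance of the perimeter
  p <- random_polygon(3)
  pr <- faz_polygon(rev(p$x), rev(p$y))
  expect_identical(polygon_perimeter(p), polygon_perimeter(pr))

  expect_error(faz_polygon(c(0, 1), c(0, 1)), class = "faz_invalid_polygon_error")
})

test_that("convex hull is identity on convex input and matches gift wrapping", {
  pent <- circle_polygon(100, 5)
  h <- convex_hull(pent)
  expect_setequal(round(h$x, 9), round(pent$x, 9))

  # 5-pointed star: hull has 10 boundary vertices... only the 5 outer tips
  th <- 2 * pi * (0:9) / 10
  r <- rep(c(100, 40), 5)
  star <- faz_polygon(r * cos(th), r * sin(th))
  h <- convex_hull(star)
  expect_lt(polygon_area(star), polygon_area(h))
  expect_lt(polygon_perimeter(h), polygon_perimeter(star))

  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::runif(50, -100, 100); y <- stats::runif(50, -100, 100)
    p <- random_polygon(seed, 50)
    h <- convex_hull(p)
    o <- gift_wrap_oracle(p$x, p$y)
    expect_setequal(paste(round(h$x, 6), round(h$y, 6)),
                    paste(round(o[, 1], 6), round(o[, 2], 6)))
  }

  expect_error(faz_polygon(c(0, 1, 2, 3), c(0, 1, 2, 3)),
               class = "faz_invalid_polygon_error")
})

test_that("equivalent ellipse recovers axes of exact shapes and raster moments", {
  e <- ellipse_polygon(300, 150, 720)
  ee <- equivalent_ellipse(e)
  expect_lt(abs(ee$major_axis_um - 600) / 600, 0.01)
  expect_lt(abs(ee$minor_axis_um - 300) / 300, 0.01)

  circ <- circle_polygon(120, 720)
  ec <- equivalent_ellipse(circ)
  expect_lt(abs(ec$major_axis_um - ec$minor_axis_um) / ec$major_axis_um, 0.005)

  rect <- faz_polygon(c(0, 4, 4, 0), c(0, 0, 1, 1))
  er <- equivalent_ellipse(rect)
  o <- raster_moment_axes(rect)
  expect_lt(abs(er$major_axis_um - o["major"]) / o["major"], 0.01)
  expect_lt(abs(er$minor_axis_um - o["minor"]) / o["minor"], 0.01)

  # rotation carries through to theta
  e45 <- ellipse_polygon(300, 150, 720, theta = pi / 4)
  expect_lt(abs(equivalent_ellipse(e45)$theta_rad - pi / 4), 0.01)
})

test_that("mask_to_polygon extracts the largest component at sub-pixel scale", {
  px <- 5.86
  m <- matrix(0, 256, 256)
  for (r in 1:256) m[r, ] <- ((r - 0.5 - 128)^2 + ((1:256) - 0.5 - 128)^2) <= 50^2
  p <- mask_to_polygon(m, pixel_size_um = px)
  expect_lt(abs(polygon_area(p) - pi * (50 * px)^2) / (pi * (50 * px)^2), 0.01)

  # speck below min_component_px is dropped with a warning
  m2 <- m; m2[5:6, 5:7] <- 1
  expect_warning(p2 <- mask_to_polygon(m2, pixel_size_um = px,
                                       min_component_px = 10),
                 "secondary foreground")
  expect_equal(polygon_area(p2), polygon_area(p))

  # interior holes are filled: area unchanged by a hole
  m3 <- m; m3[120:136, 120:136] <- 0
  p3 <- mask_to_polygon(m3, pixel_size_um = px)
  expect_lt(abs(polygon_area(p3) - polygon_area(p)) / polygon_area(p), 0.01)

  expect_error(mask_to_polygon(matrix(0, 16, 16)),
               class = "faz_no_foreground_error")
  expect_error(mask_to_polygon(matrix(c(0, 1, 0, 0), 2, 2),
                               min_component_px = 10),
               class = "faz_no_foreground_error")
})

test_that("boundary resampling is uniform, deterministic and length-preserving", {
  circ <- circle_polygon(100, 720)
  cl <- resample_boundary(circ, 400)
  sp <- sqrt(rowSums((cl - rbind(cl[-1, ], cl[1, , drop = FALSE]))^2))
  expect_lt(max(abs(sp - 2 * pi * 100 / 400)) / (2 * pi * 100 / 400), 0.01)

  expect_identical(resample_boundary(circ, 128), resample_boundary(circ, 128))

  sq <- faz_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  cl8 <- resample_boundary(sq, 8)
  tot <- sum(sqrt(rowSums((cl8 - rbind(cl8[-1, ], cl8[1, , drop = FALSE]))^2)))
  expect_lt(abs(tot - 40) / 40, 0.02)

  expect_error(resample_boundary(circ, 7), class = "faz_parameter_error")

  # ellipse boundaries resample through the same interface
  e <- faz_ellipse(10, 20, 300, 200, 0.4)
  ce <- resample_boundary(e, 256)
  expect_identical(attr(ce, "source"), "ellipse")
  expect_equal(nrow(ce), 256)
})

test_that("geometric invariants hold over random polygons", {
  for (seed in 1:20) {
    p <- random_polygon(seed)
    a <- polygon_area(p); per <- polygon_perimeter(p)
    # isoperimetric inequality
    expect_lte(4 * pi * a, per^2 * (1 + 1e-12))
    h <- convex_hull(p)
    expect_gte(polygon_area(h), a - 1e-9)
    expect_lte(polygon_perimeter(h), per + 1e-9)
    # scale equivariance
    s <- 2.5
    ps <- faz_polygon(p$x * s, p$y * s)
    expect_equal(polygon_area(ps), a * s^2, tolerance = 1e-12)
    expect_equal(polygon_perimeter(ps), per * s, tolerance = 1e-12)
    expect_equal(equivalent_ellipse(ps)$major_axis_um,
                 equivalent_ellipse(p)$major_axis_um * s, tolerance = 1e-9)
    # rotation invariance
    phi <- 0.7
    pr <- faz_polygon(p$x * cos(phi) - p$y * sin(phi),
                      p$x * sin(phi) + p$y * cos(phi))
    expect_equal(polygon_area(pr), a, tolerance = 1e-9)
    expect_equal(polygon_perimeter(pr), per, tolerance = 1e-9)
  }
})
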