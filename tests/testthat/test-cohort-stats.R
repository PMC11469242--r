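make_null_groups <- function(seed, n_per = 60, k = 3, shift = 0) {
  set.seed(seed)
  data.frame(m = stats::rnorm(n_per * k) + rep(seq_len(k) - 1, each = n_per) * shift,
             ternary = rep(seq_len(k) - 1, each = n_per))
}

test_that("group tests pick the gated pathway and keep the type-I rate", {
  # normal, homoscedastic data take the ANOVA/Tukey branch
  r <- group_difference_tests(make_null_groups(1, shift = 1), "m")
  expect_equal(unique(r$pathway), "anova_tukey")
  expect_equal(nrow(r), 3)

  # heavily skewed data fall back to Kruskal-Wallis + Dunn/Holm
  d <- make_null_groups(2)
  d$m <- exp(2.5 * d$m)
  r2 <- group_difference_tests(d, "m")
  expect_equal(unique(r2$pathway), "kruskal_dunn_holm")

  # null calibration: family-wise rejection rate near alpha
  rej <- vapply(1:300, function(s) {
    r <- group_difference_tests(make_null_groups(s + 100, n_per = 40), "m")
    any(r$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(rej), 0.08)

  # power at a one-SD shift
  hit <- vapply(1:60, function(s) {
    r <- group_difference_tests(make_null_groups(s + 900, n_per = 60,
                                                 shift = 1), "m")
    all(r$p_adjusted < 0.05)
  }, logical(1))
  expect_gt(mean(hit), 0.9)

  expect_error(group_difference_tests(data.frame(m = 1:4,
                                                 ternary = c(0, 0, 1, 1)),
                                      "m"),
               class = "faz_data_error")
})

test_that("Bonferroni bookkeeping doubles with the metric count", {
  d <- make_null_groups(5, shift = 0.6)
  r1 <- group_difference_tests(d, "m", n_metrics_tested = 1)
  r2 <- group_difference_tests(d, "m", n_metrics_tested = 2)
  expect_equal(r1$p_posthoc, r2$p_posthoc)
  expect_equal(r2$p_adjusted, pmin(1, r1$p_adjusted * 2))
})

test_that("the zero-inflated Poisson fit recovers simulated coefficients", {
  d <- simulate_zip(3)
  z <- fit_zip(d, "cd")
  expect_equal(z$family, "zip")
  co <- z$coefficients
  est <- co$estimate[co$component == "count" & co$term == "m"]
  se <- co$se[co$component == "count" & co$term == "m"]
  expect_lt(abs(est - 0.3), 3 * se)
  est_z <- co$estimate[co$component == "zero" & co$term == "m"]
  se_z <- co$se[co$component == "zero" & co$term == "m"]
  expect_lt(abs(est_z - (-0.5)), 3 * se_z)
  # mixture nests the plain Poisson: its likelihood cannot be lower
  pois <- stats::glm(gs ~ cd + age_y + sex + diabetes, data = d,
                     family = stats::poisson())
  expect_gte(as.numeric(stats::logLik(z$model)),
             as.numeric(stats::logLik(pois)) - 1e-6)
})

test_that("degenerate ZIP outcomes fall back to plain Poisson with a warning", {
  d <- simulate_zip(4)
  d$gs <- d$gs + 1L   # no zeros
  expect_warning(z <- fit_zip(d, "cd"), "no zeros")
  expect_equal(z$family, "poisson")

  d2 <- simulate_zip(5); d2$gs <- 0L
  expect_warning(z2 <- fit_zip(d2, "cd"), "zero")
  expect_equal(z2$family, "poisson")

  # constant metric column is uninformative, not an error
  d3 <- simulate_zip(6); d3$cd <- 1
  z3 <- suppressWarnings(fit_zip(d3, "cd"))
  est <- z3$coefficients$estimate[z3$coefficients$component == "count" &
                                    z3$coefficients$term == "m"]
  expect_true(is.na(est) || abs(est) < 0.5)

  expect_error(fit_zip(simulate_zip(7, n = 10), "cd"),
               class = "faz_data_error")
})

test_that("SMOTE balances classes and flags synthetic rows", {
  set.seed(8)
  x <- rbind(matrix(stats::rnorm(200), ncol = 2),
             matrix(stats::rnorm(30, 4), ncol = 2))
  y <- rep(c("a", "b"), c(100, 15))
  b <- smote(x, y)
  expect_equal(as.vector(table(b$y)), c(100, 100))
  expect_equal(sum(b$synthetic), 85)
  expect_false(any(b$synthetic[seq_len(nrow(x))]))
  # synthetic points interpolate the minority cloud: stay in its bbox
  xb <- b$x[b$synthetic, ]
  expect_true(all(xb[, 1] >= min(x[101:115, 1]) &
                  xb[, 1] <= max(x[101:115, 1])))
  expect_error(smote(x[1:101, ], rep(c("a", "b"), c(100, 1))),
               class = "faz_data_error")
})

make_cv_cohort <- function(seed, n = 300, effect = 0, task_levels = 2) {
  set.seed(seed)
  lab <- rep(seq_len(task_levels) - 1, length.out = n)
  data.frame(age_y = stats::rnorm(n, 60, 10),
             sex = stats::rbinom(n, 1, 0.5),
             met = stats::rnorm(n) + effect * lab,
             binary = lab %% 2, ternary = lab %% 3)
}

test_that("cross-validated prediction is calibrated, deterministic and leak-free", {
  d <- make_cv_cohort(1, task_levels = 2)
  r <- predict_cv(d, "met", "binary", seed = 5)
  expect_length(r$fold_auc, 5)
  expect_true(all(r$fold_auc >= 0 & r$fold_auc <= 1))

  # determinism
  r2 <- predict_cv(d, "met", "binary", seed = 5)
  expect_identical(r$fold_auc, r2$fold_auc)

  # SMOTE leakage guard: test folds partition the original rows only
  idx <- sort(unlist(lapply(r$fold_detail, `[[`, "test_idx")))
  expect_identical(idx, seq_len(nrow(d)))
  expect_true(all(vapply(r$fold_detail, function(f) f$n_train_synthetic >= 0,
                         logical(1))))

  # a noiseless monotone transform of the label separates perfectly
  ds <- make_cv_cohort(2, task_levels = 2)
  ds$met <- ds$binary * 10 + 1
  rs <- predict_cv(ds, "met", "binary", seed = 1)
  expect_equal(rs$mean_auc, 1.0)
  dt <- make_cv_cohort(3, task_levels = 3)
  dt$met <- dt$ternary * 5 + 2
  rt <- predict_cv(dt, "met", "ternary", seed = 1)
  expect_equal(rt$mean_auc, 1.0, tolerance = 1e-6)

  # baseline model runs without a metric column
  rb <- predict_cv(d, NULL, "binary", seed = 2)
  expect_true(is.finite(rb$mean_auc))

  # the adjacent-threshold ordinal variant is a working alternative
  ra <- predict_cv(dt, "met", "ternary", seed = 1,
                   ordinal_model = "adjacent_threshold")
  expect_gt(ra$mean_auc, 0.95)

  expect_error(predict_cv(make_cv_cohort(4, n = 8), "met", "binary", seed = 1),
               class = "faz_data_error")
})

test_that("a metric carrying real signal beats the baseline model", {
  wins <- vapply(1:10, function(s) {
    d <- make_cv_cohort(s + 40, n = 200, effect = 1.2, task_levels = 2)
    predict_cv(d, "met", "binary", seed = s)$mean_auc >
      predict_cv(d, NULL, "binary", seed = s)$mean_auc
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("intergrader overlap and Bland-Altman agree with closed forms", {
  m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
  expect_equal(intergrader(m, m), list(dice = 1, jaccard = 1))
  m2 <- matrix(0L, 64, 64); m2[50:60, 50:60] <- 1L
  expect_equal(intergrader(m, m2), list(dice = 0, jaccard = 0))

  # dice = 2j/(1+j) on arbitrary overlapping pairs
  for (seed in 1:8) {
    set.seed(seed)
    a <- matrix(stats::rbinom(400, 1, 0.4), 20)
    b <- matrix(stats::rbinom(400, 1, 0.4), 20)
    r <- intergrader(a, b)
    expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-9)
  }

  # polygons rasterised into a shared frame
  p <- circle_polygon(200, 128, center = c(500, 500))
  q <- circle_polygon(200, 128, center = c(560, 500))
  r <- intergrader(p, q, pixel_size_um = 5)
  expect_gt(r$dice, 0.5); expect_lt(r$dice, 1)

  expect_error(intergrader(m, matrix(0L, 32, 32)), class = "faz_data_error")

  set.seed(9)
  a <- stats::rnorm(40); b <- a + stats::rnorm(40, 0.3, 0.5)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mean(a - b))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * stats::sd(a - b))
  expect_error(bland_altman(1, numeric(0)), class = "faz_parameter_error")
})
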