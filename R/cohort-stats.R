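#' Group-difference tests for one FAZ metric
#'
#' Tests a metric across severity groups following the conventional gated
#' pathway: if every group passes Shapiro-Wilk normality and Levene's test
#' finds homogeneous variances, one-way ANOVA with Tukey's HSD post hoc is
#' used; otherwise Kruskal-Wallis with Dunn's post hoc test and Holm
#' correction. A final Bonferroni factor accounts for testing several
#' metrics in the same analysis.
#'
#' @param data a data.frame with the metric column and a group column
#' @param metric name of the metric column
#' @param group name of the grouping column (default `"ternary"`)
#' @param n_metrics_tested Bonferroni factor across metrics (default 1)
#' @param alpha_gate significance level of the normality/homogeneity gates
#' @return a data.frame with one row per group pair: `group1`, `group2`,
#'   `p_posthoc` (Tukey- or Holm-adjusted within the metric), `p_adjusted`
#'   (after the across-metric Bonferroni factor), `pathway`
#' @export
group_difference_tests <- function(data, metric, group = "ternary",
                                   n_metrics_tested = 1, alpha_gate = 0.05) {
  if (!metric %in% names(data) || !group %in% names(data))
    parameter_error("metric/group column not found")
  x <- data[[metric]]
  g <- factor(data[[group]])
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 3))
    data_error("need at least 2 groups with at least 3 eyes each")

  normal <- all(vapply(levels(g), function(l) {
    xi <- x[g == l]
    if (length(xi) > 5000) xi <- xi[1:5000]
    stats::shapiro.test(xi)$p.value > alpha_gate
  }, logical(1)))
  homog <- car::leveneTest(x ~ g)[1, "Pr(>F)"] > alpha_gate

  if (normal && homog) {
    fit <- stats::aov(x ~ g)
    tk <- stats::TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    res <- data.frame(
      group1 = vapply(pairs, `[`, "", 2),
      group2 = vapply(pairs, `[`, "", 1),
      p_posthoc = tk[, "p adj"],
      pathway = "anova_tukey")
  } else {
    res <- dunn_test(x, g)
    res$pathway <- "kruskal_dunn_holm"
  }
  res$p_adjusted <- pmin(1, res$p_posthoc * n_metrics_tested)
  rownames(res) <- NULL
  res
}

# Dunn's rank-based post hoc z tests with tie correction and Holm adjustment
dunn_test <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  combs <- utils::combn(lv, 2)
  z <- apply(combs, 2, function(pr) {
    (mr[pr[1]] - mr[pr[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ],
             p_posthoc = stats::p.adjust(p, "holm"))
}

#' Zero-inflated Poisson model of the Gensini score
#'
#' Fits, by maximum likelihood, the mixture "structural zero with probability
#' `plogis(z'gamma)`, else Poisson with mean `exp(x'beta)`" with the FAZ
#' metric plus age, sex and diabetes in both the count and the
#' zero-inflation part. The GS outcome is rounded to an integer count. When
#' the outcome contains no zeros the inflation part is degenerate and the
#' function falls back to a plain Poisson GLM with a warning.
#'
#' @param data a data.frame with columns `gs`, `age_y`, `sex`, `diabetes`,
#'   the metric column, and (if `eye` is given) an `eye` column
#' @param metric name of the FAZ metric column
#' @param eye optionally `"OD"` or `"OS"` to fit the per-eye model
#' @return a list with `coefficients` (data.frame: component count/zero,
#'   term, estimate, se, z, p), `model` (the fitted object), and `family`
#'   (`"zip"` or `"poisson"`)
#' @export
fit_zip <- function(data, metric, eye = NULL) {
  if (!is.null(eye)) data <- data[data$eye == eye, , drop = FALSE]
  need <- c("gs", "age_y", "sex", "diabetes", metric)
  if (!all(need %in% names(data)))
    parameter_error(paste("missing columns:",
                          paste(setdiff(need, names(data)), collapse = ", ")))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (nrow(data) < 30) data_error("need at least 30 complete rows")
  d <- data.frame(y = as.integer(round(data$gs)), m = data[[metric]],
                  age_y = data$age_y, sex = data$sex, diabetes = data$diabetes)
  if (any(d$y < 0)) parameter_error("gs must be nonnegative")

  if (!any(d$y == 0) || all(d$y == 0)) {
    warning(sprintf(
      "outcome has %s zeros; zero-inflation is degenerate, fitting a plain Poisson model",
      if (all(d$y == 0)) "only" else "no"), call. = FALSE)
    m <- suppressWarnings(stats::glm(y ~ m + age_y + sex + diabetes, data = d,
                                     family = stats::poisson()))
    sm <- summary(m)$coefficients
    co <- data.frame(component = "count", term = rownames(sm),
                     estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4])
    rownames(co) <- NULL
    return(list(coefficients = co, model = m, family = "poisson"))
  }

  m <- glmmTMB::glmmTMB(y ~ m + age_y + sex + diabetes,
                        ziformula = ~ m + age_y + sex + diabetes,
                        family = stats::poisson(), data = d)
  sm <- summary(m)$coefficients
  mk <- function(tab, comp) {
    data.frame(component = comp, term = rownames(tab), estimate = tab[, 1],
               se = tab[, 2], z = tab[, 3], p = tab[, 4])
  }
  co <- rbind(mk(sm$cond, "count"), mk(sm$zi, "zero"))
  rownames(co) <- NULL
  list(coefficients = co, model = m, family = "zip")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances every class up to the majority-class size by interpolating
#' between a minority sample and one of its `k` nearest minority neighbours:
#' `x_new = x + u * (x_nn - x)` with `u ~ U(0, 1)`. Returns the augmented
#' feature matrix and labels plus a flag marking synthetic rows, so callers
#' can verify that synthetic points never leak into evaluation data.
#'
#' @param x numeric feature matrix (rows = observations)
#' @param y class labels (factor or coercible)
#' @param k number of nearest neighbours considered (default 5; reduced when
#'   a class is smaller than `k + 1`)
#' @return a list with `x`, `y`, and logical `synthetic`
#' @export
smote <- function(x, y, k = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  sizes <- table(y)
  n_target <- max(sizes)
  out_x <- list(x); out_y <- list(y)
  for (cl in names(sizes)) {
    need <- n_target - sizes[[cl]]
    if (need == 0) next
    xi <- x[y == cl, , drop = FALSE]
    n <- nrow(xi)
    if (n < 2) data_error("SMOTE needs at least 2 samples in every class")
    kk <- min(k, n - 1)
    d2 <- pairwise_sq(xi, xi)
    diag(d2) <- Inf
    nn_idx <- apply(d2, 1, function(r) order(r)[1:kk], simplify = FALSE)
    base <- sample.int(n, need, replace = TRUE)
    pick <- vapply(base, function(b) nn_idx[[b]][sample.int(kk, 1)], 0L)
    u <- stats::runif(need)
    new_x <- xi[base, , drop = FALSE] +
      u * (xi[pick, , drop = FALSE] - xi[base, , drop = FALSE])
    out_x <- c(out_x, list(new_x))
    out_y <- c(out_y, list(factor(rep(cl, need), levels = levels(y))))
  }
  xs <- do.call(rbind, out_x)
  ys <- do.call(c, lapply(out_y, as.character))
  list(x = xs, y = factor(ys, levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(xs) - nrow(x))))
}

#' SMOTE-balanced logistic prediction with stratified five-fold CV
#'
#' Evaluates how well age, sex and (optionally) one FAZ metric predict the
#' CAD severity group. Folds are stratified by class; SMOTE balancing is
#' applied to the training fold only, never to the held-out fold. The binary
#' task uses logistic regression and reports the ROC AUC; the ternary task
#' uses ordinal logistic regression and reports the macro (unweighted)
#' average of the three one-vs-rest AUCs. The 95% interval is a t-interval
#' over the five fold estimates.
#'
#' @param data a data.frame with `age_y`, `sex`, the label column (`binary`
#'   or `ternary`) and, if requested, the metric column; typically
#'   pre-filtered to left eyes
#' @param metric name of the FAZ metric column, or `NULL` for the
#'   age-plus-sex baseline model
#' @param task `"binary"` or `"ternary"`
#' @param seed integer seed controlling fold assignment and SMOTE draws
#' @param k_folds number of stratified folds (default 5)
#' @param smote_k SMOTE neighbourhood size (default 5)
#' @param ordinal_model `"cumulative"` (proportional-odds, default) or
#'   `"adjacent_threshold"`, a per-threshold variant fitted as separate
#'   logistic models between adjacent severity stages
#' @return a list of class `faz_cv_result`: `fold_auc`, `mean_auc`,
#'   `ci_95`, `f1`, `accuracy`, `precision`, `recall` (macro for the ternary
#'   task), and `fold_detail` (per fold: test row indices into `data`,
#'   training size, number of synthetic training rows)
#' @export
predict_cv <- function(data, metric = NULL, task = c("binary", "ternary"),
                       seed = 1L, k_folds = 5, smote_k = 5,
                       ordinal_model = c("cumulative", "adjacent_threshold")) {
  task <- match.arg(task)
  ordinal_model <- match.arg(ordinal_model)
  label <- task
  feats <- c("age_y", "sex", metric)
  if (!all(c(feats, label) %in% names(data)))
    parameter_error("missing feature or label columns")
  keep <- stats::complete.cases(data[, c(feats, label)])
  data <- data[keep, , drop = FALSE]
  y <- factor(data[[label]])
  if (nlevels(y) != ifelse(task == "binary", 2, 3))
    data_error(sprintf("%s task needs %d classes", task,
                       ifelse(task == "binary", 2, 3)))
  if (any(table(y) < 5)) data_error("every class needs at least 5 rows")
  x <- as.matrix(data[, feats, drop = FALSE])

  with_local_seed(seed, {
    folds <- stratified_folds(y, k_folds)
    fold_auc <- numeric(k_folds)
    fold_detail <- vector("list", k_folds)
    pred_class <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k_folds)) {
      te <- which(folds == f); tr <- which(folds != f)
      bal <- smote(x[tr, , drop = FALSE], y[tr], k = smote_k)
      dtr <- data.frame(bal$x); dtr$.y <- bal$y
      dte <- data.frame(x[te, , drop = FALSE])
      if (task == "binary") {
        fit <- suppressWarnings(stats::glm(.y ~ ., data = dtr,
                                           family = stats::binomial()))
        pr <- stats::predict(fit, newdata = dte, type = "response")
        fold_auc[f] <- as.numeric(pROC::auc(
          pROC::roc(response = y[te], predictor = pr, levels = levels(y),
                    direction = "<", quiet = TRUE)))
        pred_class[te] <- factor(levels(y)[1 + (pr > 0.5)], levels = levels(y))
      } else {
        pr <- ordinal_probs(dtr, dte, ordinal_model)
        fold_auc[f] <- macro_ovr_auc(y[te], pr)
        pred_class[te] <- factor(colnames(pr)[max.col(pr, "first")],
                                 levels = levels(y))
      }
      fold_detail[[f]] <- list(test_idx = which(keep)[te],
                               n_train = nrow(dtr),
                               n_train_synthetic = sum(bal$synthetic))
    }
    cls <- class_metrics(y, pred_class)
    se <- stats::sd(fold_auc) / sqrt(k_folds)
    ci <- mean(fold_auc) + c(-1, 1) * stats::qt(0.975, k_folds - 1) * se
    structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                   ci_95 = pmin(pmax(ci, 0), 1),
                   f1 = cls$f1, accuracy = cls$accuracy,
                   precision = cls$precision, recall = cls$recall,
                   fold_detail = fold_detail, task = task,
                   metric = if (is.null(metric)) "baseline" else metric),
              class = "faz_cv_result")
  })
}

#' @export
print.faz_cv_result <- function(x, ...) {
  cat(sprintf("<faz_cv_result> %s task, model: %s\n", x$task, x$metric))
  cat(sprintf("  mean AUC %.3f (95%% CI %.3f-%.3f), accuracy %.3f, F1 %.3f\n",
              x$mean_auc, x$ci_95[1], x$ci_95[2], x$accuracy, x$f1))
  invisible(x)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

# class probabilities for the 3-class ordinal task
ordinal_probs <- function(dtr, dte, ordinal_model) {
  lv <- levels(dtr$.y)
  if (ordinal_model == "cumulative") {
    # polr cannot start on perfectly separated data; the threshold variant can
    fit <- tryCatch(
      suppressWarnings(MASS::polr(.y ~ ., data = dtr, method = "logistic",
                                  Hess = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pr <- stats::predict(fit, newdata = dte, type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, lv))
      return(pr[, lv, drop = FALSE])
    }
  }
  # adjacent-threshold variant: one logistic model per stage boundary,
  # fitted on the observations in the two adjacent stages
  yi <- as.integer(dtr$.y)
  p_ge <- matrix(1, nrow(dte), length(lv))   # P(Y >= j) built stepwise
  for (j in 2:length(lv)) {
    sel <- yi %in% c(j - 1, j)
    dj <- dtr[sel, , drop = FALSE]
    dj$.y <- NULL
    dj$.b <- as.integer(yi[sel] == j)
    fj <- suppressWarnings(stats::glm(.b ~ ., data = dj,
                                      family = stats::binomial()))
    pj <- stats::predict(fj, newdata = dte, type = "response")
    p_ge[, j] <- p_ge[, j - 1] * pj
  }
  pr <- cbind(p_ge[, -ncol(p_ge)] - p_ge[, -1], p_ge[, ncol(p_ge)])
  pr <- pmax(pr, 0)
  pr <- pr / rowSums(pr)
  colnames(pr) <- lv
  pr
}

macro_ovr_auc <- function(y_true, probs) {
  lv <- levels(y_true)
  aucs <- vapply(lv, function(cl) {
    resp <- factor(ifelse(y_true == cl, "pos", "neg"), levels = c("neg", "pos"))
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp,
                                   predictor = probs[, cl],
                                   levels = c("neg", "pos"),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

class_metrics <- function(y_true, y_pred) {
  lv <- levels(y_true)
  per <- vapply(lv, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl, na.rm = TRUE)
    fp <- sum(y_true != cl & y_pred == cl, na.rm = TRUE)
    fn <- sum(y_true == cl & y_pred != cl, na.rm = TRUE)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  list(precision = mean(per[1, ]), recall = mean(per[2, ]),
       f1 = mean(per[3, ]),
       accuracy = mean(y_true == y_pred, na.rm = TRUE))
}

#' Intergrader agreement
#'
#' Region overlap between two graders' segmentations of the same image:
#' Dice coefficient `2|A&B| / (|A| + |B|)` and Jaccard index
#' `|A&B| / |A|B|` on the rasterised masks. Polygons are rasterised onto the
#' frame implied by their joint bounding box when masks are not supplied.
#'
#' @param a,b the two graders' segmentations: `faz_mask` objects, binary
#'   matrices of identical size, or [faz_polygon()]s
#' @param pixel_size_um rasterisation scale used when polygons are given
#' @return a list with `dice` and `jaccard`
#' @export
intergrader <- function(a, b, pixel_size_um = default_pixel_size_um()) {
  ma <- as_binary_mask(a, b, pixel_size_um, 1)
  mb <- as_binary_mask(b, a, pixel_size_um, 2)
  if (!all(dim(ma) == dim(mb)))
    data_error("grader masks must share the same image frame")
  inter <- sum(ma & mb)
  dice <- if (sum(ma) + sum(mb) == 0) NA_real_ else
    2 * inter / (sum(ma) + sum(mb))
  uni <- sum(ma | mb)
  jac <- if (uni == 0) NA_real_ else inter / uni
  list(dice = dice, jaccard = jac)
}

as_binary_mask <- function(obj, other, pixel_size_um, which_one) {
  if (inherits(obj, "faz_mask")) return(obj$pixels != 0)
  if (is.matrix(obj) && !inherits(obj, "faz_polygon")) return(obj != 0)
  p <- faz_polygon(obj)
  q <- if (inherits(other, "faz_polygon") ||
           (!is.matrix(other) && !inherits(other, "faz_mask")))
    faz_polygon(other) else NULL
  xr <- range(p$x, if (!is.null(q)) q$x)
  yr <- range(p$y, if (!is.null(q)) q$y)
  pad <- 2 * pixel_size_um
  gx <- seq(xr[1] - pad, xr[2] + pad, by = pixel_size_um)
  gy <- seq(yr[1] - pad, yr[2] + pad, by = pixel_size_um)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  matrix(points_in_polygon(pts, p), nrow = length(gy), ncol = length(gx),
         byrow = TRUE)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean paired difference `a - b`) and 95% limits of agreement
#' `bias +/- 1.96 * SD` for one metric measured by two graders.
#'
#' @param a,b paired numeric measurement vectors
#' @return a list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) parameter_error("paired vectors must match")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) data_error("need at least 2 complete pairs")
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
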