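#' Stratified calibration/validation split
#'
#' Random 75/25 split in which the validation set is guaranteed to contain
#' at least one sample of every year, every harvest date and every
#' treatment (marginal coverage, mirroring autocorrelation-aware repeated
#' splitting).  Calibration and validation are disjoint and exhaustive.
#'
#' @param table data.frame with `year`, `harvest`, `treatment` columns.
#' @param cal_fraction calibration fraction (default 0.75).
#' @param seed integer seed.
#' @return list with integer row indices `calibration` and `validation`.
#' @export
stratified_split <- function(table, cal_fraction = 0.75, seed = 1) {
  n <- nrow(table)
  strata <- c("year", "harvest", "treatment")
  for (s in strata) {
    tb <- table(table[[s]])
    small <- names(tb)[tb < 2]
    if (length(small) > 0) {
      stop_fusion(sprintf("stratum %s = %s has fewer than 2 rows", s, small[1]))
    }
  }
  m <- max(length(unique(table$treatment)), round(n * (1 - cal_fraction)))
  covers <- function(idx) {
    all(vapply(strata, function(s) {
      length(unique(table[[s]][idx])) == length(unique(table[[s]]))
    }, logical(1)))
  }
  with_seed(seed, {
    val <- NULL
    for (try in seq_len(100)) {
      cand <- sample.int(n, m)
      if (covers(cand)) { val <- cand; break }
    }
    if (is.null(val)) {
      # constructive fallback: seed coverage, then fill at random
      val <- integer(0)
      for (s in strata) {
        for (lev in unique(table[[s]])) {
          if (!lev %in% table[[s]][val]) {
            val <- c(val, sample(which(table[[s]] == lev), 1))
          }
        }
      }
      val <- unique(val)
      pool <- setdiff(seq_len(n), val)
      if (length(val) < m) val <- c(val, sample(pool, m - length(val)))
    }
    list(calibration = sort(setdiff(seq_len(n), val)), validation = sort(val))
  })
}

#' Fit a random-forest regressor
#'
#' Thin wrapper around a 500-tree regression forest exposing the contract
#' the pipeline relies on: prediction, out-of-bag mean squared error and
#' permutation importance.  `mtry` defaults to `p/3` and is clamped to
#' `[1, p]` with a warning.
#'
#' @param x data.frame of predictors.
#' @param y numeric response.
#' @param mtry candidate variables per split (default `max(1, floor(p/3))`).
#' @param num_trees trees (default 500).
#' @param seed integer seed.
#' @return object of class `rf_fit` with elements `model`, `oob_mse`,
#'   `importance`, `mtry`.
#' @export
fit_rf <- function(x, y, mtry = NULL, num_trees = 500, seed = 1) {
  p <- ncol(x)
  mtry <- mtry %||% max(1, floor(p / 3))
  if (mtry > p) {
    warning(sprintf("mtry %d exceeds %d predictors; clamped", mtry, p))
    mtry <- p
  }
  mtry <- max(1L, as.integer(mtry))
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees, mtry = mtry,
                        importance = "permutation", seed = seed,
                        num.threads = 1)
  structure(list(model = fit, oob_mse = fit$prediction.error,
                 importance = fit$variable.importance, mtry = mtry),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  predict(object$model, data = newdata, num.threads = 1)$predictions
}

#' Validation coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - c)^2)`.  By default `c` is the
#' mean of the observed validation values (the standard convention, which
#' keeps R2 comparable across models); `center = "predicted"` uses the
#' mean predicted value instead.
#'
#' @param observed,predicted numeric vectors (>= 2 values).
#' @param center `"observed"` (default) or `"predicted"`.
#' @return unitless scalar (<= 1).
#' @export
r2_val <- function(observed, predicted, center = c("observed", "predicted")) {
  center <- match.arg(center)
  assert_that(length(observed) >= 2 && length(observed) == length(predicted),
              "need >= 2 paired observations")
  cbar <- if (center == "observed") mean(observed) else mean(predicted)
  denom <- sum((observed - cbar)^2)
  assert_that(denom > 0, "zero denominator: observed values are constant")
  1 - sum((observed - predicted)^2) / denom
}

#' Relative root mean squared error of prediction
#'
#' `rRMSEP = 100 * sqrt(mean((y - yhat)^2)) / (max(y) - min(y))`, in
#' percent of the observed range.
#'
#' @param observed,predicted numeric vectors.
#' @return percentage.
#' @export
rrmsep <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 2,
              "need >= 2 paired observations")
  rng <- max(observed) - min(observed)
  assert_that(rng > 0, "zero observed range")
  100 * sqrt(mean((observed - predicted)^2)) / rng
}

#' Normalised deviation of prediction from observation
#'
#' `(yhat - y) / (yhat + y)`, bounded in `[-1, 1]` for positive values;
#' positive = overestimation.  A zero sum yields `NA` with a warning.
#'
#' @param observed,predicted numeric vectors.
#' @return numeric vector.
#' @export
norm_dev <- function(observed, predicted) {
  s <- predicted + observed
  out <- (predicted - observed) / s
  if (any(s == 0)) {
    warning("zero observed + predicted sum: normalised deviation set to NA")
    out[s == 0] <- NA_real_
  }
  out
}

# 5-fold cross-validated mtry choice on the calibration rows over a grid
# around p/3; ties resolved toward the smaller mtry.
tune_mtry <- function(x, y, seed, num_trees = 500, k_folds = 5) {
  p <- ncol(x)
  grid <- sort(unique(pmin(pmax(ceiling(p / 3) + (-2:2), 1), p)))
  if (length(grid) == 1) return(grid)
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_mse <- vapply(grid, function(m) {
    errs <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = num_trees, mtry = m,
                            seed = derive_seed(seed, f * 100 + m),
                            num.threads = 1)
      pr <- predict(fit, data = x[!tr, , drop = FALSE],
                    num.threads = 1)$predictions
      mean((y[!tr] - pr)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[which.min(cv_mse)]
}

#' Repeated stratified-split random-forest modeling
#'
#' The validation engine: `n_splits` stratified 75/25 splits; per split,
#' mtry is tuned by 5-fold cross-validation on the calibration rows over
#' a grid around `p/3`, a 500-tree forest is fitted, and the validation
#' R2 and rRMSEP recorded together with the permutation importances.
#' Aggregates the metric distributions, the median-importance variable
#' ranking, per-sample validation predictions and appearance counts.
#'
#' @param table data.frame with key columns (`plot_id`, `year`, `harvest`,
#'   `treatment`), the predictors and the response.
#' @param predictors character vector of predictor column names.
#' @param response response column name.
#' @param n_splits number of random splits (default 100).
#' @param seed master seed; per-split seeds are derived from it.
#' @param tune logical; `FALSE` skips mtry tuning (uses `p/3`).
#' @param num_trees trees per forest.
#' @param center passed to [r2_val()].
#' @return object of class `model_summary`: `splits` (per-split metrics),
#'   `metrics` (distribution summaries), `importance_ranking`,
#'   `predictions` (long per-sample table), `appearance_counts`.
#' @export
repeated_modeling <- function(table, predictors, response, n_splits = 100,
                              seed = 1, tune = TRUE, num_trees = 500,
                              center = "observed") {
  assert_that(all(predictors %in% names(table)),
              "missing predictor columns in table")
  assert_that(response %in% names(table), "missing response column")
  x_all <- table[, predictors, drop = FALSE]
  y_all <- table[[response]]
  assert_that(!anyNA(x_all) && !anyNA(y_all), "table contains missing values")
  n <- nrow(table)
  splits <- vector("list", n_splits)
  imp <- matrix(NA_real_, n_splits, length(predictors),
                dimnames = list(NULL, predictors))
  preds <- vector("list", n_splits)
  appear <- integer(n)
  for (s in seq_len(n_splits)) {
    s_seed <- derive_seed(seed, s)
    sp <- tryCatch(stratified_split(table, seed = s_seed),
                   error = function(e) {
                     stop_fusion(sprintf("split %d failed: %s", s, conditionMessage(e)))
                   })
    xc <- x_all[sp$calibration, , drop = FALSE]
    yc <- y_all[sp$calibration]
    mtry <- if (tune) tune_mtry(xc, yc, seed = derive_seed(s_seed, 7),
                                num_trees = num_trees)
            else max(1, floor(length(predictors) / 3))
    fit <- fit_rf(xc, yc, mtry = mtry, num_trees = num_trees,
                  seed = derive_seed(s_seed, 11))
    yhat <- predict(fit, x_all[sp$validation, , drop = FALSE])
    yv <- y_all[sp$validation]
    splits[[s]] <- data.frame(split = s, seed = s_seed, mtry = mtry,
                              r2_val = r2_val(yv, yhat, center = center),
                              rrmsep = rrmsep(yv, yhat))
    imp[s, ] <- fit$importance[predictors]
    appear[sp$validation] <- appear[sp$validation] + 1L
    preds[[s]] <- data.frame(split = s, row = sp$validation,
                             observed = yv, predicted = yhat)
  }
  splits <- do.call(rbind, splits)
  med_imp <- apply(imp, 2, median)
  ranking <- data.frame(variable = predictors, median_importance = med_imp)
  ranking <- ranking[order(-ranking$median_importance, ranking$variable), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  qs <- function(v) {
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    c(p5 = q[1], q25 = q[2], median = q[3], q75 = q[4], p95 = q[5])
  }
  predictions <- do.call(rbind, preds)
  keys <- intersect(c("plot_id", "year", "harvest", "treatment"), names(table))
  predictions <- cbind(predictions, table[predictions$row, keys, drop = FALSE])
  rownames(predictions) <- NULL
  structure(list(
    splits = splits,
    metrics = list(r2_val = qs(splits$r2_val), rrmsep = qs(splits$rrmsep)),
    importance = imp, importance_ranking = ranking,
    predictions = predictions, appearance_counts = appear,
    response = response, n_splits = n_splits, seed = seed),
    class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary> %s, %d splits: median R2_val %.3f, median rRMSEP %.2f%%\n",
              x$response, x$n_splits, x$metrics$r2_val[["median"]],
              x$metrics$rrmsep[["median"]]))
  invisible(x)
}

#' Dunn's post-hoc pairwise rank test
#'
#' Pairwise z statistics on the joint ranks with tie correction,
#' two-sided p-values, Holm-adjusted.
#'
#' @param values numeric vector.
#' @param groups factor/vector of group labels.
#' @param p_adjust adjustment method (default `"holm"`).
#' @return data.frame `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2, "need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  assert_that(all(ns >= 3), "every group needs at least 3 values")
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    assert_that(se > 0, "degenerate (fully tied) groups")
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

# Compact letter display from a pairwise significance table
# (insert-and-absorb).
cld_letters <- function(levs, pair_table, alpha = 0.05) {
  sets <- list(levs)
  sig <- pair_table[pair_table$p_adj < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    a <- sig$group1[k]; b <- sig$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[i] && all(new_sets[[i]] %in% new_sets[[j]]) &&
            length(new_sets[[i]]) < length(new_sets[[j]])) keep[i] <- FALSE
      }
    }
    sets <- new_sets[keep]
  }
  lab <- setNames(rep("", length(levs)), levs)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) lab[g] <- paste0(lab[g], letters[i])
  }
  lab
}

#' Year effect on prediction quality (Kruskal-Wallis + Dunn)
#'
#' For each mixture family, tests whether the normalised deviations
#' differ between sampling years: a Kruskal-Wallis test plus Dunn's
#' pairwise comparisons (Holm-adjusted) and a compact letter display.
#'
#' @param df data.frame with columns `norm_dev`, `year`, `mixture`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return named list (one element per mixture) with `kruskal` (the
#'   `htest`), `dunn` (pairwise table) and `letters`.
#' @export
year_effect_test <- function(df, alpha = 0.05) {
  assert_that(all(c("norm_dev", "year", "mixture") %in% names(df)),
              "need columns norm_dev, year, mixture")
  out <- lapply(split(df, df$mixture), function(d) {
    g <- factor(d$year)
    assert_that(nlevels(g) >= 2, "need at least 2 year groups")
    kw <- kruskal.test(d$norm_dev, g)
    dn <- dunn_test(d$norm_dev, g)
    list(kruskal = kw, dunn = dn,
         letters = cld_letters(levels(g), dn, alpha = alpha))
  })
  out
}
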