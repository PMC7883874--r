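#' Permutation importance averaged over repeated forests
#'
#' Fits `n_runs` random forests (500 trees each, regression mtry p/3)
#' with distinct derived seeds and averages the permutation importance
#' (increase in out-of-bag mean squared error) of every predictor.
#' Variables are returned ranked by decreasing mean importance, ties
#' broken by column name for reproducibility.
#'
#' @param x data.frame of predictors (>= 2 columns).
#' @param y numeric response (>= 10 values, non-constant).
#' @param n_runs number of forests (default 50).
#' @param seed integer seed.
#' @param num_trees trees per forest (default 500).
#' @return data.frame `variable`, `mean_importance`, `sd_importance`,
#'   `rank`, sorted by rank.
#' @export
importance_runs <- function(x, y, n_runs = 50, seed = 1, num_trees = 500) {
  assert_that(ncol(x) >= 2, "need at least 2 predictors")
  assert_that(length(y) >= 10, "need at least 10 samples")
  assert_that(sd(y) > 0, "response is constant")
  p <- ncol(x)
  imp <- matrix(NA_real_, n_runs, p, dimnames = list(NULL, colnames(x)))
  for (r in seq_len(n_runs)) {
    fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                          mtry = max(1, floor(p / 3)),
                          importance = "permutation",
                          seed = derive_seed(seed, r), num.threads = 1)
    imp[r, ] <- fit$variable.importance[colnames(x)]
  }
  out <- data.frame(variable = colnames(x),
                    mean_importance = colMeans(imp),
                    sd_importance = apply(imp, 2, sd))
  out <- out[order(-out$mean_importance, out$variable), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Thresholding step: discard irrelevant variables
#'
#' A regression tree is fitted to the importance standard deviation as a
#' function of the importance rank; the minimum of its predictions is the
#' threshold, and variables whose mean importance falls below it are
#' discarded (noise variables have small, flat importance with small
#' jitter, so the tree's lowest plateau estimates the noise level).  If
#' everything would be discarded the top `ceiling(sqrt(p))` variables are
#' kept with a warning.
#'
#' @param ranked output of [importance_runs()].
#' @return list with `retained` (character vector, importance order) and
#'   `threshold_value`.
#' @export
threshold_step <- function(ranked) {
  assert_that(nrow(ranked) >= 1, "ranked variable list is empty")
  if (nrow(ranked) == 1) {
    return(list(retained = ranked$variable, threshold_value = -Inf))
  }
  tree <- rpart::rpart(sd_importance ~ rank, data = ranked, method = "anova",
                       control = rpart::rpart.control(minsplit = 2, cp = 0.01))
  threshold <- min(predict(tree))
  retained <- ranked$variable[ranked$mean_importance >= threshold]
  if (length(retained) == 0) {
    warning("threshold discarded every variable; keeping top ceiling(sqrt(p))")
    retained <- ranked$variable[seq_len(ceiling(sqrt(nrow(ranked))))]
  }
  list(retained = retained, threshold_value = threshold)
}

# Mean (and per-run vector) of OOB MSE for a fixed variable set.
oob_runs <- function(x, y, vars, n_runs, seed, num_trees) {
  vapply(seq_len(n_runs), function(r) {
    ranger::ranger(x = x[, vars, drop = FALSE], y = y, num.trees = num_trees,
                   mtry = max(1, floor(length(vars) / 3)),
                   seed = derive_seed(seed, r), num.threads = 1)$prediction.error
  }, numeric(1))
}

#' Interpretation step: smallest nested model within one sd of the best
#'
#' Fits the nested models over the importance-ordered prefixes of the
#' retained variables; each prefix's out-of-bag error is averaged over
#' `n_runs` forests.  The selected set is the smallest prefix whose mean
#' OOB error is within one standard deviation (of the minimising prefix's
#' OOB errors) of the minimum.
#'
#' @param x predictors, `y` response.
#' @param y numeric response.
#' @param retained character vector in importance order.
#' @param n_runs forests per prefix (default 25).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @return list with `interpretation_set`, `oob_trace` (mean OOB per
#'   prefix), `oob_sd` (sd per prefix).
#' @export
interpretation_step <- function(x, y, retained, n_runs = 25, seed = 1,
                                num_trees = 500) {
  assert_that(length(retained) >= 1, "no retained variables")
  K <- length(retained)
  oob <- matrix(NA_real_, n_runs, K)
  for (k in seq_len(K)) {
    oob[, k] <- oob_runs(x, y, retained[seq_len(k)], n_runs,
                         derive_seed(seed, 1000 + k), num_trees)
  }
  trace <- colMeans(oob)
  sds <- apply(oob, 2, sd)
  kmin <- which.min(trace)
  ksel <- which(trace <= trace[kmin] + sds[kmin])[1]
  list(interpretation_set = retained[seq_len(ksel)],
       oob_trace = trace, oob_sd = sds)
}

#' Prediction step: greedy forward pass against the noise fluctuation
#'
#' Walks the interpretation set in importance order; a variable is kept
#' only if adding it lowers the mean OOB error by more than the average
#' absolute OOB fluctuation observed among the noisier post-interpretation
#' prefixes of the OOB trace.  The first (most important) variable is
#' always kept, so the set is never empty.
#'
#' @param x predictors, `y` response.
#' @param y numeric response.
#' @param interpretation_set character vector in importance order.
#' @param oob_trace full OOB trace from [interpretation_step()].
#' @param n_runs forests per candidate model (default 25).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @return character vector: the prediction set.
#' @export
prediction_step <- function(x, y, interpretation_set, oob_trace,
                            n_runs = 25, seed = 1, num_trees = 500) {
  assert_that(length(interpretation_set) >= 1, "interpretation set is empty")
  kI <- length(interpretation_set)
  K <- length(oob_trace)
  noise_fluct <- if (K > kI) mean(abs(diff(oob_trace[kI:K]))) else 0
  kept <- interpretation_set[1]
  cur <- mean(oob_runs(x, y, kept, n_runs, derive_seed(seed, 2000), num_trees))
  if (kI >= 2) {
    for (v in interpretation_set[-1]) {
      cand <- c(kept, v)
      new <- mean(oob_runs(x, y, cand, n_runs,
                           derive_seed(seed, 2000 + length(cand)), num_trees))
      if (cur - new > noise_fluct) {
        kept <- cand
        cur <- new
      }
    }
  }
  kept
}

#' Three-step random-forest variable selection
#'
#' Runs the thresholding, interpretation and prediction steps in sequence
#' and returns the full selection report.  The nesting
#' `prediction subset-of interpretation subset-of retained` holds by
#' construction; results are fully deterministic for fixed inputs and
#' seed.
#'
#' @param x data.frame of predictors.
#' @param y numeric response.
#' @param n_runs_threshold,n_runs_interp,n_runs_pred forest counts for the
#'   three steps (defaults 50, 25, 25).
#' @param seed integer seed.
#' @param num_trees trees per forest (default 500).
#' @return object of class `selection_result`: list with `ranked`,
#'   `threshold_value`, `retained_after_threshold`, `interpretation_set`,
#'   `prediction_set`, `oob_trace`, `oob_sd`.
#' @export
select_variables <- function(x, y, n_runs_threshold = 50, n_runs_interp = 25,
                             n_runs_pred = 25, seed = 1, num_trees = 500) {
  ranked <- importance_runs(x, y, n_runs = n_runs_threshold, seed = seed,
                            num_trees = num_trees)
  th <- threshold_step(ranked)
  interp <- interpretation_step(x, y, th$retained, n_runs = n_runs_interp,
                                seed = seed, num_trees = num_trees)
  pred <- prediction_step(x, y, interp$interpretation_set, interp$oob_trace,
                          n_runs = n_runs_pred, seed = seed,
                          num_trees = num_trees)
  structure(list(ranked = ranked, threshold_value = th$threshold_value,
                 retained_after_threshold = th$retained,
                 interpretation_set = interp$interpretation_set,
                 prediction_set = pred, oob_trace = interp$oob_trace,
                 oob_sd = interp$oob_sd),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d ranked | %d retained | %d interpretation | %d prediction\n",
              nrow(x$ranked), length(x$retained_after_threshold),
              length(x$interpretation_set), length(x$prediction_set)))
  cat("prediction set:", paste(x$prediction_set, collapse = ", "), "\n")
  invisible(x)
}
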