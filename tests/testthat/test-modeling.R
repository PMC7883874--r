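test_that("stratified splits cover every year, harvest and treatment", {
  tr <- default_truth()
  for (s in c(1, 2, 3, 10, 50)) {
    sp <- stratified_split(tr, seed = s)
    expect_equal(sort(c(sp$calibration, sp$validation)), seq_len(nrow(tr)))
    expect_length(sp$validation, 35)
    v <- tr[sp$validation, ]
    expect_setequal(unique(v$year), unique(tr$year))
    expect_setequal(unique(v$harvest), unique(tr$harvest))
    expect_setequal(unique(v$treatment), unique(tr$treatment))
  }
  expect_identical(stratified_split(tr, seed = 4), stratified_split(tr, seed = 4))
})

test_that("singleton strata abort with the stratum named", {
  tr <- default_truth()
  tr$treatment[1] <- "ODD"
  expect_error(stratified_split(tr, seed = 1), "ODD")
})

test_that("random forest wrapper honours the fitting contract", {
  set.seed(3)
  x <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
  y <- 3 * x$x1 + rnorm(200, 0, 0.5)
  fit <- fit_rf(x[1:150, ], y[1:150], seed = 1)
  pr <- predict(fit, x[151:200, ])
  expect_gt(r2_val(y[151:200], pr), 0.8)
  expect_equal(names(which.max(fit$importance)), "x1")
  expect_warning(fit2 <- fit_rf(x, y, mtry = 10, seed = 1), "clamped")
  expect_equal(fit2$mtry, 3)
  yc <- rep(2, 200)
  fitc <- fit_rf(x, yc, seed = 1)
  expect_equal(fitc$oob_mse, 0)
  expect_equal(unique(predict(fitc, x)), 2)
})

test_that("validation R2 follows its definition in both centring conventions", {
  expect_equal(r2_val(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2_val(c(1, 2, 3), c(2, 2, 2)), 0)
  obs <- c(2, 4, 9); prd <- c(3, 5, 7)
  expect_equal(r2_val(obs, prd), 1 - sum((obs - prd)^2) / sum((obs - 5)^2))
  expect_equal(r2_val(obs, prd, center = "predicted"),
               1 - sum((obs - prd)^2) / sum((obs - 5)^2))  # same mean here
  expect_error(r2_val(c(2, 2), c(1, 3)), "constant")
})

test_that("rRMSEP is the range-normalised RMSE in percent", {
  expect_equal(rrmsep(c(0, 10), c(1, 9)), 10)
  expect_equal(rrmsep(c(1, 5, 7), c(1, 5, 7)), 0)
  obs <- c(2, 4, 9); prd <- c(3, 5, 7)
  expect_equal(rrmsep(obs * 3, prd * 3), rrmsep(obs, prd), tolerance = 1e-12)
  expect_error(rrmsep(c(4, 4), c(1, 2)), "zero observed range")
})

test_that("normalised deviation is antisymmetric and bounded", {
  expect_equal(norm_dev(1, 1), 0)
  expect_equal(norm_dev(1, 3), 0.5)
  expect_equal(norm_dev(3, 1), -0.5)
  expect_warning(nd <- norm_dev(0, 0), "set to NA")
  expect_true(is.na(nd))
  set.seed(2)
  o <- runif(50, 0.1, 10); p <- runif(50, 0.1, 10)
  expect_true(all(abs(norm_dev(o, p)) <= 1))
  expect_equal(norm_dev(o, p), -norm_dev(p, o))
})

test_that("repeated modeling metrics agree with recomputation from stored predictions", {
  tr <- default_truth()
  set.seed(8)
  tr$pred1 <- tr$FM_t_ha * exp(rnorm(nrow(tr), 0, 0.15))
  tr$pred2 <- rnorm(nrow(tr))
  tr$pred3 <- tr$FM_t_ha + rnorm(nrow(tr), 0, 2)
  ms <- repeated_modeling(tr, c("pred1", "pred2", "pred3"), "FM_t_ha",
                          n_splits = 4, seed = 5, tune = FALSE)
  expect_equal(nrow(ms$splits), 4)
  for (s in 1:4) {
    d <- ms$predictions[ms$predictions$split == s, ]
    expect_equal(ms$splits$r2_val[s],
                 1 - sum((d$observed - d$predicted)^2) /
                   sum((d$observed - mean(d$observed))^2), tolerance = 1e-10)
    expect_equal(ms$splits$rrmsep[s],
                 100 * sqrt(mean((d$observed - d$predicted)^2)) /
                   diff(range(d$observed)), tolerance = 1e-10)
  }
  expect_equal(sum(ms$appearance_counts), 4 * 35)
  expect_equal(ms$importance_ranking$variable[3], "pred2")  # pure noise last
  ms2 <- repeated_modeling(tr, c("pred1", "pred2", "pred3"), "FM_t_ha",
                           n_splits = 4, seed = 5, tune = FALSE)
  expect_identical(ms$splits, ms2$splits)
})

test_that("Kruskal-Wallis statistic matches a rank-based brute-force computation", {
  set.seed(6)
  for (k in 1:5) {
    vals <- c(rnorm(8), rnorm(7, 0.5), sample(rnorm(5), 5, TRUE))
    grp <- rep(c("a", "b", "c"), c(8, 7, 5))
    kw <- kruskal.test(vals, factor(grp))
    expect_equal(unname(kw$statistic), brute_kruskal_h(vals, grp),
                 tolerance = 1e-10)
  }
})

test_that("two-group Dunn z is consistent with the Kruskal-Wallis H", {
  set.seed(12)
  vals <- c(rnorm(10), rnorm(12, 0.8))
  grp <- rep(c("y1", "y2"), c(10, 12))
  dn <- dunn_test(vals, grp)
  kw <- kruskal.test(vals, factor(grp))
  expect_equal(dn$z^2, unname(kw$statistic), tolerance = 1e-10)
  expect_error(dunn_test(rep(1, 6), rep(c("a", "b"), 3)), "at least 3|degenerate")
})

test_that("year effect test reports per-mixture tests and letter displays", {
  set.seed(31)
  df <- data.frame(
    norm_dev = c(rnorm(20, 0.25, 0.05), rnorm(20, -0.05, 0.05),
                 rnorm(20, 0, 0.05), rnorm(20, 0, 0.05)),
    year = rep(rep(c(2018, 2019), each = 20), 2),
    mixture = rep(c("CG", "LG"), each = 40))
  res <- year_effect_test(df)
  expect_named(res, c("CG", "LG"))
  expect_lt(res$CG$kruskal$p.value, 0.01)
  expect_gt(res$LG$kruskal$p.value, 0.05)
  expect_false(res$CG$letters[["2018"]] == res$CG$letters[["2019"]])
  expect_equal(res$LG$letters[["2018"]], res$LG$letters[["2019"]])
})
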