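test_that("design construction transforms age as specified", {
  r <- norm_recipe("log", c("lnAge", "MPE", "lnAge:MPE"))
  d <- data.frame(age = c(10, 6.5), mpe = c(12, 8), sex = c(0, 1))
  X <- build_design(d, r)
  expect_equal(colnames(X), c("(Intercept)", "lnAge", "MPE", "lnAge:MPE"))
  expect_equal(unname(X[1, "lnAge"]), log(10))
  expect_equal(unname(X[1, "lnAge:MPE"]), log(10) * 12)

  # quadratic family: centred, orthogonal, unit-norm columns
  p <- study_profiles(300, seed = 21)
  q <- norm_recipe("quad", c("Age", "Age2", "MPE"))
  Xq <- build_design(p, q)
  expect_equal(sum(Xq[, "Age"] * Xq[, "Age2"]), 0, tolerance = 1e-10)
  expect_equal(sum(Xq[, "Age"]^2), 1, tolerance = 1e-10)
  expect_equal(sum(Xq[, "Age"]), 0, tolerance = 1e-10)
  # basis is stored and reproduces identical columns on the same data
  r2 <- attr(Xq, "recipe")
  expect_false(is.null(r2$basis))
  expect_equal(build_design(p, r2), Xq, ignore_attr = TRUE)
})

test_that("hierarchy violations are rejected", {
  expect_error(norm_recipe("log", c("lnAge:MPE")), "hierarchy")
  expect_error(norm_recipe("quad", c("Age2", "MPE")), "hierarchy")
  expect_error(norm_recipe("log", c("Age")), "pool")
})

test_that("quad predictions equal raw-polynomial OLS (same column space)", {
  p <- study_profiles(250, seed = 22)
  set.seed(22)
  y <- 0.5 + 0.1 * p$age - 0.003 * p$age^2 + 0.02 * p$mpe + stats::rnorm(250, 0, 0.5)
  m <- fit_norm_model(y, p, norm_recipe("quad", c("Age", "Age2", "MPE")))
  raw <- stats::lm(y ~ age + I(age^2) + mpe, data = p)
  expect_equal(unname(predict(m, p)), unname(stats::fitted(raw)), tolerance = 1e-10)
})

test_that("exhaustive selection recovers the generating subset", {
  hits_cp <- hits_bic <- logical(0)
  for (s in 1:15) {
    p <- study_profiles(668, seed = 3000 + s)
    y <- -3.87 + 1.352 * log(p$age) + 0.053 * p$mpe + stats::rnorm(668, 0, 0.702)
    sel <- exhaustive_select(y, p, "log")
    hits_cp <- c(hits_cp, sel$winner_cp == "lnAge + MPE")
    hits_bic <- c(hits_bic, sel$winner_bic == "lnAge + MPE")
  }
  expect_gte(mean(hits_cp), 0.6)
  expect_gte(mean(hits_bic), 0.85)
})

test_that("Cp of the full model equals its parameter count", {
  p <- study_profiles(400, seed = 31)
  set.seed(31)
  y <- stats::rnorm(400)
  sel <- exhaustive_select(y, p, "log")
  full <- sel$candidates[which.max(sel$candidates$p), ]
  expect_equal(full$cp, full$p, tolerance = 1e-10)
  # adding terms never increases SSE
  ord <- order(sel$candidates$p)
  expect_lte(min(sel$candidates$sse), sel$candidates$sse[ord[1]])
})

test_that("final fits match a pseudo-inverse oracle and handle edge cases", {
  p <- study_profiles(300, seed = 41)
  r <- norm_recipe("log", c("lnAge", "MPE", "lnAge:MPE"))
  set.seed(41)
  y <- -4.64 + 1.742 * log(p$age) - 0.04 * p$mpe + 0.025 * log(p$age) * p$mpe +
    stats::rnorm(300, 0, 0.79)
  m <- fit_norm_model(y, p, r, test_id = "ROCFimm")
  X <- build_design(p, r)
  beta_oracle <- drop(MASS::ginv(X) %*% y)
  expect_equal(unname(coef(m)), beta_oracle, tolerance = 1e-8)
  expect_equal(m$n_train, 300)

  # zero-noise data: R2 = 1 and sigma ~ 0
  y0 <- drop(X %*% c(1, 0.5, 0.02, 0.01))
  m0 <- suppressWarnings(fit_norm_model(y0, p, r))
  expect_equal(m0$r2, 1, tolerance = 1e-10)
  expect_lt(m0$sigma, 1e-10)

  # rank deficiency names the collinear column
  p2 <- p; p2$mpe <- 2 * log(p2$age)
  expect_error(fit_norm_model(y, p2, norm_recipe("log", c("lnAge", "MPE"))),
               "collinear")
})

test_that("coefficient recovery is unbiased on study-sized cohorts", {
  est <- t(vapply(1:20, function(s) {
    p <- study_profiles(668, seed = 5000 + s)
    y <- -3.87 + 1.352 * log(p$age) + 0.053 * p$mpe + stats::rnorm(668, 0, 0.702)
    coef(fit_norm_model(y, p, norm_recipe("log", c("lnAge", "MPE"))))
  }, numeric(3)))
  bias <- colMeans(est) - c(-3.87, 1.352, 0.053)
  mcse <- apply(est, 2, stats::sd) / sqrt(20)
  expect_true(all(abs(bias) < 2.5 * mcse))
})

test_that("repeated cross-validation favours the generating specification", {
  p <- study_profiles(668, seed = 51)
  set.seed(51)
  y <- -3.87 + 1.352 * log(p$age) + 0.053 * p$mpe + stats::rnorm(668, 0, 0.702)
  specs <- list(truth = norm_recipe("log", c("lnAge", "MPE")),
                overfit = norm_recipe("log", c("lnAge", "MPE", "Sex",
                                               "lnAge:MPE", "MPE:Sex")),
                quad = norm_recipe("quad", c("Age", "Age2", "MPE", "Sex")))
  cv <- repeated_cv(specs, y, p, reps = 40, seed = 9)
  expect_equal(names(which.max(cv$win_fraction)), "truth")
  expect_equal(sum(cv$win_fraction), 1)
  # true-model CV error approaches the generating residual SD
  expect_equal(unname(cv$mean_rmse["truth"]), 0.702, tolerance = 0.05 * 0.702)
  # external holdout error is in line with within-CV error
  expect_lt(abs(cv$external_rmse["truth"] - cv$mean_rmse["truth"]),
            0.15 * cv$mean_rmse["truth"])
  # identical specs give identical fold errors under a shared seed
  cv2 <- repeated_cv(specs["truth"], y, p, reps = 5, seed = 13)
  cv3 <- repeated_cv(specs["truth"], y, p, reps = 5, seed = 13)
  expect_identical(cv2$mean_mse, cv3$mean_mse)
  expect_error(repeated_cv(specs, y[1:10], p[1:10, ], k = 10, reps = 2, seed = 1),
               "exceeds")
})

test_that("diagnostics report VIF, influence and residual tests", {
  p <- study_profiles(668, seed = 61)
  set.seed(61)
  y <- -3.87 + 1.352 * log(p$age) + 0.053 * p$mpe + stats::rnorm(668, 0, 0.7)
  m <- fit_norm_model(y, p, norm_recipe("log", c("lnAge", "MPE")))
  d <- norm_diagnostics(m)
  expect_true(all(d$vif >= 1))
  expect_lt(d$max_cooks_d, 1)
  # well-specified homoscedastic Gaussian data: calibrated null tests
  levene_ok <- ks_ok <- logical(0)
  for (s in 1:10) {
    ps <- study_profiles(668, seed = 6100 + s)
    ys <- 1 + 0.5 * log(ps$age) + stats::rnorm(668, 0, 0.5)
    ds <- norm_diagnostics(fit_norm_model(ys, ps, norm_recipe("log", "lnAge")))
    levene_ok <- c(levene_ok, ds$levene_p > 0.05)
    ks_ok <- c(ks_ok, ds$ks_p > 0.05)
  }
  expect_gte(mean(levene_ok), 0.8)
  expect_gte(mean(ks_ok), 0.8)

  # an orthogonal design has unit VIFs; near-duplication blows them up
  po <- study_profiles(400, seed = 62)
  mq <- fit_norm_model(stats::rnorm(400), po, norm_recipe("quad", c("Age", "Age2")))
  expect_equal(unname(norm_diagnostics(mq)$vif), c(1, 1), tolerance = 1e-8)
  pc <- po; pc$mpe <- log(pc$age) + stats::rnorm(400, 0, 0.001)
  mc <- fit_norm_model(stats::rnorm(400), pc, norm_recipe("log", c("lnAge", "MPE")))
  expect_gt(max(norm_diagnostics(mc)$vif), 100)
})
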