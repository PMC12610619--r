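test_that("raw-score recoding follows the instruments' rubrics", {
  expect_equal(unname(recode_svtt(c(1, 0.5, 0))), c(1L, 0L, 0L))
  expect_equal(unname(recode_svtt(rep(1, 5))), rep(1L, 5))
  expect_error(recode_svtt(c(1, 0.75)), "0.75")
  expect_equal(unname(recode_rocf(c(2, 1, 0.5, 0))), c(3L, 2L, 1L, 0L))
  expect_error(recode_rocf(1.5), "1.5")
  # order preserved, matrix shape and item names kept
  m <- matrix(c(0, 0.5, 1, 2), 2, 2, dimnames = list(NULL, c("Item 1", "Item 2")))
  rm <- recode_rocf(m)
  expect_equal(dim(rm), dim(m))
  expect_equal(colnames(rm), colnames(m))
  expect_true(all(order(c(m)) == order(c(rm))))
  bad <- matrix(c(0, 3), 1, 2, dimnames = list(NULL, c("Item 1", "Item 2")))
  expect_error(recode_rocf(bad), "Item 2")
})

test_that("expected ability matches hand-computed linear predictors", {
  svtt <- published_norm_model("svtt")
  # -3.870 + 1.352 ln(10) + 0.053 * 12
  expect_equal(predict(svtt, data.frame(age = 10, mpe = 12)),
               -3.870 + 1.352 * log(10) + 0.053 * 12, tolerance = 1e-10)
  expect_equal(round(predict(svtt, data.frame(age = 10, mpe = 12)), 4), -0.1209)
  recall <- published_norm_model("rocf_recall")
  expect_equal(round(predict(recall, data.frame(age = 10, mpe = 12)), 4), -0.4181)
  # extrapolation warns
  expect_warning(predict(svtt, data.frame(age = 4, mpe = 12)), "extrapolating")
  # the published copy model carries no orthogonal basis: applying it errors
  copy <- published_norm_model("rocf_copy")
  expect_error(predict(copy, data.frame(age = 10, mpe = 12)), "basis")
})

test_that("percentile conversion is a Gaussian CDF transform", {
  m <- published_norm_model("svtt")
  pr50 <- percentile(m, predict(m, data.frame(age = 9, mpe = 10)),
                     data.frame(age = 9, mpe = 10))
  expect_equal(pr50$pr, 50)
  th <- predict(m, data.frame(age = 9, mpe = 10))
  expect_equal(percentile(m, th + 1.645 * m$sigma,
                          data.frame(age = 9, mpe = 10))$pr, 95, tolerance = 0.1)
  expect_equal(percentile(m, th - m$sigma,
                          data.frame(age = 9, mpe = 10))$pr, 15.9, tolerance = 0.05)
  expect_error(percentile(m, Inf, data.frame(age = 9, mpe = 10)), "finite")
  # strictly increasing in theta_obs; round trip recovers the z-score
  prof <- data.frame(age = 12, mpe = 14)
  obs <- seq(-2, 2, 0.25)
  res <- percentile(m, obs, prof)
  expect_true(all(diff(res$pr) > 0))
  expect_equal(stats::qnorm(res$p) * m$sigma + res$theta_hat, obs,
               tolerance = 1e-10)
  # display clamped, raw probability retained
  deep <- percentile(m, res$theta_hat[1] - 6 * m$sigma, prof)
  expect_equal(deep$pr_display, 0.1)
  expect_lt(deep$p, 1e-6)
})

test_that("end-to-end scoring is deterministic and monotone", {
  bank <- published_bank("svtt")
  model <- published_norm_model("svtt")
  prof <- data.frame(age = 10, mpe = 12, sex = 0)
  allmax <- stats::setNames(rep(1, 36), item_ids(bank))
  hi <- score_participant(allmax, bank, model, prof)
  expect_gt(hi$percentile$pr, 50)
  lo <- score_participant(stats::setNames(rep(0, 36), item_ids(bank)),
                          bank, model, prof)
  expect_lt(lo$percentile$pr, hi$percentile$pr)
  # half-credit responses are dichotomised before scoring
  half <- stats::setNames(c(rep(1, 30), rep(0.5, 6)), item_ids(bank))
  none <- stats::setNames(c(rep(1, 30), rep(0, 6)), item_ids(bank))
  expect_equal(score_participant(half, bank, model, prof)$ability$theta,
               score_participant(none, bank, model, prof)$ability$theta)
  # identical inputs give identical outputs
  again <- score_participant(allmax, bank, model, prof)
  expect_identical(hi$percentile$pr, again$percentile$pr)
  # mismatched test ids are refused
  expect_error(score_participant(allmax, bank,
                                 published_norm_model("rocf_recall"), prof),
               "SVTT")
})

test_that("percentiles of a self-generated cohort are uniform (PIT)", {
  co <- simulate_cohort(sim_config(n = 668, tests = "svtt"), seed = 314)
  m <- published_norm_model("svtt")
  res <- percentile(m, co$theta$svtt, co$demographics)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})
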