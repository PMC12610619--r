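test_that("2PL response probability follows the logistic form", {
  # P = 0.5 exactly at theta = b
  it <- item_2pl("Item 36", a = 1.144, b = -0.330)
  expect_equal(prob_2pl(it, -0.330), 0.5)
  # saturation and monotonicity
  it2 <- item_2pl("x", 2, 0)
  expect_equal(prob_2pl(it2, 50), 1, tolerance = 1e-12)
  th <- seq(-6, 6, 0.5)
  expect_true(all(diff(prob_2pl(it2, th)) > 0))
  # direct scalar evaluation of the logistic formula
  expect_equal(prob_2pl(item_2pl("Item 1", 2.130, -3.081), -2.715),
               0.685590, tolerance = 1e-5)
})

test_that("GRM cumulative probabilities respect boundary semantics", {
  it <- item_grm("Item 1", a = 1.824, boundaries = c(-2.506, -1.542, 2.292))
  # P(score >= k) = 0.5 at the k-th boundary
  expect_equal(cum_prob_grm(it, 1, -2.506), 0.5)
  expect_equal(cum_prob_grm(it, 2, -1.542), 0.5)
  # P*(0) = 1 and P*(K) = 0 by definition
  expect_equal(cum_prob_grm(it, 0, 1.7), 1)
  expect_equal(cum_prob_grm(it, 4, 1.7), 0)
  expect_error(cum_prob_grm(it, 5, 0), "out of range")
  # scalar oracle: 1/(1+exp(-1.824*1.542)) at theta = 0, k = 2
  expect_equal(cum_prob_grm(it, 2, 0), 0.943353, tolerance = 1e-5)
  # nonincreasing in k, strictly increasing in theta
  at0 <- vapply(0:4, cum_prob_grm, numeric(1), item = it, theta = 0)
  expect_true(all(diff(at0) <= 0))
  expect_true(all(diff(cum_prob_grm(it, 1, seq(-4, 4, 0.25))) > 0))
})

test_that("GRM category probabilities normalise and telescope", {
  banks <- list(tiny_grm_bank(), published_bank("rocf_copy"),
                published_bank("rocf_recall"))
  th <- seq(-6, 6, 0.2)
  for (bank in banks) {
    for (it in bank$items) {
      p <- cat_probs_grm(it, th)
      expect_true(all(p >= 0))
      expect_equal(rowSums(p), rep(1, length(th)), tolerance = 1e-12)
    }
  }
  # mass collapses into the bottom category as theta -> -Inf
  it <- tiny_grm_bank()$items[[1L]]
  expect_equal(unname(cat_probs_grm(it, -30)[1, 1]), 1, tolerance = 1e-10)
  # category mass k >= 1 equals the first cumulative curve
  it1 <- item_grm("Item 1", 1.824, c(-2.506, -1.542, 2.292))
  p <- cat_probs_grm(it1, -2.506)
  expect_equal(sum(p[1, -1L]), 0.5, tolerance = 1e-12)
})

test_that("item information matches its closed forms", {
  expect_equal(item_information(item_2pl("x", 2, 0), 0), 1)
  # a^2/4 at theta = b for the steepest published command item
  expect_equal(item_information(item_2pl("Item 5", 14.644, -2.715), -2.715),
               53.6117, tolerance = 1e-4)
  # GRM information is a sum of squares over positive masses
  th <- seq(-6, 6, 0.1)
  for (it in published_bank("rocf_recall")$items)
    expect_true(all(item_information(it, th) >= 0))
  # numerical cross-check: I(theta) = -E[d2 loglik] for a 2PL item equals
  # a^2 p (1-p) via central differences of the log-likelihoods
  it <- item_2pl("x", 1.3, 0.4)
  h <- 1e-5
  for (theta in c(-1, 0.4, 2)) {
    p <- function(t) prob_2pl(it, t)
    d2_1 <- (log(p(theta + h)) - 2 * log(p(theta)) + log(p(theta - h))) / h^2
    d2_0 <- (log(1 - p(theta + h)) - 2 * log(1 - p(theta)) + log(1 - p(theta - h))) / h^2
    expect_equal(-(p(theta) * d2_1 + (1 - p(theta)) * d2_0),
                 item_information(it, theta), tolerance = 1e-5)
  }
})

test_that("response log-likelihood matches a cell-by-cell recomputation", {
  bank <- tiny_grm_bank()
  resp <- rbind(c(0L, 3L, 1L), c(2L, NA, 0L), c(NA, NA, NA))
  colnames(resp) <- item_ids(bank)
  thetas <- c(-0.5, 1.2, 0)
  # brute-force oracle: loop every non-missing cell
  oracle <- 0
  for (i in 1:3) for (j in 1:3) {
    if (is.na(resp[i, j])) next
    oracle <- oracle + log(cat_probs_grm(bank$items[[j]], thetas[i])[1, resp[i, j] + 1L])
  }
  expect_equal(response_loglik(bank, resp, thetas), unname(oracle), tolerance = 1e-12)
  # all-missing matrix contributes zero
  allna <- matrix(NA_integer_, 2, 3, dimnames = list(NULL, item_ids(bank)))
  expect_equal(response_loglik(bank, allna, c(0, 0)), 0)
  # single correct 2PL response at theta = b gives log(0.5)
  b1 <- item_bank(list(item_2pl("Item 1", 1.5, 0.7)), c(0, 1))
  expect_equal(response_loglik(b1, matrix(1L, 1, 1, dimnames = list(NULL, "Item 1")), 0.7),
               log(0.5))
  # out-of-range codes are rejected with the offender named
  bad <- matrix(c(5L, 0L, 1L), 1, dimnames = list("P1", item_ids(bank)))
  expect_error(response_loglik(bank, bad, 0), "Item 1")
})
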