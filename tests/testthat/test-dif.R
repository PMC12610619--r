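test_that("null items stay unflagged and delta-R2 shrinks with n", {
  dr_small <- dr_big <- flags <- numeric(0)
  for (s in 1:15) {
    set.seed(700 + s)
    for (n in c(300, 1200)) {
      th <- stats::rnorm(n); grp <- stats::rbinom(n, 1, 0.5)
      y <- as.integer(stats::runif(n) < stats::plogis(1.5 * th))
      d <- dif_item(y, th, grp)
      if (n == 300) dr_small <- c(dr_small, d$delta_r2[["nagelkerke"]])
      else { dr_big <- c(dr_big, d$delta_r2[["nagelkerke"]]); flags <- c(flags, d$flagged) }
    }
  }
  expect_lte(mean(flags), 0.05)
  expect_lt(mean(dr_big), mean(dr_small))       # converges to 0 in probability
  expect_true(all(dr_big >= 0))
})

test_that("an injected difficulty shift is detected with high power", {
  flags <- numeric(0)
  for (s in 1:15) {
    set.seed(800 + s)
    n <- 600
    th <- stats::rnorm(n); grp <- stats::rbinom(n, 1, 0.5)
    y <- as.integer(stats::runif(n) < stats::plogis(1.5 * (th - ifelse(grp == 1, 1, 0))))
    flags <- c(flags, dif_item(y, th, grp)$flagged)
  }
  expect_gte(mean(flags), 0.8)
})

test_that("flag decisions are invariant to group label swapping", {
  set.seed(900)
  n <- 500
  th <- stats::rnorm(n); grp <- stats::rbinom(n, 1, 0.5)
  y <- as.integer(stats::runif(n) < stats::plogis(th - 0.5 * grp))
  d1 <- dif_item(y, th, grp)
  d2 <- dif_item(y, th, 1 - grp)
  expect_equal(d1$flagged, d2$flagged)
  expect_equal(unname(d1$delta_r2), unname(d2$delta_r2), tolerance = 1e-4)
})

test_that("polytomous items go through the proportional-odds route", {
  set.seed(901)
  n <- 500
  th <- stats::rnorm(n); grp <- stats::rbinom(n, 1, 0.5)
  it <- item_grm("x", 1.6, c(-1, 0, 1))
  y <- vapply(seq_len(n), function(i)
    sum(stats::runif(1) >= cumsum(cat_probs_grm(it, th[i])[1, ])[1:3]), integer(1))
  d <- dif_item(y, th, grp)
  expect_s3_class(d, "dif_result")
  expect_false(d$flagged)
  expect_true(all(d$r2[, "nagelkerke"] <= 1))
  # single-category item errors
  expect_error(dif_item(rep(1L, n), th, grp, item_id = "flat"), "flat")
})

test_that("purification keeps clean banks clean and isolates a contaminated item", {
  bank <- published_bank("rocf_copy")
  set.seed(910)
  n <- 500
  th <- stats::rnorm(n); grp0 <- stats::rbinom(n, 1, 0.5)
  clean <- simulate_responses(bank, th)
  sc <- dif_purify(clean, bank, grp0)
  expect_length(sc$flagged, 0)
  expect_true(sc$converged)
  expect_equal(sc$iterations, 0L)    # stable at the first pass

  # one contaminated item out of 18
  hits <- spurious <- numeric(0)
  for (s in 1:3) {
    set.seed(920 + s)
    th <- stats::rnorm(600); grp <- stats::rbinom(600, 1, 0.5)
    pair <- inject_dif(bank, "Item 7", 1.0)
    resp <- simulate_responses(pair$reference, th)
    focal <- simulate_responses(pair$focal, th)
    resp[grp == 1, ] <- focal[grp == 1, ]
    sc <- dif_purify(resp, bank, grp)
    hits <- c(hits, "Item 7" %in% sc$flagged)
    spurious <- c(spurious, length(setdiff(sc$flagged, "Item 7")))
  }
  expect_gte(mean(hits), 2 / 3)
  expect_lte(mean(spurious), 1)

  # max_iter = 0 returns the unpurified pass verbatim
  sc0 <- dif_purify(clean, bank, grp0, max_iter = 0)
  expect_equal(sc0$iterations, 0L)
  expect_length(sc0$results, 18)
  df <- as.data.frame(sc0)
  expect_named(df, c("item_id", "delta_r2_mcfadden", "delta_r2_coxsnell",
                     "delta_r2_nagelkerke", "p_uniform", "p_nonuniform",
                     "flagged"))
})

test_that("per-group calibration aligns parameters and recovers a shift", {
  bank <- tiny_2pl_bank()
  set.seed(930)
  n <- 1600
  th <- stats::rnorm(n); grp <- rep(0:1, each = n / 2)
  pair <- inject_dif(bank, "Item 3", 0.8)
  resp <- simulate_responses(pair$reference, th)
  focal <- simulate_responses(pair$focal, th)
  resp[grp == 1, ] <- focal[grp == 1, ]
  gp <- group_item_params(resp, "2PL", grp)
  expect_named(gp$fits, c("0", "1"))
  expect_equal(gp$table$id, item_ids(bank))
  shift_hat <- gp$table[gp$table$id == "Item 3", "b.1"] -
    gp$table[gp$table$id == "Item 3", "b.0"]
  expect_equal(shift_hat, 0.8, tolerance = 0.35)
})
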