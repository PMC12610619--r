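# Small banks and simulators shared across test files.

tiny_2pl_bank <- function(a = c(1.2, 0.8, 1.5, 1.0, 2.0),
                          b = c(-1, -0.5, 0, 0.5, 1)) {
  item_bank(mapply(function(aa, bb, i) item_2pl(paste("Item", i), aa, bb),
                   a, b, seq_along(a), SIMPLIFY = FALSE),
            category_values = c(0, 1))
}

tiny_grm_bank <- function() {
  item_bank(list(item_grm("Item 1", 1.8, c(-1.5, 0, 1.5)),
                 item_grm("Item 2", 1.2, c(-1, 0.5, 2)),
                 item_grm("Item 3", 2.5, c(-2, -0.5, 1))),
            category_values = c(0, 0.5, 1, 2))
}

# one-factor ordinal data: x_j = cut(lambda f + sqrt(1-lambda^2) e)
sim_one_factor_ordinal <- function(n, p, lambda, cuts = c(-0.8, 0.2, 1.0)) {
  f <- stats::rnorm(n)
  y <- vapply(seq_len(p), function(j) {
    x <- lambda * f + sqrt(1 - lambda^2) * stats::rnorm(n)
    as.integer(cut(x, c(-Inf, cuts, Inf))) - 1L
  }, integer(n))
  colnames(y) <- paste0("it", seq_len(p))
  y
}

study_profiles <- function(n, seed) {
  set.seed(seed)
  data.frame(age = stats::runif(n, 6, 17.99),
             mpe = pmin(pmax(stats::rnorm(n, 12.15, 3.62), 0), 22),
             sex = stats::rbinom(n, 1, 0.542))
}
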