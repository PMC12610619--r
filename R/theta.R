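#' Quadrature grid for a standard-normal latent trait
#'
#' Equally spaced nodes with standard-normal weights renormalised to sum to
#' one; the default (61 nodes on `[-6, 6]`) is used throughout calibration
#' and EAP scoring.
#'
#' @param n_nodes Number of nodes.
#' @param range Node range `c(lo, hi)`.
#' @return List with `nodes` and `weights`, class `quadrature_grid`.
#' @export
quadrature_grid <- function(n_nodes = 61L, range = c(-6, 6)) {
  stopifnot(n_nodes >= 3L, range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "quadrature_grid")
}

# Per-item log category probabilities at the nodes: list over categories k
# of items x nodes matrices (rows of unused categories stay 0 and are never
# touched by a legal response).
logprob_at_nodes <- function(bank, nodes) {
  p <- length(bank$items)
  K <- n_categories(bank)
  lp <- lapply(seq_len(max(K)), function(k) matrix(0, p, length(nodes)))
  for (j in seq_len(p)) {
    pm <- if (bank$model == "2PL") {
      pr <- prob_2pl(bank$items[[j]], nodes)
      # clamp away exact 0/1 so that 0-indicator x (-Inf) never yields NaN
      rbind(log(pmax(1 - pr, .Machine$double.xmin)),
            log(pmax(pr, .Machine$double.xmin)))
    } else {
      t(log(pmax(cat_probs_grm(bank$items[[j]], nodes), .Machine$double.xmin)))
    }
    for (k in seq_len(K[j])) lp[[k]][j, ] <- pm[k, ]
  }
  lp
}

# 0/1 indicator matrices (persons x items), one per category.
category_indicators <- function(responses, n_cat) {
  lapply(seq_len(n_cat) - 1L, function(k) {
    ik <- !is.na(responses) & responses == k
    storage.mode(ik) <- "double"
    ik
  })
}

# Per-person log-likelihood at each quadrature node: persons x nodes matrix,
# accumulated with one indicator-matrix product per category.
loglik_at_nodes <- function(bank, responses, nodes) {
  lp <- logprob_at_nodes(bank, nodes)
  ind <- category_indicators(responses, length(lp))
  ll <- matrix(0, nrow(responses), length(nodes))
  for (k in seq_along(lp)) ll <- ll + ind[[k]] %*% lp[[k]]
  ll
}

#' Ability estimation
#'
#' Estimate each person's latent trait from a calibrated item bank.
#' `"EAP"` (the default) is the posterior mean under a standard-normal
#' prior, computed on a quadrature grid, with the posterior standard
#' deviation as its standard error. `"MAP"` is the posterior mode, `"ML"`
#' the maximum of the conditional likelihood; both use observed-information
#' standard errors. Persons with no scorable responses receive the prior
#' mean (theta 0, SE 1) and flag `"no_responses"`; all-minimum or
#' all-maximum patterns, for which the ML estimate diverges, fall back to
#' MAP with flag `"extreme_pattern"`.
#'
#' @param responses Persons x items matrix of ordinal codes (`NA` missing).
#' @param bank An [item_bank()] covering the columns.
#' @param method `"EAP"`, `"MAP"` or `"ML"`.
#' @param grid A [quadrature_grid()].
#' @return A data frame of class `ability_estimates` with columns
#'   `person_id`, `theta`, `se`, `method`, `flag`.
#' @export
estimate_theta <- function(responses, bank,
                           method = c("EAP", "MAP", "ML"),
                           grid = quadrature_grid()) {
  method <- match.arg(method)
  responses <- as_response_matrix(responses, bank)
  n <- nrow(responses)
  ids <- if (is.null(rownames(responses))) as.character(seq_len(n)) else rownames(responses)
  n_obs <- rowSums(!is.na(responses))
  kmax <- matrix(rep(n_categories(bank) - 1L, each = n), n)
  all_min <- rowSums(responses == 0L, na.rm = TRUE) == n_obs
  all_max <- rowSums(responses == kmax, na.rm = TRUE) == n_obs

  ll <- loglik_at_nodes(bank, responses, grid$nodes)
  lpost <- sweep(ll, 2L, log(grid$weights), `+`)
  lpost <- lpost - apply(lpost, 1L, max)
  post <- exp(lpost)
  post <- post / rowSums(post)

  theta <- se <- numeric(n)
  flag <- character(n)
  if (method == "EAP") {
    theta <- as.numeric(post %*% grid$nodes)
    se <- sqrt(pmax(as.numeric(post %*% grid$nodes^2) - theta^2, 0))
  } else {
    rng <- range(grid$nodes)
    for (i in seq_len(n)) {
      if (n_obs[i] == 0L) next
      ri <- responses[i, , drop = FALSE]
      use_map <- method == "MAP" || (method == "ML" && (all_min[i] || all_max[i]))
      f <- if (use_map) {
        function(t) response_loglik(bank, ri, t) + stats::dnorm(t, log = TRUE)
      } else {
        function(t) response_loglik(bank, ri, t)
      }
      opt <- stats::optimize(f, rng, maximum = TRUE, tol = 1e-7)
      theta[i] <- opt$maximum
      h <- 1e-4
      d2 <- (f(theta[i] + h) - 2 * f(theta[i]) + f(theta[i] - h)) / h^2
      se[i] <- if (d2 < 0) 1 / sqrt(-d2) else NA_real_
      if (method == "ML" && use_map) flag[i] <- "extreme_pattern"
    }
  }
  if (any(n_obs == 0L)) {
    warning(sum(n_obs == 0L), " person(s) with no scorable responses; ",
            "returning the prior mean")
    theta[n_obs == 0L] <- 0
    se[n_obs == 0L] <- 1
    flag[n_obs == 0L] <- "no_responses"
  }
  structure(data.frame(person_id = ids, theta = theta, se = se,
                       method = method, flag = flag,
                       stringsAsFactors = FALSE),
            class = c("ability_estimates", "data.frame"))
}
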