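#' Control parameters for MML-EM calibration
#'
#' @param tol Convergence tolerance on the maximum absolute parameter
#'   change between cycles.
#' @param max_cycles Maximum number of EM cycles.
#' @param n_nodes,theta_range Quadrature grid (standard-normal prior).
#' @param a_bounds Allowed discrimination range; the upper bound
#'   accommodates near-Guttman items while preventing divergence.
#' @return A list of class `calib_control`.
#' @export
calib_control <- function(tol = 1e-4, max_cycles = 500L,
                          n_nodes = 61L, theta_range = c(-6, 6),
                          a_bounds = c(0.02, 25)) {
  stopifnot(tol > 0, max_cycles >= 1L, a_bounds[1] > 0, a_bounds[1] < a_bounds[2])
  structure(list(tol = tol, max_cycles = as.integer(max_cycles),
                 n_nodes = as.integer(n_nodes), theta_range = theta_range,
                 a_bounds = a_bounds),
            class = "calib_control")
}

#' Calibrate item parameters by marginal maximum likelihood EM
#'
#' Bock-Aitkin MML-EM under a standard-normal latent-trait prior: the
#' E-step places posterior mass for each person on a fixed quadrature grid;
#' the M-step refits each item on the expected category counts at the
#' nodes (Newton logistic regression for the 2PL, bounded quasi-Newton
#' maximisation of the graded-response likelihood for the GRM). The
#' marginal log-likelihood is nondecreasing across cycles and its trace is
#' kept in the result.
#'
#' Items observed in fewer than two categories are unidentifiable and are
#' dropped with a message; fewer than 3 items or 50 persons triggers a
#' warning, not an error.
#'
#' @param responses Persons x items matrix of ordinal codes (`NA` missing);
#'   column names become item ids.
#' @param model `"2PL"` (binary codes) or `"GRM"` (ordered codes).
#' @param category_values Raw score values attached to the returned bank
#'   (defaults to `0:(K-1)`).
#' @param control A [calib_control()].
#' @return An object of class `irt_calibration` with fields `bank`,
#'   `loglik`, `loglik_trace`, `n_cycles`, `converged`, `dropped_items`,
#'   `n_persons`. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `predict` (ability estimation for new response matrices), `plot`
#'   (test information of the estimated bank).
#' @export
irt_calibrate <- function(responses, model = c("2PL", "GRM"),
                          category_values = NULL, control = calib_control()) {
  model <- match.arg(model)
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) stop("responses must be numeric ordinal codes")
  if (any(responses[!is.na(responses)] %% 1 != 0) || any(responses < 0, na.rm = TRUE))
    stop("responses must be nonnegative integer codes")
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses)))
    colnames(responses) <- paste("Item", seq_len(ncol(responses)))
  if (model == "2PL" && any(responses > 1L, na.rm = TRUE))
    stop("2PL calibration requires binary codes; found codes > 1")

  # drop unidentifiable items (fewer than 2 observed categories)
  n_cat_obs <- apply(responses, 2L, function(x) length(unique(x[!is.na(x)])))
  dropped <- colnames(responses)[n_cat_obs < 2L]
  if (length(dropped)) {
    message("dropping ", length(dropped), " item(s) with a single observed category: ",
            paste(dropped, collapse = ", "))
    responses <- responses[, n_cat_obs >= 2L, drop = FALSE]
  }
  if (ncol(responses) == 0L) stop("no calibratable items: every item is constant")
  if (ncol(responses) < 3L) warning("fewer than 3 items; estimates will be unstable")
  if (nrow(responses) < 50L) warning("fewer than 50 persons; estimates will be unstable")

  # collapse categories never observed for an item to consecutive codes
  # (a graded item is only identified on its observed categories)
  if (model == "GRM") {
    collapsed <- character(0)
    for (j in seq_len(ncol(responses))) {
      lev <- sort(unique(responses[!is.na(responses[, j]), j]))
      if (!identical(lev, seq_along(lev) - 1L)) {
        responses[, j] <- match(responses[, j], lev) - 1L
        collapsed <- c(collapsed, colnames(responses)[j])
      }
    }
    if (length(collapsed))
      message("collapsed unobserved categories for: ",
              paste(collapsed, collapse = ", "))
  }
  K <- if (model == "2PL") rep(2L, ncol(responses)) else
    apply(responses, 2L, max, na.rm = TRUE) + 1L
  if (model == "GRM" && any(K < 2L)) stop("GRM items need at least 2 categories")
  grid <- quadrature_grid(control$n_nodes, control$theta_range)

  # start values from marginal proportions
  items <- vector("list", ncol(responses))
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    if (model == "2PL") {
      p <- mean(x, na.rm = TRUE)
      items[[j]] <- item_2pl(colnames(responses)[j], a = 1,
                             b = -stats::qlogis(min(max(p, 0.02), 0.98)))
    } else {
      cum <- rev(cumsum(rev(tabulate(x + 1L, K[j]) / sum(!is.na(x)))))[-1L]
      b0 <- -stats::qlogis(pmin(pmax(cum, 0.02), 0.98))
      items[[j]] <- item_grm(colnames(responses)[j], a = 1,
                             boundaries = cummax(b0 + seq_along(b0) * 1e-6))
    }
  }
  cv <- if (!is.null(category_values)) category_values else 0:(max(K) - 1L)
  bank <- item_bank(items, cv)

  ind <- category_indicators(responses, max(K))     # fixed across cycles
  trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(control$max_cycles)) {
    cycles <- cycle
    # E-step
    lp <- logprob_at_nodes(bank, grid$nodes)
    ll <- matrix(0, nrow(responses), length(grid$nodes))
    for (k in seq_along(lp)) ll <- ll + ind[[k]] %*% lp[[k]]
    lpost <- sweep(ll, 2L, log(grid$weights), `+`)
    m <- apply(lpost, 1L, max)
    marg <- m + log(rowSums(exp(lpost - m)))
    trace <- c(trace, sum(marg))
    post <- exp(lpost - marg)                        # persons x Q
    # expected category counts at the nodes: items x Q per category
    counts <- lapply(ind, function(ik) crossprod(ik, post))

    # M-step, item by item on expected counts
    old <- unlist(lapply(bank$items, function(it)
      c(it$a, if (bank$model == "2PL") it$b else it$boundaries)))
    for (j in seq_len(ncol(responses))) {
      if (bank$model == "2PL") {
        rq <- counts[[2L]][j, ]
        nq <- counts[[1L]][j, ] + rq
        bank$items[[j]] <- mstep_2pl(bank$items[[j]], grid$nodes, rq, nq,
                                     control$a_bounds)
      } else {
        rk <- vapply(seq_len(K[j]), function(k) counts[[k]][j, ],
                     numeric(length(grid$nodes)))    # Q x K
        bank$items[[j]] <- mstep_grm(bank$items[[j]], grid$nodes, rk,
                                     control$a_bounds)
      }
    }
    new <- unlist(lapply(bank$items, function(it)
      c(it$a, if (bank$model == "2PL") it$b else it$boundaries)))
    if (max(abs(new - old)) < control$tol) { converged <- TRUE; break }
  }
  # final marginal log-likelihood at the converged parameters
  ll <- loglik_at_nodes(bank, responses, grid$nodes)
  lpost <- sweep(ll, 2L, log(grid$weights), `+`)
  m <- apply(lpost, 1L, max)
  marg <- m + log(rowSums(exp(lpost - m)))
  final_ll <- sum(marg)
  trace <- c(trace, final_ll)
  post <- exp(lpost - marg)

  # Empirical-Fisher standard errors (2PL): by Fisher's identity the
  # per-person score of the marginal likelihood is the posterior
  # expectation of the complete-data score; the information matrix is
  # approximated by the sum of score cross-products.
  se_params <- NULL
  if (model == "2PL") {
    np <- nrow(responses)
    G <- matrix(0, np, 2L * ncol(responses))
    for (j in seq_len(ncol(responses))) {
      it <- bank$items[[j]]
      pq <- prob_2pl(it, grid$nodes)
      x <- responses[, j]
      obs <- which(!is.na(x))
      pj <- post[obs, , drop = FALSE]
      e_p <- as.numeric(pj %*% pq)                          # E_post p(theta)
      e_t <- as.numeric(pj %*% (grid$nodes - it$b))         # E_post (theta-b)
      e_pt <- as.numeric(pj %*% (pq * (grid$nodes - it$b))) # E_post p(theta)(theta-b)
      G[obs, 2L * j - 1L] <- x[obs] * e_t - e_pt            # d/da
      G[obs, 2L * j] <- -it$a * (x[obs] - e_p)              # d/db
    }
    info <- crossprod(G)
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(G)))
    se_params <- data.frame(id = item_ids(bank),
                            se_a = se[seq(1L, length(se), by = 2L)],
                            se_b = se[seq(2L, length(se), by = 2L)])
  }

  structure(list(bank = bank, loglik = final_ll, loglik_trace = trace,
                 n_cycles = cycles, converged = converged,
                 dropped_items = dropped, n_persons = nrow(responses),
                 se_params = se_params, control = control),
            class = "irt_calibration")
}

# Newton logistic regression of expected correct counts rq out of nq on the
# quadrature nodes; slope-intercept parameterisation, difficulty b = -c/a.
mstep_2pl <- function(item, nodes, rq, nq, a_bounds) {
  a <- item$a; cc <- -item$a * item$b
  for (iter in 1:50) {
    p <- stats::plogis(a * nodes + cc)
    g <- c(sum((rq - nq * p) * nodes), sum(rq - nq * p))
    w <- nq * p * (1 - p)
    H <- -rbind(c(sum(w * nodes^2), sum(w * nodes)),
                c(sum(w * nodes),   sum(w)))
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    # damped Newton with bound clamping
    lam <- 1
    f0 <- sum(rq * log(pmax(p, 1e-300)) + (nq - rq) * log(pmax(1 - p, 1e-300)))
    repeat {
      a1 <- min(max(a - lam * step[1], a_bounds[1]), a_bounds[2])
      c1 <- cc - lam * step[2]
      p1 <- stats::plogis(a1 * nodes + c1)
      f1 <- sum(rq * log(pmax(p1, 1e-300)) + (nq - rq) * log(pmax(1 - p1, 1e-300)))
      if (f1 >= f0 - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    moved <- max(abs(c(a1 - a, c1 - cc)))
    a <- a1; cc <- c1
    if (moved < 1e-8) break
  }
  item_2pl(item$id, a = a, b = -cc / a)
}

# Bounded quasi-Newton maximisation of the expected GRM log-likelihood for
# one item; ordering kept by optimising (a, b1, gaps >= 0).
mstep_grm <- function(item, nodes, rk, a_bounds) {
  nb <- length(item$boundaries)
  par0 <- c(item$a, item$boundaries[1L],
            if (nb > 1) pmax(diff(item$boundaries), 1e-6))
  negq <- function(par) {
    a <- par[1L]
    b <- par[2L] + cumsum(c(0, par[-(1:2)]))
    cum <- cbind(1, stats::plogis(outer(nodes, b, function(t, bb) a * (t - bb))), 0)
    pk <- pmax(cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE],
               .Machine$double.xmin)
    -sum(rk * log(pk))
  }
  opt <- stats::optim(par0, negq, method = "L-BFGS-B",
                      lower = c(a_bounds[1], -30, rep(1e-6, nb - 1L)),
                      upper = c(a_bounds[2], 30, rep(Inf, nb - 1L)),
                      control = list(maxit = 30L))
  # generalized EM: keep the better of old and new point
  par <- if (opt$value <= negq(par0)) opt$par else par0
  item_grm(item$id, a = par[1L],
           boundaries = par[2L] + cumsum(c(0, par[-(1:2)])))
}

#' @export
print.irt_calibration <- function(x, ...) {
  cat(sprintf("<irt_calibration> %s, %d items, %d persons\n",
              x$bank$model, length(x$bank$items), x$n_persons))
  cat(sprintf("  logLik %.3f after %d EM cycle(s); %s\n", x$loglik, x$n_cycles,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$dropped_items))
    cat("  dropped:", paste(x$dropped_items, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.irt_calibration <- function(object, ...) {
  df <- as.data.frame(object$bank)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' @export
logLik.irt_calibration <- function(object, ...) {
  p_per_item <- if (object$bank$model == "2PL") 2L else
    length(object$bank$category_values)
  structure(object$loglik, df = p_per_item * length(object$bank$items),
            nobs = object$n_persons, class = "logLik")
}

#' @export
summary.irt_calibration <- function(object, ...) {
  out <- list(model = object$bank$model, params = coef(object),
              loglik = object$loglik, n_cycles = object$n_cycles,
              converged = object$converged, n_persons = object$n_persons)
  class(out) <- "summary.irt_calibration"
  out
}

#' @export
print.summary.irt_calibration <- function(x, ...) {
  cat(sprintf("%s calibration of %d items on %d persons\n", x$model,
              nrow(x$params), x$n_persons))
  cat(sprintf("logLik %.3f, %d EM cycles, converged: %s\n\n", x$loglik,
              x$n_cycles, x$converged))
  print(round(x$params, 3))
  invisible(x)
}

#' Score new responses with a calibrated model
#'
#' @param object An `irt_calibration`.
#' @param newdata Persons x items response matrix.
#' @param method Ability estimator, see [estimate_theta()].
#' @param ... Unused.
#' @return An `ability_estimates` data frame.
#' @export
predict.irt_calibration <- function(object, newdata,
                                    method = c("EAP", "MAP", "ML"), ...) {
  estimate_theta(newdata, object$bank, method = match.arg(method),
                 grid = quadrature_grid(object$control$n_nodes,
                                        object$control$theta_range))
}

#' @export
plot.irt_calibration <- function(x, ...) {
  plot(test_information(x$bank), ...)
}
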