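# Pseudo-R-squared set from fitted/null log-likelihoods.
pseudo_r2 <- function(ll_model, ll_null, n) {
  mcfadden <- 1 - ll_model / ll_null
  coxsnell <- 1 - exp(2 * (ll_null - ll_model) / n)
  c(mcfadden = mcfadden, coxsnell = coxsnell,
    nagelkerke = coxsnell / (1 - exp(2 * ll_null / n)))
}

# Fit one ordinal (proportional-odds) or binary logistic model; returns
# logLik, df and a divergence flag. Falls back to an in-package
# ridge-penalised fit of the same likelihood when the ML fit fails or
# separates (runaway coefficients).
fit_dif_model <- function(y, X) {
  n <- length(y)
  K <- nlevels(y)
  fit <- tryCatch({
    if (K == 2L) {
      m <- suppressWarnings(stats::glm.fit(cbind(1, X), as.integer(y) - 1L,
                                           family = stats::binomial()))
      eta <- drop(cbind(1, X) %*% m$coefficients)
      mu <- stats::plogis(eta)
      list(ll = sum(ifelse(as.integer(y) == 2L, log(mu), log1p(-mu))),
           coefs = m$coefficients[-1L], df = length(m$coefficients))
    } else {
      dat <- data.frame(y = y, X)
      m <- suppressWarnings(MASS::polr(y ~ ., data = dat, Hess = FALSE))
      list(ll = as.numeric(stats::logLik(m)), coefs = stats::coef(m),
           df = length(stats::coef(m)) + K - 1L)
    }
  }, error = function(e) NULL)
  diverged <- is.null(fit) || any(!is.finite(fit$coefs)) || any(abs(fit$coefs) > 15)
  if (diverged) {
    fit <- fit_po_penalized(y, X, lambda = 1e-3)
    warning("quasi-separation in a DIF model; using a ridge-penalised fit")
    fit$penalized <- TRUE
  } else fit$penalized <- FALSE
  fit
}

# Proportional-odds likelihood (binary as K = 2) with an optional ridge
# penalty on the slopes; cutpoints ordered via log-gap parameterisation.
fit_po_penalized <- function(y, X, lambda = 0) {
  X <- as.matrix(X)
  n <- length(y); K <- nlevels(y); q <- ncol(X)
  yi <- as.integer(y)
  beta_idx <- if (q > 0L) (K - 1L) + seq_len(q) else integer(0)
  negll <- function(par) {
    zeta <- cumsum(c(par[1L], exp(par[seq_len(K - 2L) + 1L])))
    eta <- if (q > 0L) drop(X %*% par[beta_idx]) else 0
    upper <- c(-Inf, zeta, Inf)
    pr <- stats::plogis(upper[yi + 1L] - eta) - stats::plogis(upper[yi] - eta)
    -sum(log(pmax(pr, 1e-300))) + lambda * sum(par[beta_idx]^2)
  }
  # starting cutpoints as (first, log-gaps) from the marginal proportions
  z0 <- stats::qlogis(pmin(pmax(cumsum(tabulate(yi, K))[-K] / n, 1e-3), 1 - 1e-3))
  par0 <- c(z0[1L], if (K > 2L) log(pmax(diff(z0), 1e-3)), rep(0, q))
  opt <- stats::optim(par0, negll, method = "BFGS", control = list(maxit = 500L))
  list(ll = -(opt$value), coefs = opt$par[beta_idx], df = K - 1L + q)
}

#' Differential item functioning for one item
#'
#' Ability-anchored logistic DIF screening: with the matching ability
#' `theta` in hand, fit the nested models `M0: response ~ theta`,
#' `M1: + group`, `M2: + theta x group` (binary logistic for dichotomous
#' items, proportional odds for polytomous ones). The effect size is the
#' incremental pseudo-R-squared `delta_r2 = R2(M2) - R2(M0)` in McFadden,
#' Cox-Snell and Nagelkerke flavours; an item is flagged when the
#' Nagelkerke increment reaches `threshold` (default 0.035, the
#' conventional moderate cutoff). Likelihood-ratio p-values for uniform
#' (M1 vs M0) and non-uniform (M2 vs M1) DIF are reported alongside.
#'
#' @param item_responses Ordinal response vector for one item (`NA`
#'   allowed).
#' @param theta Matching ability estimates, same length.
#' @param group Two-level factor (or coercible) of group membership.
#' @param threshold Nagelkerke delta-R2 flag threshold.
#' @param item_id Label used in the result.
#' @return An object of class `dif_result`.
#' @export
dif_item <- function(item_responses, theta, group, threshold = 0.035,
                     item_id = "item") {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (length(item_responses) != length(theta) ||
      length(item_responses) != length(group))
    stop("item_responses, theta and group must have equal lengths")
  ok <- !is.na(item_responses) & !is.na(theta) & !is.na(group)
  y <- factor(item_responses[ok], levels = sort(unique(item_responses[ok])),
              ordered = TRUE)
  if (nlevels(y) < 2L) stop("item ", item_id, " has a single observed category")
  th <- theta[ok]; g <- as.numeric(group[ok] == levels(group)[2L])
  if (min(table(group[ok])) < 25L)
    warning("fewer than 25 persons in a group for item ", item_id)
  n <- length(y)

  m_null <- fit_po_penalized(y, matrix(0, n, 0))   # intercepts only
  m0 <- fit_dif_model(y, cbind(theta = th))
  m1 <- fit_dif_model(y, cbind(theta = th, group = g))
  m2 <- fit_dif_model(y, cbind(theta = th, group = g, `theta:group` = th * g))
  # nesting can be violated numerically; enforce monotone fit
  ll0 <- m0$ll; ll1 <- max(m1$ll, ll0); ll2 <- max(m2$ll, ll1)

  r2 <- rbind(M0 = pseudo_r2(ll0, m_null$ll, n),
              M1 = pseudo_r2(ll1, m_null$ll, n),
              M2 = pseudo_r2(ll2, m_null$ll, n))
  delta <- pmax(r2["M2", ] - r2["M0", ], 0)
  lr <- c(uniform = stats::pchisq(2 * (ll1 - ll0), 1, lower.tail = FALSE),
          nonuniform = stats::pchisq(2 * (ll2 - ll1), 1, lower.tail = FALSE),
          overall = stats::pchisq(2 * (ll2 - ll0), 2, lower.tail = FALSE))
  structure(list(item_id = item_id, delta_r2 = delta, r2 = r2,
                 lr_pvalues = lr, threshold = threshold,
                 flagged = unname(delta["nagelkerke"] >= threshold),
                 n = n,
                 penalized = any(m0$penalized, m1$penalized, m2$penalized)),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  cat(sprintf("<dif_result> %s: delta-R2 (Nagelkerke) = %.4f [%s]\n",
              x$item_id, x$delta_r2["nagelkerke"],
              if (x$flagged) "FLAGGED" else "ok"))
  invisible(x)
}

#' DIF screening with iterative purification
#'
#' Runs [dif_item()] for every item of a response matrix, re-estimating the
#' matching EAP ability from the currently unflagged (anchor) items until
#' the flagged set stabilises or `max_iter` passes are exhausted. With
#' `max_iter = 0` a single un-purified pass (all items as anchors) is
#' returned.
#'
#' @param responses Persons x items matrix of ordinal codes.
#' @param bank Pooled-calibration [item_bank()] for the matching ability.
#' @param group Two-level group factor, one entry per person.
#' @param max_iter Maximum purification passes (default 10).
#' @param threshold Nagelkerke delta-R2 flag threshold.
#' @return An object of class `dif_screen`: per-item results, final
#'   flagged ids, iteration count and convergence indicator.
#' @export
dif_purify <- function(responses, bank, group, max_iter = 10L,
                       threshold = 0.035) {
  responses <- as_response_matrix(responses, bank)
  ids <- item_ids(bank)
  flagged <- character(0)
  run_pass <- function(anchors) {
    keep <- ids %in% anchors
    theta <- estimate_theta(responses[, keep, drop = FALSE],
                            item_bank(bank$items[keep], bank$category_values),
                            method = "EAP")$theta
    lapply(seq_along(ids), function(j)
      dif_item(responses[, j], theta, group, threshold = threshold,
               item_id = ids[j]))
  }
  results <- run_pass(ids)
  flagged <- ids[vapply(results, `[[`, logical(1), "flagged")]
  iterations <- 0L
  converged <- length(flagged) == 0L || max_iter == 0L
  while (!converged && iterations < max_iter) {
    iterations <- iterations + 1L
    anchors <- setdiff(ids, flagged)
    if (length(anchors) == 0L)
      stop("all items flagged for DIF: no anchor set remains")
    results <- run_pass(anchors)
    new_flagged <- ids[vapply(results, `[[`, logical(1), "flagged")]
    if (setequal(new_flagged, flagged)) converged <- TRUE
    flagged <- new_flagged
  }
  names(results) <- ids
  structure(list(results = results, flagged = flagged,
                 iterations = iterations, converged = converged,
                 threshold = threshold),
            class = "dif_screen")
}

#' @export
print.dif_screen <- function(x, ...) {
  cat(sprintf("<dif_screen> %d items, %d purification pass(es)%s\n",
              length(x$results), x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat("  flagged:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
as.data.frame.dif_screen <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r)
    data.frame(item_id = r$item_id,
               delta_r2_mcfadden = r$delta_r2[["mcfadden"]],
               delta_r2_coxsnell = r$delta_r2[["coxsnell"]],
               delta_r2_nagelkerke = r$delta_r2[["nagelkerke"]],
               p_uniform = r$lr_pvalues[["uniform"]],
               p_nonuniform = r$lr_pvalues[["nonuniform"]],
               flagged = r$flagged, row.names = NULL)))
}

#' Per-group item calibrations
#'
#' Calibrates the same model separately in each group and aligns the
#' estimated parameters by item id for side-by-side reporting, the usual
#' companion table of a DIF screen.
#'
#' @param responses Persons x items matrix.
#' @param model `"2PL"` or `"GRM"`.
#' @param group Two-level group factor, one entry per person.
#' @param control A [calib_control()].
#' @return List with per-group `irt_calibration` fits and a combined
#'   data frame `table` of aligned parameters.
#' @export
group_item_params <- function(responses, model, group, control = calib_control()) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  fits <- lapply(levels(group), function(lev) {
    tryCatch(irt_calibrate(responses[group == lev, , drop = FALSE], model = model,
                           control = control),
             error = function(e) stop("calibration failed in group '", lev, "': ",
                                      conditionMessage(e)))
  })
  names(fits) <- levels(group)
  tabs <- lapply(levels(group), function(lev) {
    df <- as.data.frame(fits[[lev]]$bank)
    names(df)[-1L] <- paste0(names(df)[-1L], ".", lev)
    df
  })
  tab <- merge(tabs[[1L]], tabs[[2L]], by = "id", all = TRUE, sort = FALSE)
  list(fits = fits, table = tab)
}
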