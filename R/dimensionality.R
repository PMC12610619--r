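# Vectorised standard bivariate normal CDF P(X <= h, Y <= k; rho) via the
# single-integral reduction Phi2(h,k,rho) = Phi(h)Phi(k) +
# int_0^rho phi2(h,k;r) dr, evaluated with Gauss-Legendre quadrature.
# Checked in the tests against mvtnorm::pmvnorm.
binorm_cdf <- function(h, k, rho, n_gl = 48L) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  h <- pmin(pmax(h, -37), 37); k <- pmin(pmax(k, -37), 37)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  gl <- legendre_nodes(n_gl)
  r <- rho / 2 * (gl$x + 1)                 # map [-1,1] -> [0, rho]
  w <- rho / 2 * gl$w
  acc <- 0
  for (i in seq_along(r)) {
    s <- 1 - r[i]^2
    acc <- acc + w[i] *
      exp(-(h^2 - 2 * r[i] * h * k + k^2) / (2 * s)) / (2 * pi * sqrt(s))
  }
  base + acc
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached.
legendre_nodes <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b; J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
    cache[[key]] <<- out
    out
  }
})

#' Polychoric correlation matrix
#'
#' Two-step pairwise maximum likelihood: item thresholds come from the
#' marginal category proportions through the inverse normal CDF; each
#' pairwise latent correlation then maximises the bivariate-normal
#' likelihood of the observed contingency table with thresholds held
#' fixed. Missing responses are handled pairwise-complete.
#'
#' @param responses Persons x items matrix of ordinal codes (`NA` missing).
#' @return An object of class `polychoric` with fields `thresholds` (list
#'   of per-item threshold vectors), `rho` (correlation matrix) and
#'   `n_pairs` (pairwise-complete sample sizes).
#' @export
polychoric_matrix <- function(responses) {
  responses <- as.matrix(responses)
  p <- ncol(responses)
  if (p < 2L) stop("need at least 2 items")
  if (is.null(colnames(responses))) colnames(responses) <- paste0("V", seq_len(p))
  kmax <- apply(responses, 2L, max, na.rm = TRUE)
  single <- apply(responses, 2L, function(x) length(unique(x[!is.na(x)]))) < 2L
  if (any(single))
    stop("item(s) with a single observed category: ",
         paste(colnames(responses)[single], collapse = ", "))
  thresholds <- lapply(seq_len(p), function(j) {
    x <- responses[, j]
    pr <- cumsum(tabulate(x + 1L, kmax[j] + 1L)) / sum(!is.na(x))
    stats::qnorm(pmin(pmax(pr[-length(pr)], 1e-6), 1 - 1e-6))
  })
  names(thresholds) <- colnames(responses)

  rho <- diag(1, p)
  npairs <- matrix(nrow(responses), p, p)
  dimnames(rho) <- dimnames(npairs) <- list(colnames(responses), colnames(responses))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(responses[, i]) & !is.na(responses[, j])
      npairs[i, j] <- npairs[j, i] <- sum(ok)
      tab <- table(factor(responses[ok, i], levels = 0:kmax[i]),
                   factor(responses[ok, j], levels = 0:kmax[j]))
      r <- polychoric_pair(tab, thresholds[[i]], thresholds[[j]])
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(thresholds = thresholds, rho = rho, n_pairs = npairs),
            class = "polychoric")
}

# Maximise the contingency-table likelihood over rho with thresholds fixed.
# Perfect linear association (the boundary of the parameter space) is
# returned exactly rather than approached by the optimiser.
polychoric_pair <- function(tab, tau1, tau2) {
  idx <- which(tab > 0, arr.ind = TRUE)
  codes <- cbind(rep(idx[, 1L], tab[idx]), rep(idx[, 2L], tab[idx]))
  r_codes <- suppressWarnings(stats::cor(codes[, 1L], codes[, 2L]))
  if (isTRUE(all.equal(r_codes, 1))) return(1)
  if (isTRUE(all.equal(r_codes, -1))) return(-1)
  t1 <- c(-Inf, tau1, Inf); t2 <- c(-Inf, tau2, Inf)
  g1 <- rep(t1, times = length(t2)); g2 <- rep(t2, each = length(t1))
  nll <- function(r) {
    cdf <- matrix(binorm_cdf(g1, g2, r), length(t1), length(t2))
    cell <- cdf[-1L, -1L, drop = FALSE] - cdf[-nrow(cdf), -1L, drop = FALSE] -
      cdf[-1L, -ncol(cdf), drop = FALSE] +
      cdf[-nrow(cdf), -ncol(cdf), drop = FALSE]
    -sum(tab * log(pmax(cell, 1e-300)))
  }
  stats::optimize(nll, c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' @export
print.polychoric <- function(x, ...) {
  cat(sprintf("<polychoric> %d items\n", ncol(x$rho)))
  print(round(x$rho[seq_len(min(6L, nrow(x$rho))), seq_len(min(6L, ncol(x$rho)))], 3))
  invisible(x)
}

#' One-factor ordinal factor analysis by (diagonally) weighted least squares
#'
#' Fits a single-factor model to a polychoric correlation matrix by
#' minimising `sum_{i<j} w_ij (rho_ij - lambda_i lambda_j)^2`. With
#' `weights = "dwls"` each residual is weighted by the inverse of the
#' asymptotic variance factor `(1 - rho_ij^2)^2` of the correlation; with
#' `"uls"` all weights are one. The test statistic is `T = (n - 1) F_min`,
#' compared against the independence baseline for CFI/TLI; RMSEA and its
#' 90% interval come from noncentral chi-square inversion and SRMR is the
#' root mean squared residual correlation.
#'
#' @param poly A [polychoric_matrix()] result (or bare correlation matrix).
#' @param n Sample size behind the correlations.
#' @param weights `"dwls"` or `"uls"`.
#' @return An object of class `cfa_fit` with loadings and fit indices.
#' @export
fit_one_factor <- function(poly, n, weights = c("dwls", "uls")) {
  weights <- match.arg(weights)
  R <- if (inherits(poly, "polychoric")) poly$rho else as.matrix(poly)
  p <- ncol(R)
  if (p < 4L) stop("need at least 4 items for positive degrees of freedom")
  off <- upper.tri(R)
  W <- if (weights == "dwls") 1 / (1 - R[off]^2)^2 else rep(1, sum(off))

  obj <- function(l) {
    fitted <- tcrossprod(l)
    sum(W * (R[off] - fitted[off])^2)
  }
  grad <- function(l) {
    fitted <- tcrossprod(l)
    res <- matrix(0, p, p)
    res[off] <- W * (R[off] - fitted[off])
    res <- res + t(res)
    -2 * res %*% l
  }
  ev <- eigen(R, symmetric = TRUE)
  start <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.1))
  start <- start * sign(sum(start))
  start <- pmin(pmax(start, -0.95), 0.95)
  opt <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("one-factor minimiser did not converge (optim code ", opt$convergence, ")")
  lambda <- opt$par * sign(sum(opt$par))    # orient positively
  fmin <- opt$value

  df <- p * (p - 3) / 2
  T_stat <- (n - 1) * fmin
  f_base <- sum(W * R[off]^2)
  T_base <- (n - 1) * f_base
  df_base <- p * (p - 1) / 2
  cfi <- 1 - max(T_stat - df, 0) / max(T_base - df_base, T_stat - df, 0)
  tli_num <- T_base / df_base - T_stat / df
  tli <- tli_num / (T_base / df_base - 1)
  rmsea <- sqrt(max(T_stat - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(T_stat, df, n)
  resid <- R - tcrossprod(lambda); diag(resid) <- 0
  srmr <- sqrt(mean(resid[off]^2))

  structure(list(loadings = stats::setNames(as.numeric(lambda), colnames(R)),
                 chisq = T_stat, df = df, chisq_df_ratio = T_stat / df,
                 cfi = cfi, tli = tli, rmsea = rmsea,
                 rmsea_ci = ci, srmr = srmr, n = n, fmin = fmin,
                 weights = weights),
            class = "cfa_fit")
}

# 90% RMSEA interval by inverting the noncentral chi-square at the
# 0.95/0.05 tail probabilities of the observed statistic.
rmsea_ci <- function(T_stat, df, n) {
  bound <- function(prob) {
    if (stats::pchisq(T_stat, df, ncp = 0) < prob) return(0)
    f <- function(ncp) stats::pchisq(T_stat, df, ncp = ncp) - prob
    hi <- max(T_stat, df) * 3 + 10
    while (f(hi) > 0) hi <- hi * 2
    ncp <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
    sqrt(ncp / (df * (n - 1)))
  }
  c(lower = bound(0.95), upper = bound(0.05))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> one factor, %d items, n = %d (%s)\n",
              length(x$loadings), x$n, x$weights))
  cat(sprintf("  chisq %.2f on %d df (ratio %.2f)\n", x$chisq, x$df, x$chisq_df_ratio))
  cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.3f [%.3f, %.3f]  SRMR %.3f\n",
              x$cfi, x$tli, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$srmr))
  invisible(x)
}

#' Ordinal alpha
#'
#' Standardised internal-consistency coefficient computed on the
#' polychoric correlation matrix:
#' `alpha = p rbar / (1 + (p - 1) rbar)` with `rbar` the mean off-diagonal
#' correlation.
#'
#' @param poly A [polychoric_matrix()] result or bare correlation matrix.
#' @return List with `alpha` and `n_items`.
#' @export
ordinal_alpha <- function(poly) {
  R <- if (inherits(poly, "polychoric")) poly$rho else as.matrix(poly)
  p <- ncol(R)
  if (p < 2L) stop("need at least 2 items")
  rbar <- mean(R[upper.tri(R)])
  list(alpha = p * rbar / (1 + (p - 1) * rbar), n_items = p)
}
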