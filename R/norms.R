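# Term pools for the two model families. "log" uses ln(age); "quad" uses a
# centred orthogonal quadratic age basis whose constants are stored at fit
# time so new profiles can be projected onto the same columns.
term_pool <- function(family) {
  switch(family,
         log = c("lnAge", "MPE", "Sex", "lnAge:MPE", "lnAge:Sex", "MPE:Sex"),
         quad = c("Age", "Age2", "MPE", "Sex", "Age:MPE", "Age:Sex", "MPE:Sex"),
         stop("unknown family '", family, "'"))
}

# interaction => both mains present; Age2 => Age
hierarchy_ok <- function(terms) {
  for (tm in terms[grepl(":", terms)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    parts[parts == "Age2"] <- "Age"
    if (!all(parts %in% terms)) return(FALSE)
  }
  !("Age2" %in% terms) || ("Age" %in% terms)
}

#' Design recipe for a norm regression
#'
#' A recipe names the model family (`"log"` for ln-age, `"quad"` for the
#' centred orthogonal quadratic age basis) and the ordered set of terms,
#' and — once a model has been fitted — carries the orthogonal-polynomial
#' basis constants needed to rebuild the same columns for new profiles.
#'
#' @param family `"log"` or `"quad"`.
#' @param terms Subset of the family's term pool; interactions require
#'   their main effects and `Age2` requires `Age`.
#' @return An object of class `norm_recipe`.
#' @export
norm_recipe <- function(family = c("log", "quad"), terms) {
  family <- match.arg(family)
  pool <- term_pool(family)
  bad <- setdiff(terms, pool)
  if (length(bad)) stop("terms not in the '", family, "' pool: ",
                        paste(bad, collapse = ", "))
  if (!hierarchy_ok(terms)) stop("term set violates the model hierarchy")
  structure(list(family = family, terms = pool[pool %in% terms], basis = NULL),
            class = "norm_recipe")
}

#' Build a norm-model design matrix
#'
#' Constructs the design (with intercept) for a set of demographic
#' profiles. `lnAge` is the natural log of age in years; for the quadratic
#' family, `Age` and `Age2` are the centred, unit-norm orthogonal
#' polynomial columns of age. The basis is computed from the data when the
#' recipe has none (fit time) and reused verbatim otherwise (predict
#' time); interactions multiply already-transformed columns.
#'
#' @param profiles Data frame with columns `age`, `mpe` and (if the recipe
#'   uses it) `sex` coded 0/1.
#' @param recipe A [norm_recipe()].
#' @return Design matrix with attribute `"recipe"` holding the (possibly
#'   updated) recipe with its basis.
#' @export
build_design <- function(profiles, recipe) {
  stopifnot(inherits(recipe, "norm_recipe"))
  n <- nrow(profiles)
  cols <- list(`(Intercept)` = rep(1, n))
  base <- list(MPE = profiles$mpe)
  if (any(grepl("Sex", recipe$terms))) base$Sex <- profiles$sex
  if (recipe$family == "log") {
    base$lnAge <- log(profiles$age)
  } else if (any(c("Age", "Age2") %in% unlist(strsplit(recipe$terms, ":")))) {
    if (is.null(recipe$basis)) {
      po <- stats::poly(profiles$age, degree = 2)
      recipe$basis <- attr(po, "coefs")
    } else {
      po <- stats::poly(profiles$age, degree = 2, coefs = recipe$basis)
    }
    base$Age <- po[, 1L]
    base$Age2 <- po[, 2L]
  }
  for (tm in recipe$terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    cols[[tm]] <- Reduce(`*`, base[parts])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "recipe") <- recipe
  X
}

#' Exhaustive subset selection by Mallows' Cp and BIC
#'
#' Enumerates every hierarchy-respecting subset of the family's term pool,
#' fits each by OLS, and scores `Cp = SSE_m / sigma2_full - n + 2 p_m`
#' (with `sigma2_full` from the full-pool model) and the Gaussian BIC.
#' The winner under each criterion is the subset with the lowest value.
#'
#' @param theta Numeric response vector (ability estimates).
#' @param profiles Demographic data frame (`age`, `mpe`, `sex`).
#' @param family `"log"` or `"quad"`.
#' @return An object of class `selection_result`: a candidate table and
#'   winners per criterion.
#' @export
exhaustive_select <- function(theta, profiles, family = c("log", "quad")) {
  family <- match.arg(family)
  pool <- term_pool(family)
  n <- length(theta)
  full_recipe <- norm_recipe(family, pool)
  Xfull <- build_design(profiles, full_recipe)
  recipe_basis <- attr(Xfull, "recipe")
  if (n <= ncol(Xfull) + 2L) stop("too few observations for the full model")
  qr_full <- qr(Xfull)
  if (qr_full$rank < ncol(Xfull)) stop("full design is singular")
  sse_full <- sum(stats::lsfit(Xfull, theta, intercept = FALSE)$residuals^2)
  p_full <- ncol(Xfull)
  sigma2_full <- sse_full / (n - p_full)

  subsets <- Filter(hierarchy_ok,
                    lapply(seq_len(2^length(pool)) - 1L, function(mask)
                      pool[bitwAnd(mask, 2^(seq_along(pool) - 1L)) > 0]))
  rows <- lapply(subsets, function(terms) {
    X <- Xfull[, c("(Intercept)", terms), drop = FALSE]
    p <- ncol(X)
    sse <- sum(stats::lsfit(X, theta, intercept = FALSE)$residuals^2)
    data.frame(terms = paste(terms, collapse = " + "),
               p = p, sse = sse,
               cp = sse / sigma2_full - n + 2 * p,
               bic = n * log(sse / n) + p * log(n),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(candidates = tab,
                 winner_cp = tab$terms[which.min(tab$cp)],
                 winner_bic = tab$terms[which.min(tab$bic)],
                 family = family, recipe_basis = recipe_basis$basis, n = n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s family, %d candidate models, n = %d\n",
              x$family, nrow(x$candidates), x$n))
  cat("  Cp winner:  {", x$winner_cp, "}\n")
  cat("  BIC winner: {", x$winner_bic, "}\n")
  invisible(x)
}

#' Fit a final norm regression
#'
#' Ordinary least squares of ability estimates on the recipe's design.
#' The residual standard deviation uses `n - p` degrees of freedom and is
#' the scale of the percentile conversion.
#'
#' @param theta Ability estimates (response).
#' @param profiles Demographic data frame (`age`, `mpe`, `sex`).
#' @param recipe A [norm_recipe()].
#' @param test_id Optional test label carried into scoring checks.
#' @return An object of class `norm_model`: `recipe` (with basis), `beta`,
#'   `sigma`, `adj_r2`, `n_train`, `test_id` and the underlying `lm` fit.
#' @export
fit_norm_model <- function(theta, profiles, recipe, test_id = NULL) {
  X <- build_design(profiles, recipe)
  recipe <- attr(X, "recipe")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design; collinear terms: ",
         paste(colnames(X)[-keep], collapse = ", "))
  }
  dat <- as.data.frame(X[, -1L, drop = FALSE], check.names = FALSE)
  dat$.theta <- theta
  fit <- stats::lm(.theta ~ ., data = dat)
  s <- summary(fit)
  structure(list(recipe = recipe,
                 beta = stats::setNames(stats::coef(fit), colnames(X)),
                 sigma = s$sigma, adj_r2 = s$adj.r.squared,
                 r2 = s$r.squared, n_train = length(theta),
                 test_id = if (is.null(test_id)) NA_character_ else test_id,
                 lm = fit),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model>%s %s family, n = %s\n",
              if (is.na(x$test_id)) "" else paste0(" ", x$test_id, ","),
              x$recipe$family,
              if (is.null(x$n_train)) "?" else x$n_train))
  print(round(x$beta, 3))
  cat(sprintf("  residual SD %.3f%s\n", x$sigma,
              if (is.null(x$adj_r2) || is.na(x$adj_r2)) ""
              else sprintf(", adjusted R2 %.3f", x$adj_r2)))
  invisible(x)
}

#' @export
coef.norm_model <- function(object, ...) object$beta

#' @export
residuals.norm_model <- function(object, ...) {
  if (is.null(object$lm)) stop("model carries no training data (loaded from file?)")
  stats::residuals(object$lm)
}

#' Expected ability for demographic profiles
#'
#' The linear predictor `x' beta` of a norm model on new profiles. Ages
#' outside the supported 6-17.99 range are extrapolations and produce a
#' warning. A quadratic-family model can only be applied when its
#' orthogonal basis was stored at fit time.
#'
#' @param object A `norm_model`.
#' @param newdata Data frame with `age`, `mpe` and (if used) `sex`.
#' @param ... Unused.
#' @return Numeric vector of expected theta values.
#' @export
predict.norm_model <- function(object, newdata, ...) {
  if (object$recipe$family == "quad" && is.null(object$recipe$basis) &&
      any(c("Age", "Age2") %in% unlist(strsplit(object$recipe$terms, ":"))))
    stop("quadratic norm model has no stored orthogonal basis; ",
         "it cannot be applied to new raw ages")
  if (any(newdata$age < 6 | newdata$age >= 18))
    warning("age outside the normed 6-17.99 range: extrapolating")
  X <- build_design(newdata, object$recipe)
  drop(X %*% object$beta)
}

#' Simulate ability scores from a norm model
#'
#' Draws `theta = x' beta + N(0, sigma^2)` for each profile — the
#' generating process behind the synthetic cohorts.
#'
#' @param object A `norm_model`.
#' @param nsim Number of replicate draws.
#' @param seed Optional RNG seed.
#' @param newdata Profiles to simulate for.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated theta values.
#' @export
simulate.norm_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Repeated k-fold cross-validation of norm-model specifications
#'
#' For each repetition a fresh random `train_frac` split is drawn; within
#' the training part the same k folds are used for every specification,
#' accumulating fold MSE/RMSE; each specification is also refit on the
#' whole training part and scored on the held-out part (external RMSE).
#' `win_fraction` is the share of repetitions in which a specification
#' attains the lowest within-CV MSE.
#'
#' @param specs Named list of [norm_recipe()] objects.
#' @param theta Response vector.
#' @param profiles Demographic data frame.
#' @param k Folds (default 10).
#' @param reps Repetitions (default 100).
#' @param train_frac Training fraction per repetition (default 0.8).
#' @param seed RNG seed.
#' @return An object of class `cv_report` with per-spec mean MSE/RMSE,
#'   win fractions and mean external RMSE.
#' @export
repeated_cv <- function(specs, theta, profiles, k = 10L, reps = 100L,
                        train_frac = 0.8, seed = 1L) {
  stopifnot(length(specs) >= 1L, !is.null(names(specs)))
  n <- length(theta)
  n_train <- floor(n * train_frac)
  if (n_train < k) stop("k = ", k, " exceeds the training-set size ", n_train)
  set.seed(seed)
  m <- length(specs)
  cv_mse <- ext_rmse <- matrix(NA_real_, reps, m,
                               dimnames = list(NULL, names(specs)))
  for (rep_i in seq_len(reps)) {
    train <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), train)
    folds <- sample(rep(seq_len(k), length.out = n_train))
    for (s in seq_len(m)) {
      X <- build_design(profiles[train, , drop = FALSE], specs[[s]])
      y <- theta[train]
      sq_err <- numeric(0)
      for (f in seq_len(k)) {
        hold <- folds == f
        beta <- stats::lsfit(X[!hold, , drop = FALSE], y[!hold],
                             intercept = FALSE)$coefficients
        sq_err <- c(sq_err, mean((y[hold] - X[hold, , drop = FALSE] %*% beta)^2))
      }
      cv_mse[rep_i, s] <- mean(sq_err)
      # external holdout: refit on the full training part, score the 20%
      beta <- stats::lsfit(X, y, intercept = FALSE)$coefficients
      Xt <- build_design(profiles[test, , drop = FALSE],
                         attr(X, "recipe"))
      ext_rmse[rep_i, s] <- sqrt(mean((theta[test] - Xt %*% beta)^2))
    }
  }
  wins <- table(factor(names(specs)[apply(cv_mse, 1L, which.min)],
                       levels = names(specs)))
  win_fraction <- stats::setNames(as.numeric(wins) / reps, names(specs))
  structure(list(mean_mse = colMeans(cv_mse),
                 mean_rmse = colMeans(sqrt(cv_mse)),
                 win_fraction = win_fraction,
                 external_rmse = colMeans(ext_rmse),
                 k = k, reps = reps, train_frac = train_frac, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, %d repetitions (train %.0f%%)\n",
              x$k, x$reps, 100 * x$train_frac))
  print(round(data.frame(mean_rmse = x$mean_rmse,
                         win_fraction = x$win_fraction,
                         external_rmse = x$external_rmse), 4))
  invisible(x)
}

#' Regression diagnostics for a fitted norm model
#'
#' Variance inflation factors per non-intercept column, the maximum Cook's
#' distance (flagging > 1), a Brown-Forsythe (median-centred Levene) test
#' of absolute residuals across fitted-value quartile groups, and a
#' Kolmogorov-Smirnov test of the standardised residuals against the
#' standard normal. The KS p-value does not apply the estimated-parameter
#' (Lilliefors) correction; treat it as approximate.
#'
#' @param model A `norm_model` fitted in this session (carries its `lm`).
#' @return An object of class `norm_diagnostics`.
#' @export
norm_diagnostics <- function(model) {
  if (is.null(model$lm)) stop("model carries no training fit; rerun fit_norm_model")
  fit <- model$lm
  X <- stats::model.matrix(fit)[, -1L, drop = FALSE]
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  cooks <- stats::cooks.distance(fit)
  res <- stats::residuals(fit)
  grp <- cut(stats::fitted(fit),
             breaks = unique(stats::quantile(stats::fitted(fit),
                                             probs = seq(0, 1, 0.25))),
             include.lowest = TRUE)
  if (min(table(grp)) < 8L) {
    warning("fewer than 8 observations in a Levene group; merging to two groups")
    grp <- cut(stats::fitted(fit),
               breaks = stats::quantile(stats::fitted(fit), c(0, 0.5, 1)),
               include.lowest = TRUE)
  }
  lev <- car::leveneTest(res ~ grp, center = stats::median)
  z <- res / stats::sd(res)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  structure(list(vif = vif, max_cooks_d = max(cooks),
                 influential = which(cooks > 1),
                 levene_stat = lev[1L, "F value"], levene_p = lev[1L, "Pr(>F)"],
                 ks_p = ks$p.value),
            class = "norm_diagnostics")
}

#' @export
print.norm_diagnostics <- function(x, ...) {
  cat("<norm_diagnostics>\n")
  cat("  VIF:", paste(sprintf("%s %.3f", names(x$vif), x$vif), collapse = ", "), "\n")
  cat(sprintf("  max Cook's D %.4f (%d flagged > 1)\n", x$max_cooks_d,
              length(x$influential)))
  cat(sprintf("  Brown-Forsythe F %.3f (p = %.3f); KS normality p = %.3f\n",
              x$levene_stat, x$levene_p, x$ks_p))
  invisible(x)
}
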