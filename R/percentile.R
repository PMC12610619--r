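#' Recode raw Token Test scores to binary codes
#'
#' The shortened Token Test awards 1 point for an immediately correct
#' command, 0.5 for success after repetition, 0 otherwise; the calibration
#' dichotomises by recoding every 0.5 as 0.
#'
#' @param raw Numeric vector or matrix of raw values in `{0, 0.5, 1}`.
#' @return Integer codes in `{0, 1}` with the input's shape and names.
#' @export
recode_svtt <- function(raw) {
  check_raw_values(raw, c(0, 0.5, 1), "SVTT")
  out <- ifelse(unclass(raw) == 1, 1L, 0L)
  restore_shape(out, raw)
}

#' Recode raw complex-figure scores to ordinal codes
#'
#' The 0/0.5/1/2 accuracy-and-placement rubric maps onto ordered codes
#' 0/1/2/3 (an order-preserving bijection; the first boundary of each
#' graded item corresponds to raw category 0.5).
#'
#' @param raw Numeric vector or matrix of raw values in `{0, 0.5, 1, 2}`.
#' @return Integer codes in `{0, 1, 2, 3}`.
#' @export
recode_rocf <- function(raw) {
  check_raw_values(raw, c(0, 0.5, 1, 2), "ROCF")
  out <- match(unclass(raw), c(0, 0.5, 1, 2)) - 1L
  restore_shape(out, raw)
}

check_raw_values <- function(raw, legal, what) {
  v <- unclass(as.matrix(raw))
  bad <- which(!is.na(v) & !v %in% legal)
  if (length(bad)) {
    nm <- if (!is.null(colnames(as.matrix(raw))))
      colnames(as.matrix(raw))[(bad[1L] - 1L) %/% nrow(as.matrix(raw)) + 1L]
    else paste("position", bad[1L])
    stop("illegal ", what, " raw value ", v[bad[1L]], " (", nm, "); legal: ",
         paste(legal, collapse = ", "))
  }
  invisible(raw)
}

restore_shape <- function(out, raw) {
  if (is.matrix(raw)) {
    out <- matrix(out, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  } else names(out) <- names(raw)
  out
}

#' Demographically adjusted percentile rank
#'
#' The normative conversion: given an observed ability `theta_obs` and a
#' demographic profile, the expected ability is `theta_hat = x' beta`, the
#' cumulative probability is `p = Phi((theta_obs - theta_hat) / sigma)`
#' and the percentile rank is `100 p`. The displayed rank is clamped to
#' `[0.1, 99.9]`; the raw probability is retained.
#'
#' @param model A `norm_model` (see [fit_norm_model()], [published_norm_model()]).
#' @param theta_obs Observed ability estimate(s).
#' @param profile Data frame of demographic profiles (`age`, `mpe`, `sex`),
#'   one row per `theta_obs` (or a single row recycled).
#' @return A data frame of class `percentile_result` with columns
#'   `theta_obs`, `theta_hat`, `p`, `pr`, `pr_display`.
#' @examples
#' m <- published_norm_model("svtt")
#' percentile(m, theta_obs = 0, profile = data.frame(age = 10, mpe = 12))
#' @export
percentile <- function(model, theta_obs, profile) {
  stopifnot(inherits(model, "norm_model"))
  if (any(!is.finite(theta_obs))) stop("theta_obs must be finite")
  if (model$sigma <= 0) stop("model residual SD must be positive")
  if (nrow(profile) == 1L && length(theta_obs) > 1L)
    profile <- profile[rep(1L, length(theta_obs)), , drop = FALSE]
  theta_hat <- predict(model, profile)
  p <- stats::pnorm((theta_obs - theta_hat) / model$sigma)
  structure(data.frame(theta_obs = theta_obs, theta_hat = theta_hat,
                       p = p, pr = 100 * p,
                       pr_display = round(pmin(pmax(100 * p, 0.1), 99.9), 1)),
            class = c("percentile_result", "data.frame"))
}

#' Score a participant end to end
#'
#' The full clinical pipeline for one or more participants: recode raw
#' instrument scores to ordinal codes, estimate ability (EAP by default)
#' against the published (or any) item bank, and convert to a
#' demographically adjusted percentile rank with the matching norm model.
#' The bank and norm model must agree on the test id.
#'
#' @param raw Persons x items matrix (or single-person vector) of raw
#'   instrument scores on the native scale.
#' @param bank An [item_bank()]; its `test_id` selects the recoding rule
#'   (SVTT dichotomisation vs ROCF ordinal mapping).
#' @param model A `norm_model` for the same test.
#' @param profile Demographic data frame, one row per person.
#' @param method Ability estimator (default `"EAP"`).
#' @return List with `ability` (an `ability_estimates` data frame) and
#'   `percentile` (a `percentile_result` data frame, plus the ability SE
#'   and any estimation flags).
#' @export
score_participant <- function(raw, bank, model, profile, method = "EAP") {
  stopifnot(inherits(bank, "item_bank"), inherits(model, "norm_model"))
  if (!is.na(bank$test_id) && !is.na(model$test_id) &&
      bank$test_id != model$test_id)
    stop("bank is for ", bank$test_id, " but norm model is for ", model$test_id)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L,
                                       dimnames = list(NULL, names(raw)))
  codes <- if (identical(bank$test_id, "SVTT") ||
               length(bank$category_values) == 2L)
    recode_svtt(raw) else recode_rocf(raw)
  ability <- estimate_theta(codes, bank, method = method)
  pct <- percentile(model, ability$theta, profile)
  pct$se <- ability$se
  pct$flag <- ability$flag
  list(ability = ability, percentile = pct)
}

#' Published norm regression models
#'
#' Load one of the shipped demographic norm equations. The copy model is
#' quadratic in age on an orthogonal-polynomial basis whose constants were
#' not published; it is shipped without a basis and therefore cannot be
#' applied to new raw ages (predicting with it errors) — it documents the
#' published coefficients and residual SD.
#'
#' @param test One of `"rocf_copy"`, `"rocf_recall"`, `"svtt"`.
#' @return A `norm_model`.
#' @export
published_norm_model <- function(test = c("rocf_copy", "rocf_recall", "svtt")) {
  test <- match.arg(test)
  read_norm_model(system.file("extdata", paste0("norm_", test, ".json"),
                              package = "irtnorms", mustWork = TRUE))
}
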