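#' Test information, SEM and reliability curves
#'
#' Sum the item Fisher informations of a bank over a theta grid. The
#' standard error of measurement is `SEM(theta) = 1 / sqrt(I(theta))` and
#' conditional reliability is `1 - SEM(theta)^2` under the unit-variance
#' latent-trait convention. No prior information term is added.
#'
#' @param bank An [item_bank()].
#' @param thetas Numeric grid of evaluation points (default `[-6, 6]` in
#'   steps of 0.01).
#' @return An object of class `information_curve` with fields `theta`,
#'   `info`, `sem`, `reliability`.
#' @examples
#' tif <- test_information(published_bank("svtt"))
#' tif_summary(tif)
#' @export
test_information <- function(bank, thetas = seq(-6, 6, by = 0.01)) {
  stopifnot(inherits(bank, "item_bank"))
  if (length(bank$items) == 0L) stop("empty item bank")
  if (is.unsorted(thetas, strictly = TRUE)) stop("thetas must be strictly increasing")
  info <- rowSums(vapply(bank$items, item_information, numeric(length(thetas)),
                         theta = thetas))
  sem <- ifelse(info > 0, 1 / sqrt(info), Inf)
  structure(list(theta = thetas, info = info, sem = sem,
                 reliability = 1 - sem^2),
            class = "information_curve")
}

#' @export
print.information_curve <- function(x, ...) {
  s <- tif_summary(x)
  cat(sprintf(paste0("<information_curve> %d points on [%.2f, %.2f]\n",
                     "  peak I = %.3f at theta = %.2f (SEM %.3f, reliability %.3f)\n"),
              length(x$theta), min(x$theta), max(x$theta),
              max(x$info), s$theta_max, s$sem_at_max, s$reliability_at_max))
  invisible(x)
}

#' @export
plot.information_curve <- function(x, ...) {
  graphics::plot(x$theta, x$info, type = "l", xlab = expression(theta),
                 ylab = "Test information", ...)
  invisible(x)
}

#' Summarise an information curve
#'
#' Locates the information maximum by grid search, reports SEM and
#' reliability there, and (optionally) the trapezoidal average information
#' over an ability interval divided by its width.
#'
#' @param curve An `information_curve` from [test_information()].
#' @param interval Optional `c(lo, hi)` inside the curve's grid.
#' @return List with `theta_max`, `info_max`, `sem_at_max`,
#'   `reliability_at_max` and, when `interval` is given, `mean_information`.
#' @export
tif_summary <- function(curve, interval = NULL) {
  stopifnot(inherits(curve, "information_curve"))
  i <- which.max(curve$info)
  out <- list(theta_max = curve$theta[i], info_max = curve$info[i],
              sem_at_max = curve$sem[i], reliability_at_max = curve$reliability[i])
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L, interval[1] < interval[2])
    if (interval[1] < min(curve$theta) - 1e-9 || interval[2] > max(curve$theta) + 1e-9)
      stop("interval [", interval[1], ", ", interval[2], "] outside the curve grid")
    keep <- curve$theta >= interval[1] - 1e-9 & curve$theta <= interval[2] + 1e-9
    th <- curve$theta[keep]; v <- curve$info[keep]
    # trapezoidal integral / width
    out$mean_information <- sum(diff(th) * (v[-1] + v[-length(v)]) / 2) /
      (max(th) - min(th))
  }
  out
}

#' Reliability implied by a standard error of measurement
#'
#' Under a unit-variance latent trait, conditional reliability at theta is
#' `1 - SEM(theta)^2`.
#'
#' @param sem Positive standard error(s) of measurement.
#' @return `1 - sem^2`.
#' @examples
#' reliability_from_sem(0.315)  # about 0.90
#' @export
reliability_from_sem <- function(sem) {
  if (any(!is.finite(sem) | sem <= 0)) stop("sem must be positive and finite")
  1 - sem^2
}
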