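#' Configuration for a synthetic study cohort
#'
#' Defaults reproduce the study's demographic structure: age uniform on
#' [6, 17.99), mean parental education (MPE) normal with mean 12.15 and SD
#' 3.62 truncated to [0, 22] (renormalised sampling, not clipping), and
#' sex Bernoulli(0.542) for girls. Latent abilities are generated from the
#' published norm regressions with their residual SDs, and item responses
#' from the published banks — so every downstream stage can be exercised
#' against a known truth.
#'
#' @param n Cohort size.
#' @param tests Character subset of `c("svtt", "rocf_recall", "rocf_copy")`.
#' @param age_range,mpe_mean,mpe_sd,mpe_range,sex_p Demographic
#'   distribution settings.
#' @param banks,norms Named lists overriding the published item banks /
#'   norm models per test.
#' @param dif Optional DIF injection: `list(test =, item_id =, shift =,
#'   group =)` shifting that item's location(s) for one sex (`group` 0 or
#'   1) before sampling.
#' @param missing_rate Completely-at-random missingness proportion.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 668L,
                       tests = c("svtt", "rocf_recall", "rocf_copy"),
                       age_range = c(6, 17.99),
                       mpe_mean = 12.15, mpe_sd = 3.62, mpe_range = c(0, 22),
                       sex_p = 0.542,
                       banks = NULL, norms = NULL,
                       dif = NULL, missing_rate = 0) {
  stopifnot(n >= 1L, sex_p >= 0, sex_p <= 1,
            missing_rate >= 0, missing_rate < 1)
  tests <- match.arg(tests, several.ok = TRUE)
  if (is.null(banks))
    banks <- stats::setNames(lapply(tests, published_bank), tests)
  if (is.null(norms))
    norms <- stats::setNames(lapply(tests, published_norm_model), tests)
  structure(list(n = as.integer(n), tests = tests, age_range = age_range,
                 mpe_mean = mpe_mean, mpe_sd = mpe_sd, mpe_range = mpe_range,
                 sex_p = sex_p, banks = banks, norms = norms, dif = dif,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# truncated-normal draws by inverse-CDF sampling (renormalised, no clipping)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a study cohort
#'
#' Draws demographics per [sim_config()], generates each test's true
#' ability from its norm regression truth (`theta = x' beta + N(0,
#' sigma^2)`), and samples item responses from the bank's 2PL/GRM
#' probabilities at the true ability. A quadratic norm truth without a
#' stored orthogonal basis gets its basis constructed from the simulated
#' ages and stored in the returned provenance. Optional DIF injection
#' shifts one item's location parameters for one sex before sampling;
#' optional missingness is completely at random.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (required, for reproducibility).
#' @return A list of class `synthetic_cohort`: `demographics`,
#'   `theta` (named list per test), `responses` (named list of coded
#'   response matrices), `config` (with any constructed bases filled in)
#'   and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("simulate_cohort requires an explicit seed")
  set.seed(seed)
  n <- config$n
  demographics <- data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    mpe = rtruncnorm(n, config$mpe_mean, config$mpe_sd,
                     config$mpe_range[1], config$mpe_range[2]),
    sex = stats::rbinom(n, 1L, config$sex_p))

  theta <- responses <- list()
  for (test in config$tests) {
    truth <- config$norms[[test]]
    if (truth$recipe$family == "quad" && is.null(truth$recipe$basis)) {
      # construct the orthogonal age basis from this cohort and store it
      X <- build_design(demographics, truth$recipe)
      truth$recipe <- attr(X, "recipe")
      config$norms[[test]] <- truth
    }
    mu <- predict(truth, demographics)
    th <- mu + stats::rnorm(n, 0, truth$sigma)
    theta[[test]] <- th
    bank <- config$banks[[test]]
    resp <- sample_responses(bank, th, dif = config$dif, test = test,
                             sex = demographics$sex)
    if (config$missing_rate > 0)
      resp[matrix(stats::runif(length(resp)) < config$missing_rate,
                  nrow(resp))] <- NA_integer_
    rownames(resp) <- demographics$person_id
    responses[[test]] <- resp
  }
  structure(list(demographics = demographics, theta = theta,
                 responses = responses, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Simulate item responses at given abilities
#'
#' Samples one response per person-item cell from the bank's 2PL or GRM
#' category probabilities at the supplied abilities, using the current RNG
#' state. This is the generating process for calibration-recovery studies
#' (where abilities are typically standard-normal draws, matching the
#' calibration prior).
#'
#' @param bank An [item_bank()].
#' @param theta Numeric vector of abilities.
#' @return Integer response matrix (persons x items).
#' @export
simulate_responses <- function(bank, theta) {
  stopifnot(inherits(bank, "item_bank"))
  sample_responses(bank, theta)
}

sample_responses <- function(bank, theta, dif = NULL, test = NULL, sex = NULL) {
  n <- length(theta)
  banks <- list(ref = bank, focal = bank)
  use_focal <- rep(FALSE, n)
  if (!is.null(dif) && identical(dif$test, test)) {
    banks$focal <- shift_item(bank, dif$item_id, dif$shift)
    use_focal <- sex == dif$group
  }
  out <- matrix(NA_integer_, n, length(bank$items),
                dimnames = list(NULL, item_ids(bank)))
  u <- matrix(stats::runif(n * length(bank$items)), n)
  for (j in seq_along(bank$items)) {
    for (side in c("ref", "focal")) {
      rows <- if (side == "ref") which(!use_focal) else which(use_focal)
      if (!length(rows)) next
      it <- banks[[side]]$items[[j]]
      if (bank$model == "2PL") {
        out[rows, j] <- as.integer(u[rows, j] < prob_2pl(it, theta[rows]))
      } else {
        cum <- stats::plogis(outer(theta[rows], it$boundaries,
                                   function(t, b) it$a * (t - b)))
        out[rows, j] <- as.integer(rowSums(u[rows, j] < cum))
      }
    }
  }
  out
}

shift_item <- function(bank, item_id, shift) {
  stopifnot(is.finite(shift))
  ids <- item_ids(bank)
  j <- match(item_id, ids)
  if (is.na(j)) stop("unknown item '", item_id, "'")
  it <- bank$items[[j]]
  bank$items[[j]] <- if (inherits(it, "item_2pl"))
    item_2pl(it$id, it$a, it$b + shift)
  else item_grm(it$id, it$a, it$boundaries + shift)
  bank
}

#' Paired banks with injected DIF
#'
#' Returns a reference/focal bank pair in which one item's location
#' parameter(s) are translated by `shift` for the focal group — the
#' ground truth for DIF power studies.
#'
#' @param bank An [item_bank()].
#' @param item_id Item to contaminate.
#' @param shift Location shift in theta units (positive = harder for the
#'   focal group).
#' @return List with `reference` and `focal` banks.
#' @export
inject_dif <- function(bank, item_id, shift) {
  list(reference = bank, focal = shift_item(bank, item_id, shift))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, seed = %s, tests: %s\n",
              nrow(x$demographics), format(x$seed),
              paste(x$config$tests, collapse = ", ")))
  invisible(x)
}
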