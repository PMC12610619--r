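#' 2PL response probability
#'
#' Probability of a correct (code 1) response under the two-parameter
#' logistic model, `P(theta) = 1 / (1 + exp(-a (theta - b)))`, on the pure
#' logistic metric.
#'
#' @param item An [item_2pl()].
#' @param theta Numeric vector of latent-trait values.
#' @return Probabilities, same length as `theta`.
#' @export
prob_2pl <- function(item, theta) {
  stopifnot(inherits(item, "item_2pl"))
  stats::plogis(item$a * (theta - item$b))
}

#' GRM cumulative category probability
#'
#' Probability of scoring at or above category `k` under the graded
#' response model: `P*(k) = 1 / (1 + exp(-a (theta - boundary_k)))`. By
#' definition `P*(0) = 1` and `P*(K) = 0` for an item with K categories.
#'
#' @param item An [item_grm()].
#' @param k Category index, `0 <= k <= K`.
#' @param theta Numeric vector of latent-trait values.
#' @return Probabilities, same length as `theta`.
#' @examples
#' it <- item_grm("Item 1", a = 1.824, boundaries = c(-2.506, -1.542, 2.292))
#' cum_prob_grm(it, 1, theta = -2.506)  # 0.5 at the first boundary
#' @export
cum_prob_grm <- function(item, k, theta) {
  stopifnot(inherits(item, "item_grm"), length(k) == 1L)
  K <- length(item$boundaries) + 1L
  if (k < 0 || k > K) stop("category index k = ", k, " out of range [0, ", K, "]")
  if (k == 0) return(rep(1, length(theta)))
  if (k == K) return(rep(0, length(theta)))
  stats::plogis(item$a * (theta - item$boundaries[k]))
}

#' GRM category probabilities
#'
#' Probability of each of the K ordered categories at `theta`, obtained by
#' differencing adjacent cumulative boundary curves.
#'
#' @param item An [item_grm()].
#' @param theta Numeric vector.
#' @return A `length(theta) x K` matrix of category probabilities; rows sum
#'   to 1.
#' @export
cat_probs_grm <- function(item, theta) {
  stopifnot(inherits(item, "item_grm"))
  # columns: P*(0) = 1, P*(1), ..., P*(K-1), P*(K) = 0
  cum <- cbind(1, stats::plogis(outer(theta, item$boundaries,
                                      function(t, b) item$a * (t - b))), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
  colnames(p) <- paste0("cat", seq_len(ncol(p)) - 1L)
  p
}

#' Item Fisher information
#'
#' For a 2PL item, `I(theta) = a^2 P (1 - P)`. For a graded-response item,
#' `I(theta) = sum_k (dP_k/dtheta)^2 / P_k` where
#' `dP_k/dtheta = a (P*_k (1 - P*_k) - P*_{k+1} (1 - P*_{k+1}))`.
#'
#' @param item An [item_2pl()] or [item_grm()].
#' @param theta Numeric vector.
#' @return Nonnegative information values, same length as `theta`.
#' @export
item_information <- function(item, theta) UseMethod("item_information")

#' @export
item_information.item_2pl <- function(item, theta) {
  p <- prob_2pl(item, theta)
  item$a^2 * p * (1 - p)
}

#' @export
item_information.item_grm <- function(item, theta) {
  cum <- cbind(1, stats::plogis(outer(theta, item$boundaries,
                                      function(t, b) item$a * (t - b))), 0)
  pk <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
  dcum <- item$a * cum * (1 - cum)
  dk <- dcum[, -ncol(dcum), drop = FALSE] - dcum[, -1L, drop = FALSE]
  rowSums(dk^2 / pmax(pk, .Machine$double.xmin))
}

#' Joint conditional log-likelihood of a response matrix
#'
#' Sum over all non-missing cells of the log probability of the observed
#' ordinal code given the item parameters and each person's ability.
#' Missing responses contribute zero (missing-at-random, never imputed).
#'
#' @param bank An [item_bank()] covering the response columns.
#' @param responses Integer matrix (persons x items) of ordinal codes with
#'   `NA` for missing; column names must match bank item ids.
#' @param thetas Numeric vector of abilities, one per person.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(bank, responses, thetas) {
  responses <- as_response_matrix(responses, bank)
  if (length(thetas) != nrow(responses))
    stop("need one theta per person: got ", length(thetas), " for ",
         nrow(responses), " persons")
  ll <- 0
  for (j in seq_along(bank$items)) {
    x <- responses[, j]
    obs <- !is.na(x)
    if (!any(obs)) next
    if (bank$model == "2PL") {
      p <- prob_2pl(bank$items[[j]], thetas[obs])
      ll <- ll + sum(ifelse(x[obs] == 1L, log(p), log1p(-p)))
    } else {
      pm <- cat_probs_grm(bank$items[[j]], thetas[obs])
      ll <- ll + sum(log(pm[cbind(seq_len(sum(obs)), x[obs] + 1L)]))
    }
  }
  ll
}

# Coerce and validate a response matrix against a bank: integer codes in
# [0, K_j - 1], columns matched to bank items by name when present.
as_response_matrix <- function(responses, bank) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) stop("responses must be numeric ordinal codes")
  if (!is.null(colnames(responses))) {
    missing_items <- setdiff(colnames(responses), item_ids(bank))
    if (length(missing_items))
      stop("response columns not in bank: ", paste(missing_items, collapse = ", "))
    responses <- responses[, item_ids(bank), drop = FALSE]
  } else if (ncol(responses) != length(bank$items)) {
    stop("response matrix has ", ncol(responses), " columns but bank has ",
         length(bank$items), " items")
  }
  k <- n_categories(bank)
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    bad <- which(!is.na(x) & (x != floor(x) | x < 0 | x > k[j] - 1L))
    if (length(bad))
      stop("illegal code ", x[bad[1L]], " for item ", item_ids(bank)[j],
           ", person ",
           if (is.null(rownames(responses))) bad[1L] else rownames(responses)[bad[1L]])
  }
  storage.mode(responses) <- "integer"
  responses
}
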