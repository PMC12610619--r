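#' Dichotomous 2PL item
#'
#' Construct a two-parameter logistic item with discrimination `a` and
#' difficulty `b`, both on the logistic metric (no 1.702 scaling constant).
#'
#' @param id Item label (character scalar).
#' @param a Discrimination, must be strictly positive.
#' @param b Difficulty in latent-trait (theta) units, must be finite.
#' @return An object of class `item_2pl`.
#' @examples
#' item_2pl("Item 36", a = 1.144, b = -0.330)
#' @export
item_2pl <- function(id, a, b) {
  stopifnot(length(id) == 1L, length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || a <= 0) stop("discrimination 'a' must be positive for item ", id)
  if (!is.finite(b)) stop("difficulty 'b' must be finite for item ", id)
  structure(list(id = as.character(id), a = as.numeric(a), b = as.numeric(b)),
            class = "item_2pl")
}

#' Ordered polytomous graded-response item
#'
#' A graded response model item with K ordered categories is defined by a
#' single discrimination `a` and K - 1 boundary locations: `boundaries[k]` is
#' the theta value at which the probability of scoring at or above category
#' k equals 0.5.
#'
#' @param id Item label.
#' @param a Discrimination (> 0).
#' @param boundaries Nondecreasing numeric vector of boundary locations.
#' @return An object of class `item_grm`.
#' @examples
#' item_grm("Item 1", a = 1.824, boundaries = c(-2.506, -1.542, 2.292))
#' @export
item_grm <- function(id, a, boundaries) {
  stopifnot(length(id) == 1L, length(a) == 1L)
  if (!is.finite(a) || a <= 0) stop("discrimination 'a' must be positive for item ", id)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || anyNA(boundaries))
    stop("item ", id, " needs at least one finite boundary")
  if (is.unsorted(boundaries)) stop("boundaries must be nondecreasing for item ", id)
  structure(list(id = as.character(id), a = as.numeric(a), boundaries = boundaries),
            class = "item_grm")
}

#' Item parameter bank
#'
#' A homogeneous collection of calibrated items for one test, together with
#' the mapping from ordinal response codes (0, 1, 2, ...) to the
#' instrument's raw score values (e.g. 0/0.5/1/2 for the complex-figure
#' scoring rubric).
#'
#' @param items List of [item_2pl()] or [item_grm()] objects (not mixed).
#' @param category_values Strictly increasing raw score values, one per
#'   ordinal category.
#' @param test_id Optional test identifier (e.g. `"SVTT"`, `"ROCFcopy"`,
#'   `"ROCFimm"`) used for consistency checks when scoring.
#' @return An object of class `item_bank` with fields `model` (`"2PL"` or
#'   `"GRM"`), `items`, `category_values` and `test_id`.
#' @seealso [published_bank()] for the shipped parameter tables,
#'   [read_item_bank()] for the JSON interchange format.
#' @export
item_bank <- function(items, category_values, test_id = NULL) {
  if (length(items) == 0L) stop("an item bank needs at least one item")
  cls <- vapply(items, function(x) class(x)[1L], character(1))
  if (!all(cls == cls[1L]) || !cls[1L] %in% c("item_2pl", "item_grm"))
    stop("items must all be 'item_2pl' or all 'item_grm'")
  model <- if (cls[1L] == "item_2pl") "2PL" else "GRM"
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate item ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  category_values <- as.numeric(category_values)
  if (is.unsorted(category_values, strictly = TRUE))
    stop("category_values must be strictly increasing")
  if (model == "2PL" && length(category_values) != 2L)
    stop("a 2PL bank has exactly two categories")
  if (model == "GRM") {
    k <- vapply(items, function(x) length(x$boundaries), integer(1)) + 1L
    if (any(k > length(category_values)))
      stop("GRM items cannot have more than length(category_values) - 1 boundaries")
  }
  structure(list(model = model, items = items,
                 category_values = category_values,
                 test_id = if (is.null(test_id)) NA_character_ else as.character(test_id)),
            class = "item_bank")
}

#' @export
length.item_bank <- function(x) length(x$items)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %s, %d items, %d categories%s\n",
              x$model, length(x$items), length(x$category_values),
              if (is.na(x$test_id)) "" else paste0(" (", x$test_id, ")")))
  print(utils::head(as.data.frame(x), 6L))
  if (length(x$items) > 6L) cat("...", length(x$items) - 6L, "more items\n")
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  ids <- item_ids(x)
  a <- vapply(x$items, `[[`, numeric(1), "a")
  if (x$model == "2PL") {
    data.frame(id = ids, a = a,
               b = vapply(x$items, `[[`, numeric(1), "b"))
  } else {
    nb <- max(vapply(x$items, function(it) length(it$boundaries), integer(1)))
    bm <- t(vapply(x$items, function(it)
      c(it$boundaries, rep(NA_real_, nb - length(it$boundaries))), numeric(nb)))
    colnames(bm) <- paste0("b", seq_len(nb))
    cbind(data.frame(id = ids, a = a), as.data.frame(bm))
  }
}

#' Item identifiers of a bank
#' @param bank An [item_bank()].
#' @return Character vector of item ids in bank order.
#' @export
item_ids <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  vapply(bank$items, `[[`, character(1), "id")
}

#' Number of response categories per item
#' @param bank An [item_bank()].
#' @return Integer vector (2 for every 2PL item).
#' @export
n_categories <- function(bank) {
  if (bank$model == "2PL") rep(2L, length(bank$items))
  else vapply(bank$items, function(x) length(x$boundaries), integer(1)) + 1L
}

#' Published item banks and norm equations
#'
#' Load one of the item parameter banks shipped with the package: the 18
#' complex-figure scoring units in the copy (`"rocf_copy"`) and immediate
#' recall (`"rocf_recall"`) conditions, calibrated under the graded response
#' model, or the 36 shortened Token Test commands (`"svtt"`) calibrated
#' under the 2PL.
#'
#' @param test One of `"rocf_copy"`, `"rocf_recall"`, `"svtt"`.
#' @return An [item_bank()].
#' @examples
#' svtt <- published_bank("svtt")
#' length(svtt)
#' @export
published_bank <- function(test = c("rocf_copy", "rocf_recall", "svtt")) {
  test <- match.arg(test)
  read_item_bank(system.file("extdata", paste0(test, ".json"),
                             package = "irtnorms", mustWork = TRUE))
}
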