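#' Read a response matrix from CSV
#'
#' First column person id, remaining columns one per item; cells are
#' ordinal codes, with empty cells or `NA` treated as missing.
#'
#' @param path CSV file path.
#' @return Integer matrix with person ids as row names and item ids as
#'   column names.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("response CSV needs a person-id column plus items: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate person id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.na(df[[j + 1L]]) & is.na(suppressWarnings(as.numeric(m[, j]))))
    if (length(bad))
      stop("non-numeric cell at line ", bad[1L] + 1L, ", column '",
           colnames(m)[j], "' of ", path)
  }
  storage.mode(m) <- "numeric"
  if (any(m[!is.na(m)] %% 1 != 0))
    stop("non-integer response codes in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a response matrix to CSV
#'
#' @param responses Matrix with row names as person ids.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(person_id = rownames(responses), responses,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a demographics table from CSV
#'
#' Expects columns `person_id`, `age`, `mpe`, `sex` (sex coded 0 = boy,
#' 1 = girl).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop("demographics file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "age", "mpe")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("demographics CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$person_id))
    stop("duplicate person id(s) in demographics: ", path)
  df
}

#' Read / write an item bank as JSON
#'
#' Interchange schema: `{"model": "2PL"|"GRM", "test_id": ...,`
#' `"categories": [raw values], "items": [{"id", "a", "b"} |`
#' `{"id", "a", "boundaries": [...]}]}`. Invariants (positive
#' discriminations, ordered boundaries, increasing category values) are
#' validated on load.
#'
#' @param path JSON file path.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("bank file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$model) || !j$model %in% c("2PL", "GRM"))
    stop("bank model must be '2PL' or 'GRM': ", path)
  items <- lapply(j$items, function(it) {
    if (j$model == "2PL") item_2pl(it$id, it$a, it$b)
    else item_grm(it$id, it$a, unlist(it$boundaries))
  })
  item_bank(items, unlist(j$categories),
            test_id = if (is.null(j$test_id)) NULL else j$test_id)
}

#' @rdname read_item_bank
#' @param bank An [item_bank()] to serialise.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  items <- lapply(bank$items, function(it) {
    if (inherits(it, "item_2pl")) list(id = it$id, a = it$a, b = it$b)
    else list(id = it$id, a = it$a, boundaries = it$boundaries)
  })
  out <- list(model = bank$model, categories = bank$category_values,
              items = items)
  if (!is.na(bank$test_id)) out <- c(list(test_id = bank$test_id), out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a norm model as JSON
#'
#' Serialises the recipe (family, terms, orthogonal basis when present),
#' coefficients, residual SD and fit summaries. The training `lm` object
#' is not serialised; a reloaded model predicts and scores but cannot be
#' re-diagnosed.
#'
#' @param path JSON file path.
#' @return A `norm_model`.
#' @export
read_norm_model <- function(path) {
  if (!file.exists(path)) stop("norm model file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  recipe <- norm_recipe(j$family, j$terms)
  if (length(j$basis$alpha)) {
    recipe$basis <- list(alpha = as.numeric(j$basis$alpha),
                         norm2 = as.numeric(j$basis$norm2))
  }
  structure(list(recipe = recipe, beta = unlist(j$beta),
                 sigma = j$sigma,
                 adj_r2 = if (is.null(j$adj_r2)) NA_real_ else j$adj_r2,
                 r2 = if (is.null(j$r2)) NA_real_ else j$r2,
                 n_train = if (is.null(j$n_train)) NA_integer_ else j$n_train,
                 test_id = if (is.null(j$test_id)) NA_character_ else j$test_id,
                 lm = NULL),
            class = "norm_model")
}

#' @rdname read_norm_model
#' @param model A `norm_model` to serialise.
#' @export
write_norm_model <- function(model, path) {
  stopifnot(inherits(model, "norm_model"))
  out <- list(test_id = model$test_id, family = model$recipe$family,
              terms = model$recipe$terms,
              beta = as.list(model$beta), sigma = model$sigma,
              adj_r2 = model$adj_r2, r2 = model$r2, n_train = model$n_train,
              basis = if (is.null(model$recipe$basis)) NULL else
                list(alpha = model$recipe$basis$alpha,
                     norm2 = model$recipe$basis$norm2))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ability-estimates table from CSV
#'
#' Expects columns `person_id` and `theta` (optionally `se`).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_abilities <- function(path) {
  if (!file.exists(path)) stop("abilities file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("person_id", "theta") %in% names(df)))
    stop("abilities CSV needs person_id and theta columns: ", path)
  df
}
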