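#' Define a polytomous rating scale
#'
#' A scale definition names the items of an instrument, the number of ordered
#' response categories per item, which items are reverse-coded, and the
#' category labels used when responses arrive as text.
#'
#' @param items data frame with columns `id` (unique item identifiers),
#'   `label` (short description) and optionally `text` (full question
#'   wording).
#' @param n_categories integer (scalar or one per item), number of ordered
#'   response categories; responses are coded `0 .. n_categories - 1`.
#' @param reverse_coded character vector of item ids whose raw responses run
#'   in the opposite direction to the construct and must be flipped
#'   (`x -> m - x`) before analysis.
#' @param category_labels character vector of category labels, ordered from
#'   code 0 upward, used to map textual responses to codes.
#'
#' @return An object of class `scale_definition`.
#' @seealso [fast_scale()] for the bundled 9-item FAST definition.
#' @export
scale_definition <- function(items, n_categories = 5L,
                             reverse_coded = character(),
                             category_labels = NULL) {
  if (is.character(items)) items <- data.frame(id = items, label = items)
  if (!is.data.frame(items) || !all(c("id", "label") %in% names(items)))
    stop_fv("`items` must be a data frame with columns id and label")
  items$id <- as.character(items$id)
  if (anyDuplicated(items$id)) stop_fv("item ids must be unique")
  J <- nrow(items)
  if (J < 1L) stop_fv("a scale needs at least one item")
  n_categories <- as.integer(rep_len(n_categories, J))
  if (any(n_categories < 2L)) stop_fv("every item needs at least 2 categories")
  reverse_coded <- as.character(reverse_coded)
  if (!all(reverse_coded %in% items$id))
    stop_fv("reverse_coded ids not in the scale: %s",
            paste(setdiff(reverse_coded, items$id), collapse = ", "))
  if (!is.null(category_labels)) {
    category_labels <- as.character(category_labels)
    if (length(category_labels) != max(n_categories))
      stop_fv("category_labels must have one label per category")
  }
  structure(list(items = items, n_categories = n_categories,
                 reverse_coded = reverse_coded,
                 category_labels = category_labels),
            class = "scale_definition")
}

#' The 9-item Food Access Survey Tool (FAST)
#'
#' Bundled definition of the FAST household food insecurity instrument used
#' in rural Bangladesh: nine experience items answered on a 5-point
#' frequency scale (0 = never, 1 = rarely, 2 = sometimes, 3 = often,
#' 4 = mostly), recalled over the past 6 months. Item 1 ("square meals")
#' asks about a positive experience and is reverse-coded so that, after
#' coding, higher values always indicate more severe food insecurity.
#'
#' @return A [scale_definition()] for the FAST.
#' @export
fast_scale <- function() {
  stem <- "In the past 6 months, how often did"
  items <- data.frame(
    id = paste0("item", 1:9),
    label = c("No square meals", "Have to eat other grains",
              "Skip entire meals", "Eat less", "Run out of food",
              "Worry about food", "Purchase rice often",
              "Take food on credit", "Borrow food"),
    text = paste(stem, c(
      "you eat three 'square meals' (full stomach meals) a day (not a festival day)?",
      "you or any of your family have to eat wheat (or another grain) although you wanted to eat rice (not including when you were sick)?",
      "you yourself skip entire meals due to scarcity of food?",
      "you personally eat less food in a meal due to scarcity of food?",
      "food stored in your home run out and there was no money to buy more that day?",
      "you worry about where food would come from?",
      "your family purchase rice?",
      "your family take food (rice, lentils etc.) on credit (or loan) from a local shop?",
      "your family have to borrow food from relatives or neighbors to make a meal?")))
  scale_definition(items, n_categories = 5L, reverse_coded = "item1",
                   category_labels = c("never", "rarely", "sometimes",
                                       "often", "mostly"))
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("Scale definition: %d items, %s categories\n",
              nrow(x$items), paste(unique(x$n_categories), collapse = "/")))
  for (i in seq_len(nrow(x$items)))
    cat(sprintf("  %s: %s%s\n", x$items$id[i], x$items$label[i],
                if (x$items$id[i] %in% x$reverse_coded) " [reverse-coded]" else ""))
  invisible(x)
}

#' Read or write a scale definition as YAML
#'
#' @param path file path.
#' @return `read_scale_definition` returns a [scale_definition()];
#'   `write_scale_definition` invisibly returns `path`.
#' @export
read_scale_definition <- function(path) {
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, function(it)
    data.frame(id = it$id, label = it$label, text = it$text %||% NA_character_)))
  scale_definition(items, n_categories = y$n_categories %||% 5L,
                   reverse_coded = unlist(y$reverse_coded) %||% character(),
                   category_labels = unlist(y$category_labels))
}

#' @rdname read_scale_definition
#' @param scale a [scale_definition()].
#' @export
write_scale_definition <- function(scale, path) {
  y <- list(
    items = lapply(seq_len(nrow(scale$items)), function(i)
      as.list(scale$items[i, c("id", "label",
                               intersect("text", names(scale$items)))])),
    n_categories = scale$n_categories,
    reverse_coded = as.list(scale$reverse_coded),
    category_labels = as.list(scale$category_labels))
  yaml::write_yaml(y, path)
  invisible(path)
}

new_response_matrix <- function(values, coded, n_excluded = 0L,
                                n_categories = NULL) {
  storage.mode(values) <- "integer"
  if (is.null(n_categories)) {
    n_categories <- apply(values, 2L, function(v)
      max(v, 1L, na.rm = TRUE)) + 1L
  }
  structure(values, class = "response_matrix", coded = coded,
            n_excluded = as.integer(n_excluded),
            n_categories = as.integer(rep_len(n_categories, ncol(values))))
}

#' Construct a response matrix from in-memory data
#'
#' @param values numeric matrix or data frame, respondents in rows and items
#'   in columns; entries are category codes (`0 .. m`) or `NA`.
#' @param scale optional [scale_definition()]; when supplied, column names
#'   must match the scale's item ids and entries are range-checked.
#' @param coded logical: have reverse-coded items already been flipped?
#' @return A `response_matrix`: an integer matrix with attributes `coded`,
#'   `n_excluded` (rows dropped because every entry was missing) and
#'   `n_categories`.
#' @export
as_response_matrix <- function(values, scale = NULL, coded = FALSE) {
  values <- as.matrix(values)
  if (!nrow(values)) stop_fv("response matrix must have at least one row")
  nc <- NULL
  if (!is.null(scale)) {
    if (is.null(colnames(values))) colnames(values) <- scale$items$id
    missing_items <- setdiff(scale$items$id, colnames(values))
    if (length(missing_items))
      stop_fv("columns missing for items: %s",
              paste(missing_items, collapse = ", "))
    unknown <- setdiff(colnames(values), scale$items$id)
    if (length(unknown))
      stop_fv("unknown item columns: %s", paste(unknown, collapse = ", "))
    values <- values[, scale$items$id, drop = FALSE]
    nc <- scale$n_categories
    check_range(values, nc)
  }
  all_missing <- rowSums(!is.na(values)) == 0L
  n_excluded <- sum(all_missing)
  values <- values[!all_missing, , drop = FALSE]
  if (!nrow(values)) stop_fv("all rows are entirely missing")
  new_response_matrix(values, coded = coded, n_excluded = n_excluded,
                      n_categories = nc)
}

check_range <- function(values, n_categories) {
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0 | v > n_categories[j] - 1L | v != round(v)))
    if (length(bad))
      stop_fv("out-of-range response %s at row %d, column '%s' (allowed 0..%d)",
              format(v[bad[1L]]), bad[1L], colnames(values)[j] %||% j,
              n_categories[j] - 1L)
  }
  invisible(TRUE)
}

#' Read a respondent-by-item response file
#'
#' Reads a delimited text file whose header names the scale's items (an
#' optional leading `respondent` id column is allowed). Cells may hold
#' integer category codes, category labels from the scale definition, or a
#' missing-value token. Rows in which every item is missing are dropped and
#' counted (attribute `n_excluded`); partially missing rows are kept.
#'
#' @param path path to a CSV (or TSV, by extension) file.
#' @param scale a [scale_definition()].
#' @param missing token denoting a missing response, default `"NA"`.
#' @param sep field separator; by default inferred from the file extension.
#' @return A raw-coded `response_matrix` (`coded = FALSE`); apply
#'   [apply_coding()] before analysis.
#' @export
read_responses <- function(path, scale, missing = "NA", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, strip.white = TRUE)
  id_col <- intersect(c("respondent", "id"), names(df))[1]
  ids <- NULL
  if (!is.na(id_col)) {
    ids <- df[[id_col]]
    df <- df[, setdiff(names(df), id_col), drop = FALSE]
  }
  unknown <- setdiff(names(df), scale$items$id)
  if (length(unknown))
    stop_fv("unknown item columns: %s", paste(unknown, collapse = ", "))
  missing_items <- setdiff(scale$items$id, names(df))
  if (length(missing_items))
    stop_fv("columns missing for items: %s",
            paste(missing_items, collapse = ", "))
  df <- df[, scale$items$id, drop = FALSE]
  vals <- matrix(NA_integer_, nrow(df), ncol(df),
                 dimnames = list(ids, names(df)))
  labs <- scale$category_labels
  for (j in seq_along(df)) {
    v <- df[[j]]
    out <- rep(NA_integer_, length(v))
    is_miss <- v %in% missing | v == ""
    if (!is.null(labs)) {
      hit <- match(tolower(v), tolower(labs))
      out[!is.na(hit)] <- hit[!is.na(hit)] - 1L
    }
    numeric_like <- grepl("^\\s*-?[0-9]+\\s*$", v)
    out[numeric_like] <- as.integer(v[numeric_like])
    bad <- which(!is_miss & is.na(out))
    if (length(bad))
      stop_fv("unreadable response '%s' at row %d, column '%s'",
              v[bad[1L]], bad[1L], names(df)[j])
    out[is_miss] <- NA_integer_
    vals[, j] <- out
  }
  check_range(vals, scale$n_categories)
  as_response_matrix(vals, scale = scale, coded = FALSE)
}

#' Apply the scale's coding conventions
#'
#' Flips each reverse-coded item (`x -> m - x`, with `m` the maximum
#' category code) so that higher codes uniformly indicate more severe
#' deprivation. Guarded by the `coded` flag: applying twice is an error.
#'
#' @param matrix a raw `response_matrix`.
#' @param scale the matching [scale_definition()].
#' @return The coded `response_matrix` (`coded = TRUE`).
#' @export
apply_coding <- function(matrix, scale) {
  if (!inherits(matrix, "response_matrix"))
    matrix <- as_response_matrix(matrix, scale, coded = FALSE)
  if (isTRUE(attr(matrix, "coded")))
    stop_fv("coding has already been applied to this matrix")
  for (id in scale$reverse_coded) {
    j <- match(id, colnames(matrix))
    m <- scale$n_categories[match(id, scale$items$id)] - 1L
    matrix[, j] <- m - matrix[, j]
  }
  attr(matrix, "coded") <- TRUE
  matrix
}

#' Summarize coded responses
#'
#' @param matrix a coded `response_matrix`.
#' @return A list with `marginals` (item-by-category percentage table over
#'   non-missing responses, rows summing to 100), `floor_proportion` (share
#'   of respondents whose every non-missing response is 0), `n` respondents
#'   and `n_missing` per item.
#' @export
summarize_responses <- function(matrix) {
  if (!isTRUE(attr(matrix, "coded")))
    stop_fv("summarize_responses expects a coded matrix; run apply_coding() first")
  n <- nrow(matrix)
  if (!n) stop_fv("empty response matrix")
  nc <- attr(matrix, "n_categories")
  K <- max(nc)
  marg <- matrix(NA_real_, ncol(matrix), K,
                 dimnames = list(colnames(matrix),
                                 as.character(0:(K - 1L))))
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    counts <- tabulate(v[!is.na(v)] + 1L, nbins = nc[j])
    marg[j, seq_len(nc[j])] <- 100 * counts / sum(counts)
  }
  floor_prop <- mean(apply(matrix, 1L, function(r) all(r[!is.na(r)] == 0L)))
  list(marginals = marg, floor_proportion = floor_prop, n = n,
       n_missing = colSums(is.na(matrix)),
       n_excluded = attr(matrix, "n_excluded") %||% 0L)
}

#' Read a covariate table keyed by respondent id
#'
#' @param path CSV file; first column (or a column named `respondent`) holds
#'   respondent ids, remaining columns are binary group memberships or
#'   continuous validators.
#' @return A data frame with a `respondent` column.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("respondent" %in% names(df))) names(df)[1L] <- "respondent"
  df$respondent <- as.character(df$respondent)
  df
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d respondents x %d items (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "coded"))) "coded" else "raw"))
  if ((attr(x, "n_excluded") %||% 0L) > 0L)
    cat(sprintf("  %d all-missing rows excluded at ingest\n",
                attr(x, "n_excluded")))
  invisible(x)
}

# Subsetting keeps the class and per-item attributes when columns survive.
#' @export
`[.response_matrix` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    nc <- attr(x, "n_categories")
    names(nc) <- colnames(unclass(x))
    out <- new_response_matrix(out, coded = attr(x, "coded"),
                               n_excluded = 0L,
                               n_categories = nc[colnames(out)])
  }
  out
}
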