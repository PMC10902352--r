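#' Construct a score table
#'
#' A score table is the package's basic data container: one row per data
#' point, holding an identifier, the probability `s` assigned by the external
#' inference model (consumed here purely as data), a fixed-length numeric
#' feature representation, and optionally a ground-truth class label and a
#' group tag for bias audits.
#'
#' @param features numeric matrix or data frame of features (one row per
#'   point); columns are stored as `f_1 ... f_d` unless already named with an
#'   `f_` prefix.
#' @param score optional numeric vector of probabilities in `[0, 1]` (the
#'   inference model's output). Required for "wild" deployment data; labelled
#'   reference or held-out pools may omit it.
#' @param label optional integer class labels in `{0, ..., c-1}`.
#' @param group optional character/factor group tags.
#' @param id optional character identifiers; defaults to `p1, p2, ...`.
#'   Must be unique.
#' @return A `score_table`, a `data.frame` with columns `id`, optionally
#'   `score`, feature columns `f_*`, and optionally `label` and `group`.
#' @examples
#' st <- score_table(matrix(rnorm(20), 10, 2), score = runif(10),
#'                   label = rep(0:1, 5))
#' nrow(st)
#' @export
score_table <- function(features, score = NULL, label = NULL, group = NULL,
                        id = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (is.null(colnames(features)) || !all(startsWith(colnames(features), "f_"))) {
    colnames(features) <- paste0("f_", seq_len(ncol(features)))
  }
  if (is.null(id)) id <- paste0("p", seq_len(n))
  df <- data.frame(id = as.character(id), stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  df <- cbind(df, as.data.frame(features))
  if (!is.null(label)) df$label <- as.integer(label)
  if (!is.null(group)) df$group <- as.character(group)
  validate_score_table(new_score_table(df))
}

new_score_table <- function(df) {
  class(df) <- c("score_table", "data.frame")
  df
}

#' Validate a score table
#'
#' Checks the container invariants: unique ids, scores inside `[0, 1]`,
#' finite features of identical length across records.
#'
#' @param x a `score_table` (or plain data frame with the same columns).
#' @return `x`, invisibly classed as `score_table`, or an error describing
#'   the offending rows.
#' @export
validate_score_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"id" %in% names(x)) stop("score table must have an `id` column")
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop("duplicate point ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if ("score" %in% names(x)) {
    s <- x$score
    bad <- which(!is.finite(s) | s < 0 | s > 1)
    if (length(bad)) {
      stop("scores outside [0, 1] (or non-numeric) at rows: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  fc <- feature_cols(x)
  if (length(fc) == 0L) stop("score table has no feature columns (prefix `f_`)")
  for (cc in fc) {
    if (!is.numeric(x[[cc]])) stop("feature column ", cc, " is not numeric")
  }
  if (!is.null(x$label) && any(!is.na(x$label) & x$label < 0)) {
    stop("labels must be non-negative class indices")
  }
  if (!inherits(x, "score_table")) x <- new_score_table(x)
  invisible(x)
}

feature_cols <- function(x) grep("^f_", names(x), value = TRUE)

#' Extract the feature matrix of a score table
#'
#' @param x a `score_table`.
#' @return numeric matrix, one row per point, columns in table order.
#' @export
feature_matrix <- function(x) {
  as.matrix(x[, feature_cols(x), drop = FALSE])
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table: %d points, %d features%s%s%s>\n",
              nrow(x), length(feature_cols(x)),
              if ("score" %in% names(x)) ", scored" else "",
              if ("label" %in% names(x)) ", labelled" else "",
              if ("group" %in% names(x)) ", grouped" else ""))
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# labelled pools must contain every class in 0:(n_classes-1)
check_classes_present <- function(x, n_classes, what = "pool") {
  if (is.null(x$label)) stop(what, " must carry ground-truth labels")
  missing <- setdiff(seq_len(n_classes) - 1L, unique(x$label))
  if (length(missing)) {
    stop(what, " is missing class(es): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
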