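#' Labelled feature dataset
#'
#' Bundles a numeric feature matrix (rows = samples) with one class label per
#' row and a fixed, ordered label alphabet. The alphabet is carried as the
#' factor levels of `y` and is preserved by subsetting even when a class
#' drops out of the subset — classifiers and the Venn machine rely on this to
#' keep class probabilities aligned.
#'
#' @param x numeric matrix or data frame of features, one row per sample.
#' @param y class labels, one per row of `x` (factor or character).
#' @param labels the ordered label alphabet. Defaults to the levels of `y`
#'   (factor input) or the sorted unique labels (character input).
#' @return An object of class `labeled_dataset`: a list with elements `x`
#'   (double matrix with row/column names) and `y` (factor).
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(12), 6), rep(c("A", "B"), each = 3))
#' class_labels(ds)
#' @export
labeled_dataset <- function(x, y, labels = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_input("features must be numeric")
  storage.mode(x) <- "double"
  if (is.null(labels)) {
    labels <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  }
  y <- factor(as.character(y), levels = labels)
  if (anyNA(y)) stop_input("found labels outside the declared alphabet")
  if (nrow(x) != length(y)) {
    stop_input("feature matrix has %d rows but %d labels given", nrow(x), length(y))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  structure(list(x = x, y = y), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d samples x %d features, %d classes (%s)\n",
    nrow(x$x), ncol(x$x), nlevels(x$y), paste(levels(x$y), collapse = ", ")
  ))
  print(table(x$y))
  invisible(x)
}

#' @rdname labeled_dataset
#' @param ds a `labeled_dataset`.
#' @param idx row indices (any form accepted by matrix subsetting).
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "labeled_dataset"))
  labeled_dataset(ds$x[idx, , drop = FALSE], ds$y[idx], labels = levels(ds$y))
}

#' @rdname labeled_dataset
#' @export
class_labels <- function(ds) levels(ds$y)

#' @export
as.data.frame.labeled_dataset <- function(x, ...) {
  out <- as.data.frame(x$x)
  out$label <- as.character(x$y)
  out
}
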