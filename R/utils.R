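`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise softmax with overflow guard
softmax <- function(scores) {
  e <- exp(scores - apply(scores, 1L, max))
  e / rowSums(e)
}

assert_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  invisible(m)
}

#' Stratified fold assignment
#'
#' Assigns samples to `folds` cross-validation folds so that each class is
#' split as evenly as possible across folds (per-fold class counts differ by
#' at most one sample from perfect proportionality).
#'
#' @param labels class label per sample (factor or vector).
#' @param folds number of folds.
#' @return integer fold id per sample, in `1..folds`.
#' @keywords internal
stratified_folds <- function(labels, folds) {
  labels <- as.factor(labels)
  if (any(table(labels) < folds))
    stop("every class needs at least as many samples as folds", call. = FALSE)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Significance stars by order of magnitude
#'
#' Maps a (typically BH-adjusted) p-value to a star annotation where one star
#' marks p <= 0.01, two stars p <= 0.001, and so on, one extra star per
#' further order of magnitude.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings ("" when p > 0.01).
#' @export
#' @examples
#' significance_stars(c(0.5, 0.01, 0.0005))
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi) || pi > 0.01) return("")
    n <- min(floor(-log10(max(pi, 1e-12))) - 1, 10)
    strrep("*", n)
  }, character(1))
}
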