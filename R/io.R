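#' Read a feature x sample abundance matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' `NA` and empty fields parse to missing. Duplicate feature or sample ids
#' and ragged rows are errors.
#'
#' @param path TSV file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_omics_matrix <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                      colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2) stop("no sample columns in ", path, call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature x sample matrix to TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path; the feature-id column is named `feature`.
#' @export
write_omics_matrix <- function(m, path) {
  assert_matrix(m)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format drug response table
#'
#' Three-column TSV (`sample`, `drug`, `auc`) to a sparse samples x drugs
#' matrix; pairs absent from the file are NA (not assayed).
#'
#' @param path TSV path.
#' @return samples x drugs numeric matrix.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, na.strings = c("NA", ""))
  if (!all(c("sample", "drug", "auc") %in% colnames(df)))
    stop("drug table needs columns sample, drug, auc", call. = FALSE)
  samples <- unique(df$sample)
  drugs <- unique(df$drug)
  m <- matrix(NA_real_, length(samples), length(drugs),
              dimnames = list(samples, drugs))
  m[cbind(match(df$sample, samples), match(df$drug, drugs))] <- df$auc
  m
}

#' Write a drug response matrix as a long-format TSV
#'
#' Only assayed (non-NA) entries are written.
#'
#' @param tab samples x drugs matrix.
#' @param path output path.
#' @export
write_drug_table <- function(tab, path) {
  assert_matrix(tab, "drug table")
  idx <- which(!is.na(tab), arr.ind = TRUE)
  df <- data.frame(sample = rownames(tab)[idx[, 1]],
                   drug = colnames(tab)[idx[, 2]],
                   auc = tab[idx])
  utils::write.table(df[order(df$drug, df$sample), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path TSV with a `sample` column (also used as rownames) and any
#'   covariate columns (`plex` is read as a factor).
#' @return data.frame with sample rownames.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, na.strings = c("NA", ""))
  if (!"sample" %in% colnames(df))
    stop("annotation needs a 'sample' column", call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in annotation", call. = FALSE)
  rownames(df) <- df$sample
  if ("plex" %in% colnames(df)) df$plex <- factor(df$plex)
  df
}
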