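#' @keywords internal
#' @useDynLib amsbiomarkers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) &&
    !is.null(rownames(x)) && !is.null(colnames(x)) &&
    !anyDuplicated(rownames(x)) && !anyDuplicated(colnames(x))
}

check_count_matrix <- function(x, allow_na = FALSE) {
  stop_if_not(is_count_matrix(x),
              "counts must be a numeric matrix with unique row (gene) and column (sample) names")
  vals <- x[!is.na(x)]
  stop_if_not(all(vals >= 0), "counts must be nonnegative")
  if (!allow_na) stop_if_not(!anyNA(x), "counts must not contain missing values")
  invisible(x)
}

#' Read or write a gene-by-sample count matrix as TSV
#'
#' Tab-separated, first column `gene`, remaining columns samples, header row of
#' sample identifiers. Missing (masked) entries serialize as `NA`.
#'
#' @param path file path.
#' @param counts numeric matrix with gene row names and sample column names.
#' @return `read_count_matrix` returns the matrix; `write_count_matrix` returns
#'   `path` invisibly.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 2, "count TSV needs a gene column plus at least one sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_count_matrix(m, allow_na = TRUE)
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample-metadata table as TSV
#'
#' Columns: `sample_id`, `cohort`, `subject_id`, `timepoint` (SL/HA), `sex`
#' (M/W), `ams_c`, and the derived `severe_ams` flag.
#'
#' @param path file path.
#' @param meta data frame as returned by [generate_study()].
#' @return `read_sample_meta` returns the data frame; `write_sample_meta`
#'   returns `path` invisibly.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "subject_id", "timepoint", "sex", "ams_c")
  stop_if_not(all(need %in% names(df)),
              "metadata TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$severe_ams)) df$severe_ams <- ams_severity(df$ams_c)
  df$severe_ams <- as.logical(df$severe_ams)
  df
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
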