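#' Protein abundance matrix with explicit missingness
#'
#' A light container for a proteins x samples abundance matrix. Missing cells
#' are stored as `NA`; raw TMT exports conventionally encode missing values as
#' zeros, which [zeros_to_missing()] converts. The `scale` attribute records
#' whether values are raw intensities or log2-transformed.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimensions must be named with unique ids.
#' @param scale `"raw"` (non-negative intensities) or `"log2"`.
#' @return an `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("`values` must have protein row names and sample column names.")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    rlang::abort("protein and sample ids must be unique.")
  }
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    rlang::abort("raw intensities must be non-negative where observed.")
  }
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<abundance_matrix> %d proteins x %d samples [%s scale], %.1f%% missing\n",
    nrow(x$values), ncol(x$values), x$scale,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' Missingness mask of an abundance matrix
#'
#' @param m an [abundance_matrix()].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  is.na(m$values)
}

#' @export
as_tibble.abundance_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id",
                        names_to = "sample_id", values_to = "value") |>
    dplyr::mutate(missing = is.na(.data$value), scale = x$scale)
}

#' @rdname abundance_matrix
#' @param x an `abundance_matrix`.
#' @param ... unused.
#' @export
tidy.abundance_matrix <- function(x, ...) as_tibble.abundance_matrix(x)

#' Read / write abundance matrices as TSV
#'
#' Plain-text round trip for the proteins x samples matrix. The first column
#' holds protein ids; remaining columns are samples. On the raw scale, zeros
#' are the conventional missing-value encoding and are written back as zeros.
#'
#' @param path file path.
#' @param scale scale flag recorded on the object read back.
#' @return [read_abundance()] returns an [abundance_matrix()];
#'   [write_abundance()] returns `path` invisibly.
#' @export
read_abundance <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  abundance_matrix(mat, scale = scale)
}

#' @rdname read_abundance
#' @param m an [abundance_matrix()] to write.
#' @param na_as value to write for missing cells (`0` matches the raw-intensity
#'   convention; use `"NA"` for log2 matrices).
#' @export
write_abundance <- function(m, path, na_as = if (m$scale == "raw") 0 else NA) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  if (!is.na(na_as) && is.numeric(na_as)) vals[is.na(vals)] <- na_as
  df <- data.frame(protein_id = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
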