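#' Read an expression study from TSV files
#'
#' The matrix file is a TSV with probe-set identifiers in the first column
#' and one column of log2 expression values per sample. The metadata file
#' has one row per sample with columns `sample_id`, `compound_id`,
#' `concentration_label`, `replicate`, `batch`, `is_control` and
#' `matched_controls` (comma-joined sample ids, empty when the sample is
#' normalized against the batch-wise control mean instead).
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return an `expression_study`: list with elements `matrix`
#'   (numeric matrix, probe sets x samples) and `samples` (data.frame).
#' @export
read_expression_study <- function(matrix_path, metadata_path) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE)
  probe_sets <- as.character(mat_df[[1]])
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- probe_sets
  storage.mode(mat) <- "double"

  samples <- utils::read.delim(metadata_path, check.names = FALSE,
                               colClasses = "character")
  samples$replicate <- as.integer(samples$replicate)
  samples$is_control <- as.logical(samples$is_control)
  if (!"matched_controls" %in% names(samples)) samples$matched_controls <- ""
  samples$matched_controls[is.na(samples$matched_controls)] <- ""

  validate_expression_study(new_expression_study(mat, samples))
}

new_expression_study <- function(mat, samples) {
  structure(list(matrix = mat, samples = samples), class = "expression_study")
}

#' Validate an expression study
#'
#' Checks that matrix and metadata describe the same sample set, that
#' probe-set identifiers are unique, that the matrix has no missing values
#' (errors name the offending cells), and that every non-control sample is
#' resolvable to controls either via `matched_controls` or via a batch
#' shared with at least one control sample.
#'
#' @param study an `expression_study`.
#' @return the study, invisibly validated (returned unchanged).
#' @export
validate_expression_study <- function(study) {
  mat <- study$matrix
  samples <- study$samples
  in_mat <- colnames(mat)
  in_meta <- samples$sample_id
  only_mat <- setdiff(in_mat, in_meta)
  only_meta <- setdiff(in_meta, in_mat)
  if (length(only_mat) || length(only_meta)) {
    stop("sample sets differ between matrix and metadata; ",
         "matrix-only: [", paste(only_mat, collapse = ", "), "] ",
         "metadata-only: [", paste(only_meta, collapse = ", "), "]")
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicated probe-set identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    idx <- utils::head(idx, 5)
    stop("missing expression values at: ",
         paste(sprintf("(%s, %s)", rownames(mat)[idx[, 1]],
                       colnames(mat)[idx[, 2]]), collapse = ", "))
  }
  # reorder metadata to match matrix columns
  samples <- samples[match(in_mat, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  control_ids <- samples$sample_id[samples$is_control]
  control_batches <- unique(samples$batch[samples$is_control])
  for (i in which(!samples$is_control)) {
    matched <- parse_id_list(samples$matched_controls[i])
    if (length(matched)) {
      bad <- setdiff(matched, control_ids)
      if (length(bad)) {
        stop("sample ", samples$sample_id[i],
             " lists unknown matched controls: ", paste(bad, collapse = ", "))
      }
    } else if (!samples$batch[i] %in% control_batches) {
      stop("sample ", samples$sample_id[i],
           " has no matched controls and no control in batch ", samples$batch[i])
    }
  }
  new_expression_study(mat, samples)
}

parse_id_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression_study()]; the round trip is the identity on
#' values and structure.
#'
#' @param study an `expression_study`.
#' @param matrix_path,metadata_path output paths.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path) {
  df <- data.frame(probe_set = rownames(study$matrix), study$matrix,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$matrix), "probe sets x",
      ncol(x$matrix), "samples (",
      sum(x$samples$is_control), "controls )\n")
  invisible(x)
}
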