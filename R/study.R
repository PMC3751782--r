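#' Timepoint labels of the standard four-condition design
#'
#' The default exposure/recovery design has four conditions: 5-day exposure
#' with 1-day recovery, 5-day exposure with 10-day recovery, 10-day exposure
#' with 1-day recovery and 10-day exposure with 42-day recovery. Conditions
#' are indexed 1..4 in this order. Other designs may relabel via the
#' \code{timepoint_labels} argument of [expression_study()].
#'
#' @export
DEFAULT_TIMEPOINTS <- c("5D-1D", "5D-10D", "10D-1D", "10D-42D")

#' Construct an ExpressionStudy
#'
#' An \code{ExpressionStudy} binds a log2 expression matrix (genes x samples)
#' to per-sample annotations: tissue, class (\code{"defeat"} or
#' \code{"control"}) and timepoint index. It is the container every pipeline
#' step consumes and produces.
#'
#' @param values numeric matrix, genes in rows, samples in columns. \code{NA}
#'   entries mark missing measurements (allowed before imputation).
#' @param samples data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{class}, \code{timepoint} (integer index, 1-based). One row per
#'   column of \code{values}, in the same order.
#' @param timepoint_labels character vector naming the condition indices;
#'   its length fixes the number of conditions in the design.
#' @return an object of class \code{ExpressionStudy} with components
#'   \code{values} (rownames = gene ids, colnames = sample ids),
#'   \code{samples} and \code{timepoint_labels}.
#' @export
expression_study <- function(values, samples,
                             timepoint_labels = DEFAULT_TIMEPOINTS) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "class", "timepoint")
  if (!all(req %in% names(samples)))
    stop("sample metadata must have columns ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("dimension mismatch: ", ncol(values), " sample columns but ",
         nrow(samples), " metadata rows")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(samples$class), c("defeat", "control"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  samples$timepoint <- as.integer(samples$timepoint)
  if (any(is.na(samples$timepoint)) ||
      any(samples$timepoint < 1L) ||
      any(samples$timepoint > length(timepoint_labels)))
    stop("timepoint indices must lie in 1..", length(timepoint_labels))
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, samples = samples,
         timepoint_labels = timepoint_labels),
    class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  tissues:   ", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  cat("  classes:   ",
      paste(sprintf("%s=%d", names(table(x$samples$class)),
                    table(x$samples$class)), collapse = ", "), "\n")
  cat("  conditions:", paste(x$timepoint_labels, collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  if (nm > 0) cat("  missing:   ", nm, "cells\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

#' Subset a study to one tissue
#'
#' @param study an [expression_study()].
#' @param tissue tissue label to keep.
#' @return an \code{ExpressionStudy} with only that tissue's samples.
#' @export
subset_tissue <- function(study, tissue) {
  keep <- study$samples$tissue == tissue
  if (!any(keep)) stop("no samples for tissue ", tissue)
  expression_study(study$values[, keep, drop = FALSE],
                   study$samples[keep, , drop = FALSE],
                   study$timepoint_labels)
}

#' Read an expression study from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' gene/probe ids in the first column. The metadata file is tab-separated
#' with columns \code{sample_id}, \code{tissue}, \code{class},
#' \code{timepoint}; timepoints may be given as integer indices or as labels
#' from \code{timepoint_labels}. Blank cells and \code{"NA"} in the matrix
#' are read as missing.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param timepoint_labels condition labels defining the design order.
#' @return an [expression_study()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            timepoint_labels = DEFAULT_TIMEPOINTS) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(mat[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", matrix_path)
  values <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  tp <- suppressWarnings(as.integer(meta$timepoint))
  lab <- match(meta$timepoint, timepoint_labels)
  meta$timepoint <- ifelse(is.na(tp), lab, tp)
  if (any(is.na(meta$timepoint)))
    stop("unknown timepoint label(s) in ", metadata_path)
  expression_study(values, meta, timepoint_labels)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression()]: a round trip reproduces the in-memory
#' object (missing cells are written as \code{NA}).
#'
#' @param study an [expression_study()].
#' @param matrix_path,metadata_path output file paths.
#' @export
write_expression <- function(study, matrix_path, metadata_path) {
  df <- data.frame(gene_id = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}
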