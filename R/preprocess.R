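#' Drop probes with too many missing values
#'
#' A probe is removed when strictly more than \code{max_missing_frac} of its
#' values are missing; a probe missing exactly half survives. Survivor order
#' is preserved.
#'
#' @param study an [expression_study()], possibly with \code{NA} cells.
#' @param max_missing_frac maximum tolerated missing fraction in [0, 1).
#' @return the filtered study, with attribute \code{n_dropped}.
#' @export
filter_missing <- function(study, max_missing_frac = 0.5) {
  if (max_missing_frac < 0 || max_missing_frac >= 1)
    stop("max_missing_frac must lie in [0, 1)")
  frac <- rowMeans(is.na(study$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("all probes removed by missing-value filter")
  out <- expression_study(study$values[keep, , drop = FALSE], study$samples,
                          study$timepoint_labels)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' K-nearest-neighbour imputation of missing cells
#'
#' Each missing cell of a probe is replaced by the plain mean of the values
#' of the k nearest probes at that sample, nearness measured by Euclidean
#' distance over the samples where both probes are observed (distances are
#' rescaled to a common number of coordinates). Neighbours must be observed
#' at the target sample. If fewer than k candidates exist, all available are
#' used with a warning.
#'
#' @param study an [expression_study()]; every probe must have at least one
#'   observed value.
#' @param k neighbour count (default 10).
#' @return the study with no missing cells; attribute \code{n_imputed}
#'   counts filled cells.
#' @export
knn_impute <- function(study, k = 10) {
  if (k < 1) stop("k must be >= 1")
  x <- study$values
  if (any(rowSums(!is.na(x)) == 0))
    stop("probe(s) with no observed values; run filter_missing first")
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss) == 0) return(study)
  need <- unique(miss[, "row"])
  warned <- FALSE
  for (i in need) {
    xi <- x[i, ]
    obs_i <- !is.na(xi)
    # squared distance over co-observed coords, scaled to full length
    co <- t(!is.na(x[, obs_i, drop = FALSE]))  # samples x probes, candidate obs
    d2 <- colSums((x[i, obs_i] - t(x[, obs_i, drop = FALSE]))^2 * co,
                  na.rm = TRUE)
    novl <- colSums(co)
    d2 <- ifelse(novl > 0, d2 / novl, Inf)
    d2[i] <- Inf
    for (jj in which(!obs_i)) {
      cand <- which(!is.na(x[, jj]) & is.finite(d2))
      if (!length(cand)) stop("no imputation donors for sample ",
                              colnames(x)[jj])
      if (length(cand) < k && !warned) {
        warning("fewer than k=", k, " donor probes available; using all")
        warned <- TRUE
      }
      nn <- cand[order(d2[cand], rownames(x)[cand])][seq_len(min(k,
                                                           length(cand)))]
      x[i, jj] <- mean(x[nn, jj])
    }
  }
  out <- expression_study(x, study$samples, study$timepoint_labels)
  attr(out, "n_imputed") <- nrow(miss)
  out
}

#' Quantile-normalize samples within each tissue
#'
#' Forces every sample in a tissue to share the same empirical distribution
#' (the across-sample mean of order statistics); ties receive the mean of
#' the corresponding reference quantiles. Normalization is applied to each
#' tissue separately. Idempotent up to floating tolerance.
#'
#' @param study an [expression_study()] with no missing values.
#' @return the normalized study.
#' @export
quantile_normalize <- function(study) {
  x <- study$values
  if (anyNA(x)) stop("missing values present; impute first")
  for (tis in unique(study$samples$tissue)) {
    cols <- which(study$samples$tissue == tis)
    if (length(cols) < 2) {
      warning("tissue ", tis, " has < 2 samples; left unchanged")
      next
    }
    x[, cols] <- limma::normalizeQuantiles(x[, cols, drop = FALSE],
                                           ties = TRUE)
  }
  expression_study(x, study$samples, study$timepoint_labels)
}

#' Aggregate sibling probes to genes
#'
#' Each gene's row is the arithmetic mean, per sample, of its probes
#' ("siblings"). Probes not present in the map are dropped with a warning.
#'
#' @param study an [expression_study()] keyed by probe ids.
#' @param probe_to_gene named character vector or two-column mapping
#'   (probe -> gene); each probe maps to at most one gene.
#' @return an [expression_study()] keyed by gene ids; attribute
#'   \code{n_unmapped} counts dropped probes.
#' @export
aggregate_probes <- function(study, probe_to_gene) {
  if (is.list(probe_to_gene) && !is.null(probe_to_gene$forward)) {
    if (any(lengths(probe_to_gene$forward) > 1))
      stop("a probe maps to more than one gene")
    probe_to_gene <- vapply(probe_to_gene$forward, `[[`, character(1), 1)
  }
  if (!length(probe_to_gene)) stop("empty probe-to-gene mapping")
  probes <- rownames(study$values)
  gene <- probe_to_gene[probes]
  unmapped <- is.na(gene)
  if (all(unmapped)) stop("no probe maps to a gene")
  if (any(unmapped))
    warning(sum(unmapped), " unmapped probe(s) dropped")
  x <- study$values[!unmapped, , drop = FALSE]
  g <- gene[!unmapped]
  agg <- rowsum(x, group = g)
  agg <- agg / as.vector(table(g)[rownames(agg)])
  agg <- agg[unique(g), , drop = FALSE]  # first-appearance order
  out <- expression_study(agg, study$samples, study$timepoint_labels)
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Run the full preprocessing pipeline
#'
#' filter -> impute -> quantile-normalize -> aggregate, the hygiene sequence
#' for processed microarray data. Each step is optional via its argument.
#'
#' @param study probe-level [expression_study()].
#' @param probe_to_gene optional probe -> gene map; when \code{NULL} the
#'   aggregation step is skipped (rows already gene-level).
#' @param max_missing_frac,k see [filter_missing()] and [knn_impute()].
#' @param log2_transform set \code{TRUE} if the input is on the linear
#'   scale (values are log2-transformed first).
#' @return list with \code{study} (processed) and \code{report}, a one-row
#'   data.frame with columns \code{n_probes_in}, \code{n_dropped_missing},
#'   \code{n_imputed_cells}, \code{n_genes_out}.
#' @export
preprocess_study <- function(study, probe_to_gene = NULL,
                             max_missing_frac = 0.5, k = 10,
                             log2_transform = FALSE) {
  n_in <- nrow(study$values)
  if (log2_transform)
    study <- expression_study(log2(study$values), study$samples,
                              study$timepoint_labels)
  study <- filter_missing(study, max_missing_frac)
  n_drop <- attr(study, "n_dropped")
  study <- knn_impute(study, k)
  n_imp <- attr(study, "n_imputed")
  if (is.null(n_imp)) n_imp <- 0L
  study <- quantile_normalize(study)
  if (!is.null(probe_to_gene))
    study <- aggregate_probes(study, probe_to_gene)
  report <- data.frame(n_probes_in = n_in, n_dropped_missing = n_drop,
                       n_imputed_cells = n_imp,
                       n_genes_out = nrow(study$values))
  list(study = study, report = report)
}
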