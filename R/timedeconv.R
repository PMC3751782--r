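#' Fit the per-gene time-deconvolution linear model
#'
#' Models each gene's log2 expression as an overall treatment (defeat)
#' effect plus an additive per-condition time effect:
#' \deqn{y = \alpha_{defeat} \cdot 1[\mathrm{class}=\mathrm{defeat}] +
#'       \beta_{j(\mathrm{sample})} + \varepsilon .}
#' Every sample contributes a row: a defeated sample in condition j has
#' design row (1, e_j), a control sample (0, e_j). The over-determined
#' system is solved per gene by ordinary least squares; the solution is
#' unique when every condition contains both classes. Note there is no
#' separate intercept: each condition's beta absorbs the gene's baseline.
#'
#' @param study an [expression_study()] (one tissue) with no missing values.
#' @return object of class \code{TimeDeconvFit}: list with
#'   \code{alpha} (named per-gene defeat effect, log2 units),
#'   \code{beta} (genes x conditions matrix of time effects),
#'   \code{residual_ss} (per-gene residual sum of squares),
#'   \code{conditions} (timepoint indices present), \code{gene_ids}.
#' @export
fit_time_model <- function(study) {
  y <- study$values
  if (anyNA(y)) stop("missing values present; impute first")
  tp <- study$samples$timepoint
  conds <- sort(unique(tp))
  defeat <- as.numeric(study$samples$class == "defeat")
  X <- cbind(defeat,
             vapply(conds, function(j) as.numeric(tp == j),
                    numeric(length(tp))))
  colnames(X) <- c("alpha_defeat", paste0("beta", conds))
  both <- vapply(conds, function(j)
    length(unique(study$samples$class[tp == j])) == 2, logical(1))
  xtx <- crossprod(X)
  if (all(both) && kappa(xtx) < 1e12) {
    coef <- t(solve(xtx, crossprod(X, t(y))))
  } else {
    warning("rank-deficient design (a condition lacks one class); ",
            "using minimum-norm least squares")
    coef <- t(pinv(X) %*% t(y))
  }
  fitted <- coef %*% t(X)
  rss <- rowSums((y - fitted)^2)
  structure(list(alpha = stats::setNames(coef[, 1], rownames(y)),
                 beta = coef[, -1, drop = FALSE],
                 residual_ss = rss,
                 conditions = conds,
                 gene_ids = rownames(y)),
            class = "TimeDeconvFit")
}

# Moore-Penrose pseudoinverse via SVD (minimum-norm least squares for
# rank-deficient designs).
pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.TimeDeconvFit <- function(x, ...) {
  cat("TimeDeconvFit:", length(x$alpha), "genes,",
      length(x$conditions), "conditions\n")
  cat("  alpha_defeat range: [", signif(min(x$alpha), 4), ",",
      signif(max(x$alpha), 4), "]\n")
  invisible(x)
}

#' Remove estimated time effects from an expression matrix
#'
#' Subtracts each sample's fitted per-condition effect
#' \eqn{\hat\beta_{i,j(\mathrm{sample})}} from gene i, leaving the
#' "time-standardized" matrix in which adjusted controls have expectation 0
#' and adjusted defeated samples expectation \eqn{\hat\alpha_i}. All
#' downstream classification runs on this matrix. Within-(class, condition)
#' variance is untouched (only a per-condition constant moves).
#'
#' @param study the study the fit was computed on.
#' @param fit a [fit_time_model()] result for the same genes.
#' @return the adjusted [expression_study()].
#' @export
adjust_expression <- function(study, fit) {
  if (!identical(fit$gene_ids, rownames(study$values)))
    stop("fit and study gene ids do not match")
  idx <- match(study$samples$timepoint, fit$conditions)
  if (anyNA(idx)) stop("study contains conditions absent from the fit")
  adj <- study$values - fit$beta[, idx, drop = FALSE]
  expression_study(adj, study$samples, study$timepoint_labels)
}

#' Average time curve: defeated-vs-control mean difference per timepoint
#'
#' For each gene i and timepoint t_j, the curve value is the difference of
#' mean log2 expression, defeated minus control — i.e. the log2 ratio of
#' the class geometric means on the linear scale. Timepoints missing either
#' class yield \code{NA}. Suitable for heat-map export of module expression
#' patterns over exposure/recovery conditions.
#'
#' @param study an [expression_study()] (one tissue).
#' @return numeric matrix, genes x timepoints, columns named by the study's
#'   timepoint labels.
#' @export
average_time_curve <- function(study) {
  tp <- study$samples$timepoint
  cls <- study$samples$class
  conds <- seq_along(study$timepoint_labels)
  out <- matrix(NA_real_, nrow(study$values), length(conds),
                dimnames = list(rownames(study$values),
                                study$timepoint_labels))
  for (j in conds) {
    d <- tp == j & cls == "defeat"
    c0 <- tp == j & cls == "control"
    if (!any(d) || !any(c0)) next
    out[, j] <- rowMeans(study$values[, d, drop = FALSE]) -
      rowMeans(study$values[, c0, drop = FALSE])
  }
  out
}
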