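#' Train a ridge-regularized linear discriminant classifier
#'
#' Two-class LDA on the pooled within-class covariance:
#' \deqn{w = (\Sigma_{pooled} + \lambda I)^{-1} (\mu_1 - \mu_0),}
#' with the intercept placed at the midpoint of the projected class means
#' so that scores x.w + b are positive toward class 1. A ridge is required
#' whenever the pooled covariance is singular (p close to or above n).
#'
#' @param features numeric matrix, samples x features.
#' @param labels logical or 0/1 vector (TRUE/1 = positive class).
#' @param ridge non-negative regularizer added to the diagonal.
#' @return list with \code{weights} and \code{intercept}.
#' @export
train_lda <- function(features, labels, ridge = 0) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (ridge < 0) stop("ridge must be >= 0")
  x1 <- features[labels, , drop = FALSE]
  x0 <- features[!labels, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  n <- nrow(features)
  p <- ncol(features)
  S <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x0, 2, mu0))) /
    max(n - 2, 1)
  Sr <- S + diag(ridge, p)
  w <- tryCatch(solve(Sr, mu1 - mu0), error = function(e)
    stop("singular pooled covariance; use ridge > 0"))
  b <- -sum(w * (mu1 + mu0)) / 2
  list(weights = as.numeric(w), intercept = b)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' AUC = U / (n1 n0): the fraction of (positive, negative) score pairs in
#' which the positive scores higher, ties counted one half.
#'
#' @param scores numeric per-sample scores.
#' @param labels logical or 0/1 vector (TRUE = positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Default ridge: 0.1 * trace(pooled covariance)/p, i.e. 10% of the average
# within-class feature variance (Friedman-style shrinkage magnitude). A
# much smaller ridge merely guarantees invertibility; near p ~ n it leaves
# the weight vector dominated by noise directions of the ill-conditioned
# covariance, which defeats weight-consensus ranking.
default_ridge <- function(features, labels) {
  labels <- as.logical(labels)
  v1 <- apply(features[labels, , drop = FALSE], 2, stats::var)
  v0 <- apply(features[!labels, , drop = FALSE], 2, stats::var)
  n1 <- sum(labels); n0 <- sum(!labels)
  tr <- sum(((n1 - 1) * v1 + (n0 - 1) * v0) / max(n1 + n0 - 2, 1))
  max(0.1 * tr / ncol(features), 1e-8)
}

# One stratified random train/test split (train_frac per class, >= 1 test
# sample per class guaranteed by flooring the train count at class size - 1).
stratified_split <- function(labels, train_frac) {
  labels <- as.logical(labels)
  idx1 <- which(labels); idx0 <- which(!labels)
  take <- function(idx) {
    ntr <- min(max(2L, round(train_frac * length(idx))), length(idx) - 1L)
    sample(idx, ntr)
  }
  train <- c(take(idx1), take(idx0))
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}

# Stratified random subsample of frac per class (>= 2 per class).
stratified_subsample <- function(labels, frac) {
  labels <- as.logical(labels)
  idx1 <- which(labels); idx0 <- which(!labels)
  take <- function(idx)
    sample(idx, min(max(2L, round(frac * length(idx))), length(idx)))
  sort(c(take(idx1), take(idx0)))
}

#' Evaluate one ensemble of LDA classifier groups
#'
#' Trains \code{n_groups * group_size} classifiers. With no test cohort,
#' each classifier uses an independent stratified random train/test split
#' of \code{features} and is scored on its held-out third. With
#' \code{test_features}/\code{test_labels} given (the cross-cohort mode
#' used for module validation: classifiers learn on the inference tissue
#' and are scored on the validation tissue), each classifier trains on a
#' stratified random subsample of \code{features} and is scored on an
#' independent stratified subsample of the test cohort; a feature that
#' does not genuinely transfer cannot earn a good score this way. Every
#' classifier records its test AUC, test 0/1 error at the LDA midpoint
#' threshold, and its unit-normalized absolute weight vector |w|/||w||2.
#' Features are ranked within each group by mean normalized weight
#' (rank 1 = largest).
#'
#' @param features samples x features matrix with column names.
#' @param labels logical/0-1 class vector.
#' @param n_groups,group_size ensemble shape (defaults 250 x 500).
#' @param train_frac training (and test-subsample) fraction per class
#'   (default 2/3).
#' @param ridge ridge for [train_lda()]; \code{NULL} = 0.1 tr(S)/p of each
#'   training split (10\% of the average within-class feature variance).
#' @param test_features,test_labels optional independent test cohort with
#'   the same feature columns.
#' @return list with \code{mean_auc}, \code{mean_error},
#'   \code{group_rank} (n_groups x p matrix of within-group feature ranks),
#'   \code{mean_weight} (per-feature grand mean normalized weight).
#' @export
ensemble_evaluate <- function(features, labels, n_groups = 250,
                              group_size = 500, train_frac = 2 / 3,
                              ridge = NULL, test_features = NULL,
                              test_labels = NULL) {
  labels <- as.logical(labels)
  if (nrow(features) < 4) stop("need >= 4 samples")
  p <- ncol(features)
  if (p < 1) stop("need >= 1 feature")
  cross <- !is.null(test_features)
  if (cross) {
    test_labels <- as.logical(test_labels)
    if (!identical(colnames(test_features), colnames(features)))
      stop("test cohort features do not match")
  }
  auc_sum <- 0
  err_sum <- 0
  group_rank <- matrix(NA_real_, n_groups, p,
                       dimnames = list(NULL, colnames(features)))
  wsum_all <- numeric(p)
  ident <- diag(p)
  for (g in seq_len(n_groups)) {
    wsum <- numeric(p)
    for (cfr in seq_len(group_size)) {
      if (cross) {
        tr_idx <- stratified_subsample(labels, train_frac)
        te_idx <- stratified_subsample(test_labels, train_frac)
        xtr <- features[tr_idx, , drop = FALSE]
        ytr <- labels[tr_idx]
        xte <- test_features[te_idx, , drop = FALSE]
        yte <- test_labels[te_idx]
      } else {
        sp <- stratified_split(labels, train_frac)
        xtr <- features[sp$train, , drop = FALSE]
        ytr <- labels[sp$train]
        xte <- features[sp$test, , drop = FALSE]
        yte <- labels[sp$test]
      }
      # inline ridge LDA (train_lda semantics, loop-optimized)
      x1 <- xtr[ytr, , drop = FALSE]
      x0 <- xtr[!ytr, , drop = FALSE]
      mu1 <- colMeans(x1); mu0 <- colMeans(x0)
      S <- (crossprod(x1) - nrow(x1) * tcrossprod(mu1) +
              crossprod(x0) - nrow(x0) * tcrossprod(mu0)) /
        max(nrow(xtr) - 2, 1)
      rdg <- if (is.null(ridge))
        max(0.1 * sum(diag(S)) / p, 1e-8) else ridge
      w <- solve(S + rdg * ident, mu1 - mu0)
      sc <- xte %*% w - sum(w * (mu1 + mu0)) / 2
      n1 <- sum(yte); n0 <- length(yte) - n1
      r <- rank(sc)
      auc_sum <- auc_sum + (sum(r[yte]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      err_sum <- err_sum + mean((sc > 0) != yte)
      nw <- abs(w)
      nrm <- sqrt(sum(nw^2))
      if (nrm > 0) wsum <- wsum + nw / nrm
    }
    # rank 1 = largest mean weight within the group
    group_rank[g, ] <- rank(-wsum, ties.method = "average")
    wsum_all <- wsum_all + wsum
  }
  ncls <- n_groups * group_size
  list(mean_auc = auc_sum / ncls,
       mean_error = err_sum / ncls,
       group_rank = group_rank,
       mean_weight = stats::setNames(wsum_all / ncls, colnames(features)))
}

#' Consensus feature elimination
#'
#' Repeatedly evaluates the classifier ensemble and removes one feature per
#' round until the ensemble mean AUC reaches \code{auc_threshold}. Each
#' group votes for its bottom-ranked feature (largest within-group rank);
#' the feature with the most votes is removed, ties broken by worse mean
#' rank across groups, then lexicographically. If the threshold is still
#' unmet when a single feature remains, the final set is empty (stop reason
#' \code{"exhausted"}); if the very first ensemble already clears the
#' threshold, nothing is removed. \code{min_eliminations} can force that
#' many removals before the threshold check is applied.
#'
#' @param features samples x features matrix with column names.
#' @param labels logical/0-1 class vector (must be binary).
#' @param auc_threshold stopping threshold in (0.5, 1].
#' @param n_groups,group_size,train_frac,ridge,test_features,test_labels
#'   see [ensemble_evaluate()]; a test cohort makes both the stopping AUC
#'   and the weight consensus cross-cohort.
#' @param min_eliminations minimum number of removal rounds (default 0).
#' @return object of class \code{EliminationTrace}: list with
#'   \code{final_features}, \code{stop_reason} ("auc_reached" or
#'   "exhausted"), \code{final_auc}, \code{final_error}, and \code{trace},
#'   a data.frame of per-round \code{n_features}, \code{mean_auc},
#'   \code{mean_error}, \code{removed}.
#' @export
eliminate_features <- function(features, labels, auc_threshold = 0.75,
                               n_groups = 250, group_size = 500,
                               train_frac = 2 / 3, ridge = NULL,
                               min_eliminations = 0, test_features = NULL,
                               test_labels = NULL) {
  labels <- as.logical(labels)
  if (length(unique(labels)) != 2) stop("labels must be binary")
  if (auc_threshold <= 0.5 || auc_threshold > 1)
    stop("auc_threshold must lie in (0.5, 1]")
  cur <- colnames(features)
  if (is.null(cur)) stop("features must have column names")
  trace <- list()
  removed_n <- 0L
  repeat {
    ev <- ensemble_evaluate(features[, cur, drop = FALSE], labels,
                            n_groups, group_size, train_frac, ridge,
                            test_features =
                              if (is.null(test_features)) NULL
                              else test_features[, cur, drop = FALSE],
                            test_labels = test_labels)
    step <- data.frame(n_features = length(cur), mean_auc = ev$mean_auc,
                       mean_error = ev$mean_error, removed = NA_character_,
                       stringsAsFactors = FALSE)
    if (ev$mean_auc >= auc_threshold && removed_n >= min_eliminations) {
      trace[[length(trace) + 1L]] <- step
      return(structure(list(final_features = cur,
                            stop_reason = "auc_reached",
                            final_auc = ev$mean_auc,
                            final_error = ev$mean_error,
                            trace = do.call(rbind, trace)),
                       class = "EliminationTrace"))
    }
    if (length(cur) == 1L) {
      trace[[length(trace) + 1L]] <- step
      return(structure(list(final_features = character(0),
                            stop_reason = "exhausted",
                            final_auc = ev$mean_auc,
                            final_error = ev$mean_error,
                            trace = do.call(rbind, trace)),
                       class = "EliminationTrace"))
    }
    # consensus vote: each group nominates its bottom-ranked feature
    worst <- apply(ev$group_rank, 1, which.max)
    votes <- tabulate(worst, nbins = length(cur))
    mean_rank <- colMeans(ev$group_rank)
    ord <- order(-votes, -mean_rank, cur)
    out_feat <- cur[ord[1]]
    step$removed <- out_feat
    trace[[length(trace) + 1L]] <- step
    cur <- setdiff(cur, out_feat)
    removed_n <- removed_n + 1L
  }
}

#' @export
print.EliminationTrace <- function(x, ...) {
  cat("EliminationTrace:", nrow(x$trace), "round(s),",
      length(x$final_features), "final feature(s), stop:",
      x$stop_reason, sprintf("(AUC %.3f)\n", x$final_auc))
  invisible(x)
}

#' Validate candidate modules in one validation tissue
#'
#' Regenerates every candidate's pathway-activity vector in the validation
#' tissue and runs [eliminate_features()]. With \code{inference_study}
#' given (the standard pipeline route), classifiers are trained on
#' resampled inference-tissue activities and the stopping AUC is evaluated
#' on resampled validation-tissue samples — a module survives only if the
#' discrimination it learned in the inference tissue transfers. Without an
#' inference study, elimination falls back to train/test splits within the
#' validation tissue alone. For reporting, the inference-tissue ensemble
#' (within-tissue held-out splits) is also evaluated on the surviving
#' features and the two AUCs averaged ("both tissues").
#'
#' @param candidates list of \code{CandidateModule} from
#'   [infer_candidates()].
#' @param validation_study time-standardized [expression_study()] of the
#'   validation tissue.
#' @param inference_study time-standardized inference study (training
#'   cohort and both-tissue report); optional.
#' @param auc_threshold,n_groups,group_size,train_frac,ridge,min_eliminations
#'   passed to [eliminate_features()].
#' @return list with \code{final_modules} (the surviving
#'   \code{CandidateModule}s), \code{mean_auc}, \code{mean_error}
#'   (both-tissue averages when \code{inference_study} given, else
#'   validation values), \code{validation_auc}, \code{validation_error},
#'   \code{trace}.
#' @export
validate_pair <- function(candidates, validation_study,
                          inference_study = NULL, auc_threshold = 0.75,
                          n_groups = 250, group_size = 500,
                          train_frac = 2 / 3, ridge = NULL,
                          min_eliminations = 0) {
  names(candidates) <- vapply(candidates, `[[`, character(1),
                              "pathway_name")
  std_val <- standardize(validation_study)
  acts <- lapply(candidates, function(m)
    suppressWarnings(compute_activity(std_val, m)))
  usable <- !vapply(acts, is.null, logical(1))
  if (!any(usable)) stop("no candidate is validatable in this tissue")
  feat_val <- do.call(cbind, acts[usable])
  colnames(feat_val) <- names(candidates)[usable]
  labels_val <- std_val$samples$class == "defeat"
  std_inf <- NULL
  if (!is.null(inference_study)) {
    std_inf <- standardize(inference_study)
    labels_inf <- std_inf$samples$class == "defeat"
    feat_inf <- do.call(cbind, lapply(candidates[colnames(feat_val)],
                                      function(m)
      suppressWarnings(compute_activity(std_inf, m))))
    colnames(feat_inf) <- colnames(feat_val)
    tr <- eliminate_features(feat_inf, labels_inf, auc_threshold,
                             n_groups, group_size, train_frac, ridge,
                             min_eliminations,
                             test_features = feat_val,
                             test_labels = labels_val)
  } else {
    tr <- eliminate_features(feat_val, labels_val, auc_threshold,
                             n_groups, group_size, train_frac, ridge,
                             min_eliminations)
  }
  final <- candidates[tr$final_features]
  mean_auc <- tr$final_auc
  mean_err <- tr$final_error
  if (!is.null(std_inf) && length(final)) {
    ev_inf <- ensemble_evaluate(
      feat_inf[, tr$final_features, drop = FALSE],
      labels_inf, n_groups, group_size, train_frac, ridge)
    mean_auc <- (tr$final_auc + ev_inf$mean_auc) / 2
    mean_err <- (tr$final_error + ev_inf$mean_error) / 2
  }
  list(final_modules = unname(final), mean_auc = mean_auc,
       mean_error = mean_err, validation_auc = tr$final_auc,
       validation_error = tr$final_error, trace = tr)
}
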