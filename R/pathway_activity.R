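#' Z-score each gene across samples
#'
#' Standardizes every gene to mean 0 and standard deviation 1 across
#' samples; constant genes map to all zeros with a warning. Idempotent.
#' Pathway activities built on standardized expression are invariant to
#' per-gene affine rescaling of the raw matrix.
#'
#' @param study an [expression_study()] with no missing values.
#' @return the standardized study.
#' @export
standardize <- function(study) {
  x <- study$values
  if (anyNA(x)) stop("missing values present")
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  zero <- sdev < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sum(zero), " constant gene(s) standardized to zero")
    sdev[zero] <- 1
  }
  z <- (x - mu) / sdev
  z[zero, ] <- 0
  expression_study(z, study$samples, study$timepoint_labels)
}

# t-statistic of a single activity vector between classes; moderated with a
# gene-ensemble prior (d0, s0_sq) when supplied, else plain pooled t.
activity_tstat <- function(y, is_defeat, prior = NULL) {
  n1 <- sum(is_defeat); n0 <- sum(!is_defeat)
  m1 <- mean(y[is_defeat]); m0 <- mean(y[!is_defeat])
  d <- n1 + n0 - 2
  s2 <- (sum((y[is_defeat] - m1)^2) + sum((y[!is_defeat] - m0)^2)) / d
  if (!is.null(prior) && is.finite(prior$d0)) {
    s2 <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  } else if (!is.null(prior) && is.infinite(prior$d0)) {
    s2 <- prior$s0_sq
  }
  if (s2 <= 0) return(0)
  (m1 - m0) / sqrt(s2 * (1 / n1 + 1 / n0))
}

#' Infer one CORG module from a pathway
#'
#' Greedy condition-responsive-genes search. Member genes present in the
#' matrix are ordered by their moderated t-score — descending for the "up"
#' direction, ascending for "down". The prefix grows one gene at a time;
#' the activity of a size-k prefix is the arithmetic mean of the k
#' standardized expressions, y_k = (x_1 + ... + x_k)/k, and gene k+1 is
#' accepted only if |t(y_{k+1})| strictly exceeds |t(y_k)|. Growth stops at
#' the first non-improvement or at \code{max_size} genes. Both directions
#' are run and the one whose final activity has the larger |t| is returned,
#' so the result always scores at least as well as its best single ordered
#' gene.
#'
#' The activity t-score is the plain pooled two-sample t of the activity
#' vector. (An empirical-Bayes prior fitted to single-gene variances is
#' deliberately not applied here: the variance of a k-gene average shrinks
#' with k, so gene-level shrinkage would erase exactly the gain that
#' justifies aggregation and freeze growth at one gene. Pass
#' \code{activity_prior} to moderate anyway.)
#'
#' @param std a [standardize()]d study.
#' @param de a [moderated_t_test()] result on the same study (supplies the
#'   gene ordering).
#' @param pathway_genes character vector; members absent from the matrix
#'   are ignored.
#' @param max_size module-size limit (default 25 genes).
#' @param pathway_name label carried into the result.
#' @param activity_prior optional list(d0, s0_sq) used to moderate the
#'   activity t-score; default \code{NULL} (plain pooled t).
#' @return object of class \code{CandidateModule}: list with
#'   \code{pathway_name}, \code{member_genes} (in order added),
#'   \code{direction} ("up"/"down"), \code{activity} (per-sample),
#'   \code{activity_t}.
#' @export
infer_corg_module <- function(std, de, pathway_genes, max_size = 25,
                              pathway_name = "pathway",
                              activity_prior = NULL) {
  present <- intersect(pathway_genes, rownames(std$values))
  if (!length(present)) stop("no pathway members present in the matrix")
  tvals <- stats::setNames(de$t_stat, de$gene_id)[present]
  is_defeat <- std$samples$class == "defeat"
  prior <- activity_prior
  grow <- function(ordered) {
    x <- std$values[ordered, , drop = FALSE]
    acc <- x[1, ]
    t_cur <- activity_tstat(acc, is_defeat, prior)
    k <- 1L
    while (k < min(length(ordered), max_size)) {
      cand <- (acc * k + x[k + 1L, ]) / (k + 1L)
      t_new <- activity_tstat(cand, is_defeat, prior)
      if (abs(t_new) > abs(t_cur)) {
        acc <- cand; t_cur <- t_new; k <- k + 1L
      } else break
    }
    list(genes = ordered[seq_len(k)], activity = acc, t = t_cur)
  }
  up <- grow(present[order(-tvals, present)])
  down <- grow(present[order(tvals, present)])
  pick <- if (abs(up$t) >= abs(down$t)) list(r = up, dir = "up")
          else list(r = down, dir = "down")
  structure(list(pathway_name = pathway_name,
                 member_genes = pick$r$genes,
                 direction = pick$dir,
                 activity = pick$r$activity,
                 activity_t = pick$r$t),
            class = "CandidateModule")
}

#' @export
print.CandidateModule <- function(x, ...) {
  cat(sprintf("CandidateModule '%s' (%s, %d genes, |t| = %.3f)\n",
              x$pathway_name, x$direction, length(x$member_genes),
              abs(x$activity_t)))
  invisible(x)
}

#' Infer and rank candidate modules from an inference tissue
#'
#' Runs [infer_corg_module()] on every pathway with between
#' \code{min_size} and \code{max_pathway_size} members in the matrix
#' (filtering out bulky pathways), drops modules with identical member-gene
#' sets keeping the larger |t|, and returns the \code{top_k} modules by
#' absolute activity t-score.
#'
#' @param study the time-standardized [expression_study()] of the inference
#'   tissue (standardization is applied internally).
#' @param pathways named list of gene sets.
#' @param top_k number of candidates kept (default 100).
#' @param max_size per-module gene cap, see [infer_corg_module()].
#' @param min_size,max_pathway_size pathway filter on members present.
#' @param de optional precomputed [moderated_t_test()] result.
#' @return list of \code{CandidateModule}, sorted by |t| non-increasing.
#' @export
infer_candidates <- function(study, pathways, top_k = 100, max_size = 25,
                             min_size = 3, max_pathway_size = 200,
                             de = NULL) {
  if (is.null(de)) de <- moderated_t_test(study)
  std <- standardize(study)
  n_present <- vapply(pathways, function(m)
    length(intersect(m, rownames(std$values))), integer(1))
  keep <- n_present >= min_size & n_present <= max_pathway_size
  pathways <- pathways[keep]
  if (!length(pathways)) stop("no pathway passes the size filter")
  mods <- lapply(names(pathways), function(nm)
    infer_corg_module(std, de, pathways[[nm]], max_size, nm))
  # deduplicate identical member sets, keep the larger |t|
  key <- vapply(mods, function(m)
    paste(sort(m$member_genes), collapse = "\r"), character(1))
  ord <- order(-abs(vapply(mods, `[[`, numeric(1), "activity_t")),
               vapply(mods, `[[`, character(1), "pathway_name"))
  mods <- mods[ord][!duplicated(key[ord])]
  if (length(mods) < top_k)
    warning("only ", length(mods), " candidate modules available (< top_k)")
  mods[seq_len(min(top_k, length(mods)))]
}

#' Regenerate a module's activity in a validation tissue
#'
#' The pathway activity is the mean of the standardized expressions of the
#' module's member genes that are present in the validation matrix; absent
#' members are dropped with a warning. When no member is present the module
#' is unvalidatable and \code{NULL} is returned.
#'
#' @param std_validation a [standardize()]d validation study.
#' @param module a \code{CandidateModule}.
#' @return numeric per-sample activity vector with attributes
#'   \code{direction} and \code{genes_used}, or \code{NULL}.
#' @export
compute_activity <- function(std_validation, module) {
  present <- intersect(module$member_genes, rownames(std_validation$values))
  if (!length(present)) {
    warning("module '", module$pathway_name,
            "' has no genes in the validation matrix; unvalidatable")
    return(NULL)
  }
  if (length(present) < length(module$member_genes))
    warning(length(module$member_genes) - length(present),
            " module gene(s) absent from the validation matrix; dropped")
  pa <- colMeans(std_validation$values[present, , drop = FALSE])
  attr(pa, "direction") <- module$direction
  attr(pa, "genes_used") <- present
  pa
}

#' Candidate-module table
#'
#' @param modules list of \code{CandidateModule}.
#' @return data.frame with pathway, ordered comma-joined genes, direction,
#'   |t| and rank.
#' @export
candidate_table <- function(modules) {
  data.frame(
    pathway = vapply(modules, `[[`, character(1), "pathway_name"),
    genes = vapply(modules, function(m)
      paste(m$member_genes, collapse = ","), character(1)),
    n_genes = vapply(modules, function(m)
      length(m$member_genes), integer(1)),
    direction = vapply(modules, `[[`, character(1), "direction"),
    abs_t = abs(vapply(modules, `[[`, numeric(1), "activity_t")),
    rank = seq_along(modules),
    stringsAsFactors = FALSE)
}
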