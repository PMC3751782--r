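#' Moderated two-sample t-test (defeat vs control)
#'
#' A two-sample t-statistic whose per-gene variance is shrunk toward an
#' empirical-Bayes prior shared across genes. Per gene, the pooled sample
#' variance s^2 with d = n1 + n0 - 2 degrees of freedom is combined with a
#' prior (d0, s0^2) estimated by moment matching on the log variances:
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and the moderated statistic
#' \eqn{\tilde t = \bar y_1 - \bar y_0 \, / \, (\tilde s
#' \sqrt{1/n_1 + 1/n_0})} is referred to a t distribution on d + d0 degrees
#' of freedom (two-sided). With d0 = 0 this is the ordinary pooled t; as
#' d0 grows every gene's variance tends to s0^2.
#'
#' For "across all timepoints" analyses the input should be the
#' time-standardized matrix from [adjust_expression()].
#'
#' @param study an [expression_study()] with >= 2 samples per class and no
#'   missing values.
#' @param moderated set \code{FALSE} for the ordinary pooled-variance t.
#' @return object of class \code{DEResult}: data.frame with per-gene
#'   \code{gene_id}, \code{mean_diff} (defeat - control, log2),
#'   \code{t_stat}, \code{p_value}, \code{rank} (1 = most significant; ties
#'   broken by |t| then gene id); attributes \code{d0}, \code{s0_sq},
#'   \code{df_total}.
#' @export
moderated_t_test <- function(study, moderated = TRUE) {
  x <- study$values
  if (anyNA(x)) stop("missing values present")
  g1 <- study$samples$class == "defeat"
  g0 <- study$samples$class == "control"
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per class")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m0 <- rowMeans(x[, g0, drop = FALSE])
  v1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  v0 <- rowSums((x[, g0, drop = FALSE] - m0)^2)
  d <- n1 + n0 - 2
  s2 <- (v1 + v0) / d
  if (moderated) {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0
    s0 <- prior$s0_sq
    if (is.infinite(d0)) {
      s2_tilde <- rep(s0, length(s2))
    } else {
      s2_tilde <- (d0 * s0 + d * s2) / (d0 + d)
    }
  } else {
    d0 <- 0
    s0 <- NA_real_
    s2_tilde <- s2
  }
  if (any(s2_tilde == 0))
    stop("zero moderated variance (all genes constant?); cannot form t")
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n0))
  tstat <- (m1 - m0) / se
  df <- d + d0
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  gene_id <- rownames(x)
  ord <- order(p, -abs(tstat), gene_id)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  out <- data.frame(gene_id = gene_id, mean_diff = m1 - m0, t_stat = tstat,
                    p_value = p, rank = rk, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0
  attr(out, "df_total") <- df
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Estimate the empirical-Bayes variance prior by moment matching
#'
#' Fits the scaled-F model s^2 ~ s0^2 F(d, d0) by matching the first two
#' moments of log s^2: with z = log s^2 and
#' e = z - digamma(d/2) + log(d/2), one has
#' E[e] = log s0^2 - digamma(d0/2) + log(d0/2) and
#' Var[e] = trigamma(d/2) + trigamma(d0/2), so d0 solves
#' trigamma(d0/2) = Var[e] - trigamma(d/2) (by Newton iteration on the
#' trigamma inverse) and s0^2 follows from the mean. When the empirical
#' variance of e does not exceed trigamma(d/2), d0 is infinite and
#' s0^2 = exp(mean(e)).
#'
#' @param s2 per-gene sample variances (zeros are ignored in the fit).
#' @param d residual degrees of freedom of each s2.
#' @return list with \code{d0} (prior degrees of freedom, possibly
#'   \code{Inf}) and \code{s0_sq} (prior variance).
#' @export
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) stop("all sample variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1)
  excess <- evar - trigamma(d / 2)
  if (n < 2 || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x by Newton's method on 1/trigamma (convex, monotone).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Call differentially expressed genes
#'
#' @param de a [moderated_t_test()] result.
#' @param alpha significance threshold; genes with p <= alpha (inclusive)
#'   are called.
#' @return character vector of DEG ids, with attribute \code{n} (the count).
#' @export
call_degs <- function(de, alpha = 0.05) {
  genes <- de$gene_id[de$p_value <= alpha]
  attr(genes, "n") <- length(genes)
  genes
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability (including the observed value) of drawing at
#' least the observed overlap when \code{n_b} genes are drawn from a
#' universe of N containing \code{n_a} marked genes — identical to a
#' one-sided Fisher exact test on the 2x2 table.
#'
#' @param set_a,set_b character vectors, subsets of \code{universe}.
#' @param universe character vector of all genes assayed in both analyses.
#' @return data.frame (one row) with \code{n_universe}, \code{n_set_a},
#'   \code{n_set_b}, \code{n_overlap}, \code{p_value}.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  N <- length(universe)
  na <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, na, N - na, nb, lower.tail = FALSE)
  data.frame(n_universe = N, n_set_a = na, n_set_b = nb, n_overlap = k,
             p_value = p)
}
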