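# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A minimal study: `values` may be a matrix or n_genes/n_samples to draw
# standard normal data. Classes alternate defeat/control unless given.
make_study <- function(values, class = NULL, timepoint = NULL,
                       tissue = "A", timepoint_labels = NULL) {
  if (is.null(dim(values))) {
    values <- matrix(stats::rnorm(prod(values)), values[1], values[2])
  }
  ng <- nrow(values); ns <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", 1:ng)
  if (is.null(class)) class <- rep(c("defeat", "control"), length.out = ns)
  if (is.null(timepoint)) timepoint <- rep(1L, ns)
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("T", seq_len(max(timepoint)))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:ns), tissue = tissue,
                     class = class, timepoint = timepoint,
                     stringsAsFactors = FALSE)
  expression_study(values, meta, timepoint_labels)
}

# Balanced four-condition study from the additive generative model,
# returning study plus the generating parameters.
make_timecourse <- function(n_genes = 20, n_per_cell = 3, alpha = NULL,
                            beta = NULL, sigma = 0, seed = 1) {
  set.seed(seed)
  if (is.null(alpha)) alpha <- stats::rnorm(n_genes, 0, 1)
  if (is.null(beta)) beta <- matrix(stats::rnorm(n_genes * 4, 0, 0.5),
                                    n_genes, 4)
  tp <- rep(1:4, each = 2 * n_per_cell)
  cls <- rep(rep(c("defeat", "control"), each = n_per_cell), 4)
  mu <- beta[, tp, drop = FALSE] +
    outer(alpha, as.numeric(cls == "defeat"))
  vals <- mu + matrix(stats::rnorm(n_genes * length(tp), 0, sigma),
                      n_genes)
  rownames(vals) <- sprintf("g%03d", 1:n_genes)
  st <- make_study(vals, class = cls, timepoint = tp,
                   timepoint_labels = coremod::DEFAULT_TIMEPOINTS)
  list(study = st, alpha = alpha, beta = beta)
}

# Plain pooled two-sample t, written independently of the package.
pooled_t <- function(y, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  m1 <- mean(y[is_pos]); m0 <- mean(y[!is_pos])
  s2 <- (sum((y[is_pos] - m1)^2) + sum((y[!is_pos] - m0)^2)) /
    (n1 + n0 - 2)
  (m1 - m0) / sqrt(s2 * (1 / n1 + 1 / n0))
}

# Brute-force prefix-scan CORG oracle: every prefix activity is recomputed
# from scratch with colMeans; the strict-improvement stop rule is applied
# along each direction's ordering and the better direction returned.
corg_oracle <- function(std, de, genes, max_size = 25) {
  genes <- intersect(genes, rownames(std$values))
  tv <- stats::setNames(de$t_stat, de$gene_id)[genes]
  is_pos <- std$samples$class == "defeat"
  best <- NULL
  for (ord in list(genes[order(-tv, genes)], genes[order(tv, genes)])) {
    prev <- -Inf; sel <- NULL
    for (k in seq_len(min(length(ord), max_size))) {
      y <- colMeans(std$values[ord[1:k], , drop = FALSE])
      tk <- abs(pooled_t(y, is_pos))
      if (tk > prev) { prev <- tk; sel <- ord[1:k] } else break
    }
    if (is.null(best) || prev > best$t) best <- list(genes = sel, t = prev)
  }
  best
}

# Feature matrix with `n_signal` planted informative columns (class shift
# `delta` in units of the unit noise sd).
make_feature_matrix <- function(n_per_class = 10, n_features = 50,
                                n_signal = 3, delta = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, sprintf("f%02d", 1:n_features)))
  labels <- rep(c(TRUE, FALSE), each = n_per_class)
  if (n_signal > 0)
    x[labels, seq_len(n_signal)] <- x[labels, seq_len(n_signal)] + delta
  list(features = x, labels = labels,
       signal = colnames(x)[seq_len(n_signal)])
}

# Minimal CandidateModule for core/network tests.
make_module <- function(pathway, genes, direction = "up", t = 3) {
  structure(list(pathway_name = pathway, member_genes = genes,
                 direction = direction, activity = NULL, activity_t = t),
            class = "CandidateModule")
}
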