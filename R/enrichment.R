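#' iGA PC-value of a gene group in a ranked list
#'
#' Iterative Group Analysis score: with the group's member ranks sorted
#' ascending (r_1 < ... < r_n out of N genes), the j-th cutoff probability
#' is the hypergeometric upper tail
#' \deqn{PC(j) = P(X \ge j), \quad X \sim \mathrm{Hypergeom}(N, n, r_j),}
#' i.e. the chance that a random size-n group places at least j members in
#' the top r_j ranks. The score is the minimum over j; it depends only on
#' member ranks, so it is invariant to monotone transforms of the
#' underlying statistic.
#'
#' @param ranks distinct member positions in 1..N.
#' @param N total number of ranked genes.
#' @return list with \code{pc} (the minimum PC-value, in (0,1]) and
#'   \code{j_min} (the minimizing member count, the "number of significant
#'   genes").
#' @export
iga_pc_value <- function(ranks, N) {
  n <- length(ranks)
  if (n < 1) stop("empty group")
  if (anyDuplicated(ranks)) stop("duplicate ranks")
  if (any(ranks < 1) || any(ranks > N)) stop("ranks must lie in 1..N")
  r <- sort(as.integer(ranks))
  j <- seq_len(n)
  pc <- stats::phyper(j - 1, n, N - n, r, lower.tail = FALSE)
  jm <- which.min(pc)
  list(pc = pc[jm], j_min = jm)
}

# Shared machinery: observed and permuted iGA scores for one gene set.
# ranked_genes: character vector, most significant first.
# Returns NULL when the set has no members in the universe.
.iga_observed <- function(members, ranked_genes) {
  pos <- which(ranked_genes %in% members)
  if (!length(pos)) return(NULL)
  iga_pc_value(pos, length(ranked_genes))
}

# Best sub-pathway score: iGA over prefixes of the s most significant
# members, s in sizes (clipped to the member count).
.subpath_best <- function(member_ranks, N, sizes) {
  r <- sort(member_ranks)
  smax <- min(max(sizes), length(r))
  best <- list(pc = Inf, size = NA_integer_, j_min = NA_integer_)
  for (s in sizes[sizes <= smax]) {
    sc <- iga_pc_value(r[seq_len(s)], N)
    if (sc$pc < best$pc)
      best <- list(pc = sc$pc, size = s, j_min = sc$j_min)
  }
  best
}

#' iGA enrichment of GO terms with a permutation null
#'
#' Terms with at most \code{max_size} member genes present in the ranked
#' universe are scored by [iga_pc_value()] on the observed gene order
#' (most significant first). Significance comes from a null of random
#' permutations of the gene order (under which a term's member positions
#' are a uniform random subset of ranks, which is how the null is drawn);
#' the permutation p-value uses the add-one convention p = (1 + b)/(1 + B)
#' where b counts
#' permuted scores <= observed, so its resolution floor is
#' 1/(n_perm + 1). BH FDR is computed across tested terms. Terms with
#' p <= 0.05 are the differentially expressed GO terms (DEGOs).
#'
#' @param de a [moderated_t_test()] result defining the ranking.
#' @param go named list: term -> character vector of member genes.
#' @param max_size maximum term size (members in universe) tested.
#' @param n_perm number of permutations of the gene order.
#' @param seed RNG seed for the permutation null.
#' @return data.frame with \code{set_name}, \code{n_members},
#'   \code{iga_score}, \code{n_sig_genes}, \code{perm_p}, \code{fdr},
#'   \code{significant} (perm_p <= 0.05), \code{marginal}
#'   (perm_p <= 0.1), sorted by perm_p.
#' @export
analyze_go_terms <- function(de, go, max_size = 100, n_perm = 1000,
                             seed = 1L) {
  ranked <- de$gene_id[order(de$rank)]
  N <- length(ranked)
  sizes <- vapply(go, function(m) sum(m %in% ranked), integer(1))
  keep <- sizes >= 1 & sizes <= max_size
  if (any(!keep))
    message(sum(!keep), " term(s) skipped (0 members or > ", max_size,
            " members in universe)")
  go <- go[keep]
  if (!length(go)) stop("no testable terms")
  set.seed(seed)
  res <- lapply(names(go), function(nm) {
    obs <- .iga_observed(go[[nm]], ranked)
    n <- sum(go[[nm]] %in% ranked)
    # permuting the gene order makes member positions a uniform random
    # size-n subset of 1..N
    b <- 0L
    for (p in seq_len(n_perm)) {
      sc <- iga_pc_value(sample.int(N, n), N)
      if (sc$pc <= obs$pc) b <- b + 1L
    }
    data.frame(set_name = nm, n_members = n, iga_score = obs$pc,
               n_sig_genes = obs$j_min,
               perm_p = (1 + b) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$perm_p)
  out$significant <- out$perm_p <= 0.05
  out$marginal <- out$perm_p <= 0.1
  out[order(out$perm_p, out$set_name), , drop = FALSE]
}

#' Best sub-pathway iGA enrichment with a selection-adjusted permutation null
#'
#' For each pathway with at least \code{min(sizes)} members in the universe,
#' iGA is run on the s most significant member genes for every sub-pathway
#' size s (default 3..10) and the best (smallest) score kept. The
#' permutation null re-applies the same best-over-sizes selection on each
#' permuted gene order, so the reported p-value accounts for the selection
#' step. Pathways with p <= 0.05 are the DEPATHs.
#'
#' @param de a [moderated_t_test()] result defining the ranking.
#' @param pathways named list: pathway -> member genes.
#' @param sizes sub-pathway sizes scanned (default 3:10).
#' @param n_perm,seed permutation null settings as in [analyze_go_terms()].
#' @return data.frame with \code{set_name}, \code{n_members},
#'   \code{iga_score}, \code{n_sig_genes} (members at the minimizing rank
#'   cutoff of the best sub-pathway), \code{best_subpathway_size},
#'   \code{perm_p}, \code{fdr}, \code{significant}, \code{marginal},
#'   sorted by perm_p.
#' @export
analyze_subpathways <- function(de, pathways, sizes = 3:10, n_perm = 1000,
                                seed = 1L) {
  ranked <- de$gene_id[order(de$rank)]
  N <- length(ranked)
  smin <- min(sizes)
  counts <- vapply(pathways, function(m) sum(m %in% ranked), integer(1))
  keep <- counts >= smin
  if (any(!keep))
    message(sum(!keep), " pathway(s) skipped (< ", smin,
            " members in universe)")
  pathways <- pathways[keep]
  if (!length(pathways)) stop("no testable pathways")
  set.seed(seed)
  res <- lapply(names(pathways), function(nm) {
    n <- sum(pathways[[nm]] %in% ranked)
    pos <- which(ranked %in% pathways[[nm]])
    obs <- .subpath_best(pos, N, sizes)
    b <- 0L
    for (p in seq_len(n_perm)) {
      sc <- .subpath_best(sample.int(N, n), N, sizes)
      if (sc$pc <= obs$pc) b <- b + 1L
    }
    data.frame(set_name = nm, n_members = n, iga_score = obs$pc,
               n_sig_genes = obs$j_min, best_subpathway_size = obs$size,
               perm_p = (1 + b) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$perm_p)
  out$significant <- out$perm_p <= 0.05
  out$marginal <- out$perm_p <= 0.1
  out[order(out$perm_p, out$set_name), , drop = FALSE]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up transform: with p-values sorted ascending,
#' q_(i) = min over k >= i of m p_(k) / k, capped at 1, mapped back to the
#' input order. Output is monotone along sorted p and each q >= its p.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Overlap significance of enriched sets between two analyses
#'
#' Hypergeometric upper-tail test on the significant-term sets of two
#' enrichment analyses run on the same collection; the universe is the
#' number of tested terms.
#'
#' @param res_a,res_b results of [analyze_go_terms()] or
#'   [analyze_subpathways()] over the same collection.
#' @param alpha significance threshold defining each analysis's enriched
#'   set.
#' @return the [overlap_test()] data.frame.
#' @export
overlap_enriched <- function(res_a, res_b, alpha = 0.05) {
  if (!setequal(res_a$set_name, res_b$set_name))
    stop("the two analyses tested different collections")
  universe <- res_a$set_name
  overlap_test(res_a$set_name[res_a$perm_p <= alpha],
               res_b$set_name[res_b$perm_p <= alpha],
               universe)
}
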