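#' Identify core modules across validation tissues
#'
#' A validated module is core when it appears, with the same pathway name
#' and exact member-gene set, in at least \code{ceil(min_frac * V)} of the
#' V validation sets ("at least half" by default, so 4 of 7 qualifies and
#' 3 of 7 does not). Order of the validation sets and duplicate entries
#' within one set do not matter.
#'
#' @param final_sets named list (one element per validation tissue) of
#'   lists of \code{CandidateModule}.
#' @param min_frac support fraction (default 0.5).
#' @return list of core modules; each carries an extra field
#'   \code{supporting_tissues}.
#' @export
identify_core_modules <- function(final_sets, min_frac = 0.5) {
  V <- length(final_sets)
  if (V < 1) stop("need >= 1 validation set")
  need <- ceiling(min_frac * V)
  if (is.null(names(final_sets)))
    names(final_sets) <- paste0("validation", seq_len(V))
  key_of <- function(m) paste(m$pathway_name,
                              paste(sort(m$member_genes), collapse = ","),
                              sep = "|")
  support <- list()
  modules <- list()
  for (tis in names(final_sets)) {
    seen <- character(0)
    for (m in final_sets[[tis]]) {
      k <- key_of(m)
      if (k %in% seen) next  # duplicates within one set count once
      seen <- c(seen, k)
      support[[k]] <- union(support[[k]], tis)
      modules[[k]] <- m
    }
  }
  core_keys <- names(support)[lengths(support) >= need]
  core_keys <- sort(core_keys)
  lapply(core_keys, function(k) {
    m <- modules[[k]]
    m$supporting_tissues <- sort(support[[k]])
    m
  })
}

#' Number of distinct core genes
#'
#' @param core list of core modules.
#' @return size of the union of member genes.
#' @export
count_core_genes <- function(core) {
  length(unique(unlist(lapply(core, `[[`, "member_genes"))))
}

#' Project core modules onto a protein-protein interaction network
#'
#' Induces the PPI subgraph on the union of core-module genes. An edge is
#' labeled \code{within_module} when its two endpoints share at least one
#' module (even if either gene also belongs to other modules), otherwise
#' \code{between_module}. Genes without any edge are kept as isolated
#' nodes. Node annotation \code{alpha} is the gene's treatment effect from
#' the inference-tissue time-model fit, when supplied.
#'
#' @param core list of core modules ([identify_core_modules()]).
#' @param ppi edge list from [read_ppi()].
#' @param fit optional [fit_time_model()] of the inference tissue, for node
#'   expression annotation.
#' @param inference_tissue optional label recorded on nodes.
#' @return object of class \code{CoreModuleNetwork}: list with
#'   \code{nodes} (gene, modules, alpha, inference_tissue), \code{edges}
#'   (gene_a, gene_b, score, label) and \code{modules} (id, pathway,
#'   genes, direction, supporting tissues).
#' @export
project_onto_ppi <- function(core, ppi, fit = NULL,
                             inference_tissue = NA_character_) {
  genes <- unique(unlist(lapply(core, `[[`, "member_genes")))
  membership <- lapply(stats::setNames(genes, genes), function(g)
    which(vapply(core, function(m) g %in% m$member_genes, logical(1))))
  keep <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
  edges <- ppi[keep, , drop = FALSE]
  if (nrow(edges)) {
    shared <- mapply(function(a, b)
      length(intersect(membership[[a]], membership[[b]])) > 0,
      edges$gene_a, edges$gene_b)
    edges$label <- ifelse(shared, "within_module", "between_module")
  } else {
    edges$label <- character(0)
  }
  rownames(edges) <- NULL
  alpha <- if (!is.null(fit))
    as.numeric(fit$alpha[genes]) else rep(NA_real_, length(genes))
  nodes <- data.frame(
    gene = genes,
    modules = vapply(membership[genes], function(ix)
      paste(ix, collapse = ","), character(1)),
    alpha = alpha,
    inference_tissue = inference_tissue,
    stringsAsFactors = FALSE)
  mod_tab <- data.frame(
    id = seq_along(core),
    pathway = vapply(core, `[[`, character(1), "pathway_name"),
    genes = vapply(core, function(m)
      paste(m$member_genes, collapse = ","), character(1)),
    direction = vapply(core, `[[`, character(1), "direction"),
    supporting_tissues = vapply(core, function(m)
      paste(m$supporting_tissues %||% character(0), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, modules = mod_tab),
            class = "CoreModuleNetwork")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.CoreModuleNetwork <- function(x, ...) {
  cat("CoreModuleNetwork:", nrow(x$modules), "core module(s),",
      nrow(x$nodes), "gene(s),", nrow(x$edges), "edge(s) (",
      sum(x$edges$label == "within_module"), "within /",
      sum(x$edges$label == "between_module"), "between )\n")
  invisible(x)
}

#' Write a core-module network as JSON
#'
#' Nodes carry gene id, module memberships, inference tissue and the
#' treatment-effect annotation; edges carry endpoints, confidence score and
#' the within/between label.
#'
#' @param network a [project_onto_ppi()] result.
#' @param path output JSON path.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(modules = network$modules, nodes = network$nodes,
         edges = network$edges),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  invisible(network)
}

#' Connected components and degree summary of a core network
#'
#' Convenience wrapper over igraph for downstream inspection.
#'
#' @param network a [project_onto_ppi()] result.
#' @return igraph graph with vertex attribute \code{modules} and edge
#'   attribute \code{label}.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b", "score", "label")],
    directed = FALSE,
    vertices = network$nodes[, c("gene", "modules", "alpha")])
  g
}
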