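#' Run the full cross-tissue core-module pipeline
#'
#' For every tissue, fits the time-deconvolution model and removes the
#' per-condition effects. Candidate modules are inferred from the inference
#' tissue by greedy CORG aggregation and ranked by absolute activity
#' t-score; each remaining tissue validates them by consensus feature
#' elimination; modules surviving in at least half of the validation sets
#' are the core modules, projected onto the PPI network.
#'
#' @param studies named list of [expression_study()] (one per tissue), on
#'   the log2 scale with no missing values.
#' @param pathways named list of gene sets.
#' @param ppi PPI edge list ([read_ppi()] shape); \code{NULL} skips the
#'   projection.
#' @param inference_tissue name of the inference tissue (default: first).
#' @param top_k,max_module_size candidate inference settings.
#' @param auc_threshold,n_groups,group_size,train_frac,min_eliminations
#'   consensus-feature-elimination settings.
#' @param min_core_frac core-module support fraction (default 0.5).
#' @param seed RNG seed governing every stochastic step.
#' @return list with \code{fits} (per-tissue \code{TimeDeconvFit}),
#'   \code{adjusted} (per-tissue time-standardized studies),
#'   \code{candidates}, \code{validation} (per validation tissue:
#'   [validate_pair()] results), \code{summary} (per-pair table of final
#'   module/gene counts, mean AUC, mean error), \code{core} (core module
#'   list), \code{n_core_genes} and \code{network}
#'   (\code{CoreModuleNetwork} or \code{NULL}).
#' @export
run_pipeline <- function(studies, pathways, ppi = NULL,
                         inference_tissue = names(studies)[1],
                         top_k = 100, max_module_size = 25,
                         auc_threshold = 0.75, n_groups = 250,
                         group_size = 500, train_frac = 2 / 3,
                         min_eliminations = 0, min_core_frac = 0.5,
                         seed = 1L) {
  if (is.null(names(studies)) || !inference_tissue %in% names(studies))
    stop("studies must be a named list containing the inference tissue")
  set.seed(seed)
  fits <- lapply(studies, fit_time_model)
  adjusted <- mapply(adjust_expression, studies, fits, SIMPLIFY = FALSE)
  inf_adj <- adjusted[[inference_tissue]]
  de <- moderated_t_test(inf_adj)
  candidates <- infer_candidates(inf_adj, pathways, top_k = top_k,
                                 max_size = max_module_size, de = de)
  val_tissues <- setdiff(names(studies), inference_tissue)
  if (!length(val_tissues)) stop("need at least one validation tissue")
  validation <- list()
  for (tis in val_tissues) {
    validation[[tis]] <- validate_pair(
      candidates, adjusted[[tis]], inference_study = inf_adj,
      auc_threshold = auc_threshold, n_groups = n_groups,
      group_size = group_size, train_frac = train_frac,
      min_eliminations = min_eliminations)
  }
  summary <- data.frame(
    inference = inference_tissue,
    validation = val_tissues,
    n_final_modules = vapply(validation, function(v)
      length(v$final_modules), integer(1)),
    n_final_genes = vapply(validation, function(v)
      length(unique(unlist(lapply(v$final_modules, `[[`,
                                  "member_genes")))), integer(1)),
    mean_auc = vapply(validation, `[[`, numeric(1), "mean_auc"),
    mean_error = vapply(validation, `[[`, numeric(1), "mean_error"),
    stringsAsFactors = FALSE, row.names = NULL)
  core <- identify_core_modules(
    lapply(validation, `[[`, "final_modules"), min_core_frac)
  network <- if (!is.null(ppi) && length(core))
    project_onto_ppi(core, ppi, fits[[inference_tissue]],
                     inference_tissue) else NULL
  list(fits = fits, adjusted = adjusted, candidates = candidates,
       validation = validation, summary = summary, core = core,
       n_core_genes = count_core_genes(core), network = network)
}

#' Read a candidate-module table written by [candidate_table()]
#'
#' Reconstructs \code{CandidateModule} objects (member order and direction;
#' activities are regenerated on demand by [compute_activity()]).
#'
#' @param path TSV path.
#' @return list of \code{CandidateModule}.
#' @export
read_candidates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    structure(list(pathway_name = tab$pathway[i],
                   member_genes = strsplit(tab$genes[i], ",")[[1]],
                   direction = tab$direction[i],
                   activity = NULL,
                   activity_t = tab$abs_t[i]),
              class = "CandidateModule"))
}
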