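#' Configuration for the synthetic study generator
#'
#' Defines a multi-tissue, multi-timepoint two-class study with the
#' generative structure the pipeline assumes: per gene,
#' value = baseline + beta_timepoint + [defeat] * alpha + N(0, sigma^2),
#' with alpha nonzero only for members of planted treatment-responsive
#' modules active in that tissue. Defaults describe the standard test
#' fixture: two tissues, 1000 genes, five planted 10-gene modules active in
#' both tissues with a 1 log2-unit defeat effect, noise sd 0.5 and 10 mice
#' per class in each of the four exposure/recovery conditions.
#'
#' @param n_genes gene universe size.
#' @param tissues character vector of tissue labels; the first is the
#'   conventional inference tissue.
#' @param replicates samples per (tissue, condition, class) cell (>= 2).
#' @param n_timepoints number of exposure/recovery conditions.
#' @param n_modules,module_size planted module count and size.
#' @param delta planted defeat effect per member gene, log2 units; sign
#'   alternates across modules (up/down directions).
#' @param sigma noise standard deviation, log2 units.
#' @param beta_sd spread of per-(gene, timepoint) age/recovery effects.
#' @param baseline_mean,baseline_sd per-gene baseline intensity
#'   distribution (log2 scale); set both to 0 for effects-only data.
#' @param active_tissues tissues in which planted modules carry their
#'   effect (default: all).
#' @param n_pathways total pathway count in the generated GMT (the first
#'   \code{n_modules} embed the planted modules, the rest are decoys).
#' @param pathway_size_range size range of generated pathways.
#' @param n_go_terms,go_size_range generated GO-term collection shape.
#' @param ppi_density_in,ppi_density_bg PPI edge probability within planted
#'   modules vs background.
#' @param seed integer RNG seed; everything downstream is a deterministic
#'   function of the config.
#' @return list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_genes = 1000,
                              tissues = c("Blood", "HB"),
                              replicates = 10,
                              n_timepoints = 4,
                              n_modules = 5,
                              module_size = 10,
                              delta = 1,
                              sigma = 0.5,
                              beta_sd = 0.5,
                              baseline_mean = 8,
                              baseline_sd = 1.5,
                              active_tissues = tissues,
                              n_pathways = 40,
                              pathway_size_range = c(10, 30),
                              n_go_terms = 50,
                              go_size_range = c(5, 50),
                              ppi_density_in = 0.5,
                              ppi_density_bg = 0.01,
                              seed = 42L) {
  stopifnot(replicates >= 2, delta >= 0, sigma >= 0,
            n_modules * module_size <= n_genes,
            module_size <= max(pathway_size_range))
  structure(as.list(environment()), class = "SimulationConfig")
}

# Deterministic gene universe and planted-module membership for a config.
# Both generate_study and generate_annotations derive from this, so the
# two stay consistent without passing state between them.
.sim_layout <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  set.seed(config$seed)
  picked <- sample(genes, config$n_modules * config$module_size)
  modules <- split(picked, rep(seq_len(config$n_modules),
                               each = config$module_size))
  names(modules) <- sprintf("planted_mod%02d", seq_len(config$n_modules))
  direction <- rep(c(1, -1), length.out = config$n_modules)
  list(genes = genes, modules = modules, direction = direction)
}

#' Generate a synthetic multi-tissue study with planted modules
#'
#' Draws one [expression_study()] per tissue from the additive model
#' baseline + per-timepoint effect + defeat effect + Gaussian noise, plus
#' the ground truth needed for recovery tests. The defeat effect alpha of a
#' gene is \code{delta * direction} when the gene belongs to a planted
#' module active in that tissue, else 0. The per-condition time effects and
#' baselines are shared across tissues. Fully determined by
#' \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @return list with \code{studies} (named list of \code{ExpressionStudy},
#'   one per tissue) and \code{truth}: list with \code{alpha} (genes x
#'   tissues matrix), \code{beta_time} (genes x conditions),
#'   \code{baseline} (per gene), \code{expected_beta}
#'   (baseline + beta_time, what the no-intercept time model estimates),
#'   \code{modules} (named list of member genes), \code{direction}
#'   (per module, +1 up / -1 down), \code{active_tissues}.
#' @export
generate_study <- function(config) {
  lay <- .sim_layout(config)
  genes <- lay$genes
  G <- config$n_genes
  Tn <- config$n_timepoints
  set.seed(config$seed + 1L)
  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  beta_time <- matrix(stats::rnorm(G * Tn, 0, config$beta_sd), G, Tn,
                      dimnames = list(genes, NULL))
  alpha_gene <- numeric(G)
  names(alpha_gene) <- genes
  for (m in seq_along(lay$modules))
    alpha_gene[lay$modules[[m]]] <- config$delta * lay$direction[m]
  alpha <- sapply(config$tissues, function(tis)
    if (tis %in% config$active_tissues) alpha_gene else numeric(G))
  rownames(alpha) <- genes
  tp_labels <- if (Tn == 4) DEFAULT_TIMEPOINTS else paste0("T", seq_len(Tn))
  studies <- list()
  for (tis in config$tissues) {
    n_cell <- config$replicates
    n_samp <- Tn * 2 * n_cell
    tp <- rep(seq_len(Tn), each = 2 * n_cell)
    cls <- rep(rep(c("defeat", "control"), each = n_cell), Tn)
    mu <- baseline + beta_time[, tp, drop = FALSE]
    mu <- mu + outer(alpha[, tis], as.numeric(cls == "defeat"))
    vals <- mu + matrix(stats::rnorm(G * n_samp, 0, config$sigma), G, n_samp)
    ids <- sprintf("%s_t%d_%s_%02d", tis, tp, ifelse(cls == "defeat",
                                                     "D", "C"),
                   stats::ave(seq_len(n_samp), paste(tp, cls),
                              FUN = seq_along))
    samples <- data.frame(sample_id = ids, tissue = tis, class = cls,
                          timepoint = tp, stringsAsFactors = FALSE)
    rownames(vals) <- genes
    studies[[tis]] <- expression_study(vals, samples, tp_labels)
  }
  truth <- list(alpha = alpha, beta_time = beta_time, baseline = baseline,
                expected_beta = baseline + beta_time,
                modules = lay$modules, direction = lay$direction,
                active_tissues = config$active_tissues)
  list(studies = studies, truth = truth)
}

#' Generate pathway, GO and PPI annotations matching a config
#'
#' Pathways: each planted module is embedded in a larger pathway padded
#' with random non-planted genes; the remaining pathways are decoys of
#' random genes. GO terms: random gene sets within the configured size
#' range (the first \code{n_modules} terms are the planted modules
#' themselves, giving enriched terms; the rest are null). PPI: random
#' graph with elevated edge density inside planted modules over a sparse
#' background. Deterministic given \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @return list with \code{pathways} (named list, GMT-shaped),
#'   \code{go} (named list term -> genes) and \code{ppi} (edge-list
#'   data.frame as from [read_ppi()]).
#' @export
generate_annotations <- function(config) {
  lay <- .sim_layout(config)
  genes <- lay$genes
  planted <- unlist(lay$modules, use.names = FALSE)
  free <- setdiff(genes, planted)
  set.seed(config$seed + 2L)
  rng <- config$pathway_size_range
  pathways <- list()
  for (m in seq_along(lay$modules)) {
    sz <- sample(seq(max(rng[1], config$module_size), rng[2]), 1)
    pad <- sample(free, sz - config$module_size)
    pathways[[sprintf("pathway_planted%02d", m)]] <-
      sample(c(lay$modules[[m]], pad))
  }
  for (d in seq_len(config$n_pathways - config$n_modules)) {
    sz <- sample(seq(rng[1], rng[2]), 1)
    pathways[[sprintf("pathway_decoy%02d", d)]] <- sample(free, sz)
  }
  grng <- config$go_size_range
  go <- stats::setNames(lay$modules,
                        sprintf("GO:%07d", seq_along(lay$modules)))
  for (d in seq_len(max(0, config$n_go_terms - config$n_modules))) {
    sz <- sample(seq(grng[1], grng[2]), 1)
    go[[sprintf("GO:%07d", config$n_modules + d)]] <- sample(free, sz)
  }
  edges <- list()
  for (m in lay$modules) {
    pr <- t(utils::combn(sort(m), 2))
    keep <- stats::runif(nrow(pr)) < config$ppi_density_in
    if (any(keep))
      edges[[length(edges) + 1L]] <-
        data.frame(gene_a = pr[keep, 1], gene_b = pr[keep, 2],
                   stringsAsFactors = FALSE)
  }
  # sparse background: sample pairs rather than enumerating all C(G,2)
  n_bg <- stats::rbinom(1, as.integer(config$n_genes * 20),
                        config$ppi_density_bg)
  if (n_bg > 0) {
    a <- sample(genes, n_bg, replace = TRUE)
    b <- sample(genes, n_bg, replace = TRUE)
    ok <- a != b
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = pmin(a[ok], b[ok]), gene_b = pmax(a[ok], b[ok]),
                 stringsAsFactors = FALSE)
  }
  ppi <- do.call(rbind, edges)
  ppi$score <- round(stats::runif(nrow(ppi), 0.4, 1), 3)
  key <- paste(ppi$gene_a, ppi$gene_b)
  best <- tapply(ppi$score, key, max)
  ppi <- ppi[!duplicated(key), , drop = FALSE]
  ppi$score <- as.numeric(best[paste(ppi$gene_a, ppi$gene_b)])
  ppi <- ppi[order(ppi$gene_a, ppi$gene_b), , drop = FALSE]
  rownames(ppi) <- NULL
  list(pathways = pathways, go = go, ppi = ppi)
}

#' Write a full synthetic dataset to disk
#'
#' Emits every pipeline input format: per-tissue expression and metadata
#' TSVs, pathway GMT, gene-to-GO two-column TSV, PPI edge list, and a
#' ground-truth JSON.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the [generate_study()] result.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_study(config)
  ann <- generate_annotations(config)
  for (tis in names(sim$studies))
    write_expression(sim$studies[[tis]],
                     file.path(out_dir, paste0("expr_", tis, ".tsv")),
                     file.path(out_dir, paste0("meta_", tis, ".tsv")))
  write_gmt(ann$pathways, file.path(out_dir, "pathways.gmt"))
  gene_go <- do.call(rbind, lapply(names(ann$go), function(tm)
    data.frame(gene = ann$go[[tm]], term = tm, stringsAsFactors = FALSE)))
  utils::write.table(gene_go, file.path(out_dir, "gene_go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_ppi(ann$ppi, file.path(out_dir, "ppi.tsv"))
  jsonlite::write_json(
    list(modules = sim$truth$modules,
         direction = sim$truth$direction,
         active_tissues = sim$truth$active_tissues,
         delta = config$delta, sigma = config$sigma,
         seed = config$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(sim)
}
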