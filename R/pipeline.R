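stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full selection pipeline
#'
#' One-call orchestration of preprocessing, PLS + Monte Carlo gene
#' selection, hypergeometric enrichment and interaction-network hub
#' analysis, writing every result table plus a machine-readable
#' `run_summary.json` to `out_dir`. All randomness derives from `seed`, so
#' a rerun with the same inputs produces byte-identical outputs.
#'
#' Inputs may be file paths (read with the package's TSV readers) or
#' in-memory objects. Annotation and interactions are optional; the
#' corresponding stages are skipped when absent. Enrichment is also skipped
#' (and recorded as such) when the selection is empty.
#'
#' Output files: `selection.tsv` (gene, vip, fdr, reliability, candidate,
#' selected), `rmsecv_components.tsv`, `rmsecv_cutoff.tsv`,
#' `enrichment.tsv`, `network.sif`, `network.graphml`, `hubs.tsv`,
#' `run_summary.json`.
#'
#' @param expression path to an expression TSV (genes x samples) or an
#'   [expression_dataset()].
#' @param phenotype path to a phenotype TSV or a named numeric vector.
#'   Required unless `expression` already carries a phenotype.
#' @param annotation optional path or data.frame (gene, term).
#' @param interactions optional path or data.frame (geneA, geneB).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every stochastic stage.
#' @param quantile,log2_transform forwarded to [preprocess_expression()].
#' @param intersect forwarded to [join_phenotype()].
#' @param hub_threshold degree threshold for hub calling (strict `>`).
#' @param min_term_size forwarded to [enrich()].
#' @inheritParams select_genes.default
#' @return Invisibly, a list with `selection`, `enrichment`, `network`,
#'   `hubs`, `summary` and `out_dir`.
#' @export
run_pipeline <- function(expression, phenotype = NULL, annotation = NULL,
                         interactions = NULL, out_dir, seed = 1L,
                         quantile = FALSE, log2_transform = FALSE,
                         intersect = FALSE, a_max = 10L, folds = 4L,
                         n_perm = 1000L, alpha = 0.05, n_subsets = 100L,
                         fraction = 0.5, grid_size = 100L, rel_tol = 0.01,
                         scale = TRUE, order = "default",
                         hub_threshold = 10L, min_term_size = 1L) {
  # configuration errors must fire before any computation
  if (missing(out_dir)) stop("[config] `out_dir` is required")
  has_pheno <- !is.null(phenotype) ||
    (inherits(expression, "expression_dataset") && !is.null(expression$phenotype))
  if (!has_pheno) stop("[config] `phenotype` is required (path or named vector)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n_dropped <- 0L
  ds <- stage("data_io", {
    d <- if (is.character(expression)) read_expression(expression) else expression
    stopifnot(inherits(d, "expression_dataset"))
    if (!is.null(phenotype)) {
      ph <- if (is.character(phenotype)) read_phenotype(phenotype) else phenotype
      n_before <- length(d$sample_ids)
      d <- join_phenotype(d, ph, intersect = intersect)
      n_dropped <- n_before - length(d$sample_ids)
    }
    d
  })
  n_genes_in <- length(ds$gene_ids)

  ds <- stage("preprocess", {
    preprocess_expression(ds, quantile = quantile,
                          log2_transform = log2_transform,
                          drop_degenerate = TRUE)
  })
  n_degenerate <- length(attr(ds, "removed"))

  sel <- stage("selection", {
    select_genes(ds, a_max = a_max, folds = folds, n_perm = n_perm,
                 alpha = alpha, n_subsets = n_subsets, fraction = fraction,
                 grid_size = grid_size, rel_tol = rel_tol, scale = scale,
                 order = order, seed = seed)
  })
  write_tsv(sel$genes, file.path(out_dir, "selection.tsv"))
  write_tsv(sel$component_curve, file.path(out_dir, "rmsecv_components.tsv"))
  if (!is.null(sel$cutoff_curve)) {
    write_tsv(sel$cutoff_curve, file.path(out_dir, "rmsecv_cutoff.tsv"))
  }
  sel_ids <- selected_genes(sel)

  enr <- NULL
  if (!is.null(annotation) && length(sel_ids) > 0L) {
    enr <- stage("enrichment", {
      ann <- if (is.character(annotation)) read_annotation(annotation) else annotation
      enrich(sel_ids, ann, background = ds$gene_ids,
             min_term_size = min_term_size)
    })
    write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
  }

  net <- NULL
  hubs <- NULL
  if (!is.null(interactions)) {
    net <- stage("network", {
      ints <- if (is.character(interactions)) read_interactions(interactions)
              else interactions
      build_network(sel_ids, ints, hub_threshold = hub_threshold)
    })
    hubs <- find_hubs(net)
    export_network(net, file.path(out_dir, "network.sif"), format = "sif")
    export_network(net, file.path(out_dir, "network.graphml"),
                   format = "graphml")
    write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
  }

  summary <- list(
    n_samples = length(ds$sample_ids),
    n_samples_dropped = n_dropped,
    n_genes_input = n_genes_in,
    n_genes_degenerate = n_degenerate,
    n_genes_analysed = unname(sel$counts[["genes"]]),
    a_star = sel$a_star,
    n_candidates = unname(sel$counts[["candidates"]]),
    reliability_cutoff = sel$cutoff,
    n_selected = unname(sel$counts[["selected"]]),
    enrichment_skipped = is.null(enr) && !is.null(annotation),
    top_enrichment = if (!is.null(enr)) {
      head(as.data.frame(enr)[, c("term_id", "N", "K", "n", "k", "p_value")], 5L)
    },
    hubs = if (!is.null(hubs)) hubs,
    params = list(seed = seed, folds = folds, n_perm = n_perm, alpha = alpha,
                  n_subsets = n_subsets, fraction = fraction, a_max = a_max,
                  grid_size = grid_size, rel_tol = rel_tol, scale = scale,
                  order = order, hub_threshold = hub_threshold,
                  quantile = quantile, log2_transform = log2_transform)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(list(selection = sel, enrichment = enr, network = net,
                 hubs = hubs, summary = summary, out_dir = out_dir))
}
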