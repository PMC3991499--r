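# Synthetic data with planted structure: linearly phenotype-associated genes,
# optional array-level nuisance factors, an enriched annotation term and an
# interaction network with known degrees.  Every generator is deterministic
# given its seed.

#' Simulate an expression dataset with planted phenotype associations
#'
#' Emulates a bulk expression study of a continuous disease index at reduced
#' scale. Each sample's phenotype `y_i` is drawn uniformly over
#' `phenotype_range` (or from a two-component mixture when
#' `phenotype_mode = "bimodal"`, mimicking a cohort that pools patients and
#' controls). With `ytilde` the standardised phenotype, an informative gene
#' `j` follows
#' \deqn{x_{ij} = \mu_j + \beta_j \tilde y_i + \sum_f \lambda_{jf} u_{if} + \epsilon_{ij},}
#' where `u_if ~ N(0, batch_sd)` are `n_batch_factors` array-specific
#' nuisance factors loading on all genes (`lambda ~ N(0, 1)`),
#' `epsilon ~ N(0, noise_sd)`, and `mu_j` is a per-gene baseline drawn from
#' `baseline_range` to resemble log2 intensities. Null genes contain
#' baseline, batch and noise only. Effect signs are randomised so the
#' planted set mixes up- and down-regulated genes.
#'
#' The defaults (120 samples, 1,000 genes, 30 informative genes with
#' absolute effect 1.5 against unit noise) define the package's reference
#' simulated study.
#'
#' @param n_samples,n_genes,n_informative study dimensions;
#'   `n_informative <= n_genes`.
#' @param effect_size absolute standardised effect per informative gene;
#'   either a scalar (recycled) or a vector of length `n_informative`.
#' @param noise_sd residual standard deviation, > 0.
#' @param phenotype_range numeric `(low, high)` for the disease index.
#' @param phenotype_mode `"uniform"` or `"bimodal"`.
#' @param n_batch_factors number of array-specific nuisance factors (>= 0).
#' @param batch_sd standard deviation of the nuisance factor scores.
#' @param baseline_range range of per-gene baseline log2 expression.
#' @param seed integer seed; the output is bit-reproducible from it.
#' @return List with `data` (an [expression_dataset()] with phenotype) and
#'   `truth` (list with `informative`, the planted gene ids, and `effects`,
#'   the signed per-gene effect sizes over all genes).
#' @export
#' @examples
#' sim <- simulate_dataset(n_samples = 30, n_genes = 100, n_informative = 5,
#'                         seed = 1)
#' sim$data
#' sim$truth$informative
simulate_dataset <- function(n_samples = 120L, n_genes = 1000L,
                             n_informative = 30L, effect_size = 1.5,
                             noise_sd = 1, phenotype_range = c(0, 100),
                             phenotype_mode = c("uniform", "bimodal"),
                             n_batch_factors = 0L, batch_sd = 1,
                             baseline_range = c(6, 12), seed = 1L) {
  phenotype_mode <- match.arg(phenotype_mode)
  n_samples <- check_count(n_samples, "n_samples", lower = 4L)
  n_genes <- check_count(n_genes, "n_genes", lower = 2L)
  n_informative <- check_count(n_informative, "n_informative")
  if (n_informative > n_genes) stop("`n_informative` must be <= `n_genes`")
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  n_batch_factors <- check_count(n_batch_factors, "n_batch_factors")
  if (length(phenotype_range) != 2L || diff(phenotype_range) <= 0) {
    stop("`phenotype_range` must be (low, high) with low < high")
  }
  if (!length(effect_size) %in% c(1L, max(n_informative, 1L))) {
    stop("`effect_size` must be a scalar or one value per informative gene")
  }
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  with_seed(seed, {
    lo <- phenotype_range[1L]
    hi <- phenotype_range[2L]
    y <- if (phenotype_mode == "uniform") {
      runif(n_samples, lo, hi)
    } else {
      span <- hi - lo
      grp <- sample(rep_len(c(0L, 1L), n_samples))
      ifelse(grp == 0L, runif(n_samples, lo, lo + 0.4 * span),
             runif(n_samples, hi - 0.4 * span, hi))
    }
    ytilde <- (y - mean(y)) / sd(y)
    x <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
    baseline <- runif(n_genes, baseline_range[1L], baseline_range[2L])
    x <- x + baseline
    effects <- setNames(numeric(n_genes), gene_ids)
    informative <- character()
    if (n_informative > 0L) {
      informative <- sort(sample(gene_ids, n_informative))
      beta <- rep_len(abs(effect_size), n_informative) *
        sample(c(-1, 1), n_informative, replace = TRUE)
      effects[informative] <- beta
      x[match(informative, gene_ids), ] <-
        x[match(informative, gene_ids), ] + outer(beta, ytilde)
    }
    if (n_batch_factors > 0L) {
      u <- matrix(rnorm(n_samples * n_batch_factors, sd = batch_sd),
                  n_samples, n_batch_factors)
      lambda <- matrix(rnorm(n_genes * n_batch_factors), n_genes,
                       n_batch_factors)
      x <- x + tcrossprod(lambda, u)
    }
    dimnames(x) <- list(gene_ids, sample_ids)
    names(y) <- sample_ids
    list(data = expression_dataset(x, phenotype = y),
         truth = list(informative = informative, effects = effects))
  })
}

#' Simulate a flat gene-to-term annotation with one enriched term
#'
#' Generates `n_terms` terms whose member genes are drawn uniformly, except
#' for one designated term that preferentially covers the informative genes
#' (a fraction `coverage` of them, padded with random genes up to a size
#' drawn from `term_size_range` when needed). The enriched term's id is
#' `enriched_term`.
#'
#' @param gene_ids all gene identifiers.
#' @param informative planted gene ids the enriched term should cover.
#' @param n_terms number of terms, >= 1.
#' @param term_size_range integer `(min, max)` genes per ordinary term; must
#'   not exceed `length(gene_ids)`.
#' @param coverage fraction of informative genes covered by the enriched
#'   term, in (0, 1].
#' @param enriched_term id of the designated enriched term.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `term` (unique pairs).
#' @export
simulate_annotation <- function(gene_ids, informative = character(),
                                n_terms = 50L, term_size_range = c(10L, 40L),
                                coverage = 0.9,
                                enriched_term = "T000_enriched", seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms", lower = 1L)
  check_scalar_number(coverage, "coverage", lower = 0, upper = 1)
  term_size_range <- sort(as.integer(term_size_range))
  if (max(term_size_range) > length(gene_ids)) {
    stop("`term_size_range` exceeds the number of genes")
  }
  with_seed(seed, {
    pairs <- list()
    cov_genes <- if (length(informative)) {
      sample(informative, max(1L, round(coverage * length(informative))))
    } else character()
    size <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
    if (size > length(cov_genes)) {
      pad <- sample(setdiff(gene_ids, cov_genes), size - length(cov_genes))
      cov_genes <- c(cov_genes, pad)
    }
    pairs[[1L]] <- data.frame(gene = cov_genes, term = enriched_term,
                              stringsAsFactors = FALSE)
    if (n_terms > 1L) {
      for (t in seq_len(n_terms - 1L)) {
        size <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
        pairs[[t + 1L]] <- data.frame(gene = sample(gene_ids, size),
                                      term = sprintf("T%03d", t),
                                      stringsAsFactors = FALSE)
      }
    }
    unique(do.call(rbind, pairs))
  })
}

#' Simulate a gene-gene interaction list
#'
#' Two generators: `"preferential_attachment"` grows a scale-free-like graph
#' (Barabasi-Albert, `m` edges per new node) whose vertices are mapped to a
#' random permutation of the gene ids, so that a few genes acquire high
#' degree; `"fixed_degree"` realises an exact requested degree sequence as a
#' simple graph (Havel-Hakimi construction), erroring if the sequence is
#' infeasible.
#'
#' @param gene_ids gene identifiers (the network's vertex set).
#' @param model `"preferential_attachment"` or `"fixed_degree"`.
#' @param degrees integer degree per gene (recycled / named), required for
#'   `"fixed_degree"`.
#' @param m edges added per node under preferential attachment.
#' @param seed integer seed.
#' @return data.frame with columns `geneA`, `geneB`, one row per edge, with
#'   the realized degree sequence attached as attribute `"degrees"`.
#' @export
simulate_interactions <- function(gene_ids,
                                  model = c("preferential_attachment",
                                            "fixed_degree"),
                                  degrees = NULL, m = 2L, seed = 1L) {
  model <- match.arg(model)
  n <- length(gene_ids)
  if (n < 2L) stop("need at least 2 genes")
  with_seed(seed, {
    if (model == "preferential_attachment") {
      g <- igraph::sample_pa(n, m = m, directed = FALSE)
      igraph::V(g)$name <- sample(gene_ids)
    } else {
      if (is.null(degrees)) stop("`degrees` is required for fixed_degree")
      if (!is.null(names(degrees))) {
        degrees <- degrees[gene_ids]
        degrees[is.na(degrees)] <- 0L
      } else {
        degrees <- rep_len(as.integer(degrees), n)
      }
      g <- tryCatch(igraph::realize_degseq(as.integer(degrees)),
                    error = function(e) {
                      stop("infeasible degree sequence: ", conditionMessage(e),
                           call. = FALSE)
                    })
      igraph::V(g)$name <- gene_ids
    }
    el <- igraph::as_edgelist(g)
    out <- data.frame(geneA = el[, 1L], geneB = el[, 2L],
                      stringsAsFactors = FALSE)
    deg <- igraph::degree(g)
    attr(out, "degrees") <- setNames(as.integer(deg), igraph::V(g)$name)[gene_ids]
    out
  })
}

#' Simulate a complete study (expression, annotation, interactions, truth)
#'
#' Convenience wrapper bundling [simulate_dataset()],
#' [simulate_annotation()] and [simulate_interactions()] with per-stage
#' seeds derived from one master seed. The returned `truth` records the
#' planted gene set, effects, enriched term id and realized network degrees,
#' which is what end-to-end tests score recovery against.
#'
#' @inheritParams simulate_dataset
#' @param n_terms,term_size_range,coverage forwarded to
#'   [simulate_annotation()].
#' @param network_model,degrees,m forwarded to [simulate_interactions()].
#' @param ... forwarded to [simulate_dataset()].
#' @return List with `data`, `annotation`, `interactions`, `truth`.
#' @export
simulate_study <- function(n_samples = 120L, n_genes = 1000L,
                           n_informative = 30L, effect_size = 1.5,
                           noise_sd = 1, seed = 1L, n_terms = 50L,
                           term_size_range = c(10L, 40L), coverage = 0.9,
                           network_model = "preferential_attachment",
                           degrees = NULL, m = 2L, ...) {
  sim <- simulate_dataset(n_samples = n_samples, n_genes = n_genes,
                          n_informative = n_informative,
                          effect_size = effect_size, noise_sd = noise_sd,
                          seed = derive_seed(seed, 11L), ...)
  ann <- simulate_annotation(sim$data$gene_ids, sim$truth$informative,
                             n_terms = n_terms,
                             term_size_range = term_size_range,
                             coverage = coverage,
                             seed = derive_seed(seed, 12L))
  net <- simulate_interactions(sim$data$gene_ids, model = network_model,
                               degrees = degrees, m = m,
                               seed = derive_seed(seed, 13L))
  truth <- sim$truth
  truth$enriched_term <- "T000_enriched"
  truth$degrees <- attr(net, "degrees")
  list(data = sim$data, annotation = ann, interactions = net, truth = truth)
}
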