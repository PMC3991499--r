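#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated genes in a selection of
#' size `n`, drawn without replacement from a background of `N` genes of
#' which `K` carry the annotation:
#' \deqn{p = \sum_{i = k}^{\min(K, n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Evaluated through [stats::phyper()], which works in log space and is
#' stable for backgrounds far beyond 1e5 genes.
#'
#' @param N background size (annotated, measured genes).
#' @param K genes in the background carrying the term.
#' @param n selected genes (within the background).
#' @param k selected genes carrying the term.
#' @return The exact upper-tail probability, in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_pvalue(10, 4, 5, 3)  # 66/252
hypergeom_upper_pvalue <- function(N, K, n, k) {
  N <- check_count(N, "N", lower = 1L)
  K <- check_count(K, "K")
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (K > N || n > N) stop("need K <= N and n <= N")
  if (k > min(K, n)) stop("need k <= min(K, n)")
  if (k < max(0L, n + K - N)) stop("k below the minimum possible overlap")
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of terms in a selected gene set
#'
#' Tests every annotation term for enrichment of the selected genes against
#' a background. Following the convention of restricting the universe to
#' genes that are both measured and annotated, `N` is the number of
#' background genes present in the annotation and `n` the number of selected
#' genes among them; genes outside the background are ignored.
#'
#' @param selected character vector of selected gene ids.
#' @param annotation data.frame with columns `gene` and `term`, as from
#'   [read_annotation()] or [simulate_annotation()].
#' @param background character vector of measured gene ids (the assayed
#'   universe). Defaults to all annotated genes.
#' @param min_term_size drop terms annotating fewer than this many
#'   background genes.
#' @param term_names optional named character vector mapping term ids to
#'   descriptions.
#' @return A data.frame of class `enrichment_table`, one row per term,
#'   sorted by ascending p-value, with columns `term_id`, `term_name`, `N`,
#'   `K`, `n`, `k`, `p_value` and `bh_adjusted_p` (Benjamini-Hochberg,
#'   provided for convenience; the raw p-value is the primary statistic).
#' @export
enrich <- function(selected, annotation, background = unique(annotation$gene),
                   min_term_size = 1L, term_names = NULL) {
  stopifnot(is.character(selected) || length(selected) == 0L)
  ann <- unique(data.frame(gene = as.character(annotation$gene),
                           term = as.character(annotation$term),
                           stringsAsFactors = FALSE))
  bg <- unique(intersect(as.character(background), ann$gene))
  N <- length(bg)
  if (N == 0L) stop("empty background: no measured gene is annotated")
  sel <- unique(intersect(selected, bg))
  n <- length(sel)
  if (n == 0L) stop("no selected gene is in the annotated background")
  ann <- ann[ann$gene %in% bg, , drop = FALSE]
  K_tab <- table(ann$term)
  k_tab <- table(ann$term[ann$gene %in% sel])
  terms <- names(K_tab)[K_tab >= min_term_size]
  if (length(terms) == 0L) stop("no term passes `min_term_size`")
  K <- as.integer(K_tab[terms])
  k <- as.integer(k_tab[terms])
  k[is.na(k)] <- 0L
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = terms,
    term_name = if (is.null(term_names)) terms else
      ifelse(is.na(term_names[terms]), terms, term_names[terms]),
    N = N, K = K, n = n, k = k,
    p_value = p,
    bh_adjusted_p = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, -out$k, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, n_top = 10L, ...) {
  cat(sprintf("Hypergeometric enrichment: %d terms, background N = %d, selected n = %d\n",
              nrow(x), x$N[1L], x$n[1L]))
  print.data.frame(head(as.data.frame(x), n_top), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > n_top) cat(sprintf("... and %d more terms\n", nrow(x) - n_top))
  invisible(x)
}
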