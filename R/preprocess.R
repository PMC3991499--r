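#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution: the
#' across-column mean of order statistics. Within-column ranks are preserved;
#' ties within a column receive the mean of the reference distribution over
#' the tied ranks. Computation is delegated to
#' [limma::normalizeQuantiles()], the standard implementation for microarray
#' matrices.
#'
#' @param values numeric p x n matrix, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("`values` contains missing values")
  if (ncol(values) == 1L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Tukey median polish of an expression matrix
#'
#' Iteratively sweeps row and column medians out of the matrix, decomposing
#' it as `overall + row_effect[i] + col_effect[j] + residual[i, j]` (the
#' summarisation step of RMA-style preprocessing). Rows are swept first.
#' Iteration stops when the total absolute residual changes by less than
#' `tol` (relative) between sweeps, or after `max_iter` full sweeps.
#' Computation is delegated to [stats::medpolish()].
#'
#' @param values numeric p x n matrix.
#' @param tol convergence tolerance on the total absolute residual, > 0.
#' @param max_iter maximum number of full row+column sweeps, >= 1.
#' @return List with elements `overall` (scalar), `row_effects` (length p),
#'   `col_effects` (length n) and `residuals` (p x n); the four terms
#'   reconstruct the input exactly.
#' @export
median_polish <- function(values, tol = 0.01, max_iter = 10L) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty matrix")
  if (anyNA(values)) stop("`values` contains missing values")
  check_scalar_number(tol, "tol")
  if (tol <= 0) stop("`tol` must be > 0")
  max_iter <- check_count(max_iter, "max_iter", lower = 1L)
  mp <- stats::medpolish(values, eps = tol, maxiter = max_iter,
                         trace.iter = FALSE, na.rm = FALSE)
  list(overall = mp$overall,
       row_effects = setNames(as.numeric(mp$row), rownames(values)),
       col_effects = setNames(as.numeric(mp$col), colnames(values)),
       residuals = mp$residuals)
}

#' Remove zero-variance genes
#'
#' Genes constant across all samples carry no association signal and make
#' unit-variance scaling undefined, so they are removed before model fitting.
#'
#' @param ds an [expression_dataset()].
#' @return The filtered dataset; the removed gene ids are attached as
#'   attribute `"removed"` and reported via a message.
#' @export
drop_degenerate_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- apply(ds$values, 1L, var)
  degenerate <- v <= 0
  if (all(degenerate)) stop("all genes have zero variance across samples")
  removed <- ds$gene_ids[degenerate]
  if (length(removed)) {
    message(sprintf("drop_degenerate_genes: removed %d zero-variance gene(s)",
                    length(removed)))
    ds <- expression_dataset(ds$values[!degenerate, , drop = FALSE],
                             phenotype = ds$phenotype)
  }
  attr(ds, "removed") <- removed
  ds
}

#' Convenience preprocessing wrapper
#'
#' Optionally log2-transforms (for inputs still on the raw intensity scale),
#' quantile-normalizes across samples, and drops zero-variance genes. The
#' input is assumed background-corrected; all steps are optional because
#' public expression matrices are frequently deposited already normalized.
#'
#' @param ds an [expression_dataset()].
#' @param quantile apply [quantile_normalize()].
#' @param log2_transform apply `log2(x + 1)` first.
#' @param drop_degenerate apply [drop_degenerate_genes()].
#' @return A preprocessed [expression_dataset()].
#' @export
preprocess_expression <- function(ds, quantile = TRUE, log2_transform = FALSE,
                                  drop_degenerate = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (log2_transform) {
    if (any(v < 0)) stop("negative values: input does not look like raw intensities")
    v <- log2(v + 1)
  }
  if (quantile && ncol(v) > 1L) v <- quantile_normalize(v)
  out <- expression_dataset(v, phenotype = ds$phenotype)
  if (drop_degenerate) out <- drop_degenerate_genes(out)
  out
}
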