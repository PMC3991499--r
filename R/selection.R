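# Gene-selection statistics: permutation-null FDR on VIP, Monte Carlo
# regression-coefficient reliability, and the RMSECV-optimised reliability
# cutoff that together define the selected gene set.

RELIABILITY_SENTINEL <- 1e12

vip_from_core <- function(core, p) {
  sqrt(p * drop(core$W^2 %*% core$ssy) / sum(core$ssy))
}

resolve_genes <- function(x, genes) {
  nm <- colnames(x)
  if (is.logical(genes)) {
    if (length(genes) != ncol(x)) stop("logical gene selector has wrong length")
    return(which(genes))
  }
  if (is.numeric(genes)) {
    genes <- as.integer(genes)
    if (any(genes < 1L | genes > ncol(x))) stop("gene index out of range")
    return(genes)
  }
  if (is.null(nm)) stop("`x` has no column names; select genes by index")
  idx <- match(genes, nm)
  if (anyNA(idx)) {
    stop("unknown gene id(s): ", paste(head(genes[is.na(idx)], 5L), collapse = ", "))
  }
  idx
}

#' Permutation-based empirical FDR for VIP scores
#'
#' Fits PLS1 with `ncomp` components, computes each gene's VIP, and builds an
#' empirical null by refitting after random permutation of the response
#' (`n_perm` replicates, each reusing the observed `ncomp`). The FDR at a
#' gene's VIP value `v` is the pooled permutation tail-ratio estimator
#' \deqn{\widehat{FDR}(v) = \min\!\left(1,
#'   \frac{\frac1B\sum_b \#\{k: VIP_k^{(b)} \ge v\}}{\#\{k: VIP_k \ge v\}}\right),}
#' monotonised from the largest VIP down (so the top-ranked gene always has
#' the smallest FDR) and capped at 1.
#'
#' If a permuted fit cannot reach `ncomp` components (a numerically exhausted
#' deflation), the replicate is refitted with the largest feasible count and
#' the number of such replicates is reported in the result.
#'
#' @inheritParams pls1.default
#' @param n_perm number of response permutations, `>= 1`.
#' @param seed integer seed controlling the permutations.
#' @return List with named vectors `vip` and `fdr`, plus `ncomp`, `n_perm`
#'   and `n_partial` (replicates refitted with fewer components).
#' @export
permutation_vip_fdr <- function(x, y, ncomp, n_perm = 1000L, seed = 1L,
                                scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n_perm <- check_count(n_perm, "n_perm", lower = 1L)
  ncomp <- check_count(ncomp, "ncomp", lower = 1L)
  p <- ncol(x)
  sc <- scale_xy(x, y, scale)
  obs <- pls1_core(sc$xs, sc$yc, ncomp)
  v <- vip_from_core(obs, p)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  names(v) <- nm

  null_pool <- numeric(n_perm * p)
  n_partial <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(sc$yc)
      core <- pls1_core(sc$xs, yp, ncomp, allow_partial = TRUE)
      if (core$ncomp < ncomp) n_partial <- n_partial + 1L
      null_pool[((b - 1L) * p + 1L):(b * p)] <- vip_from_core(core, p)
    }
  })
  if (n_partial > 0L) {
    message(sprintf(paste0("permutation_vip_fdr: %d permutation fit(s) used ",
                           "fewer than %d components"), n_partial, ncomp))
  }

  # Tail counts: R(v) over observed VIPs, V(v) over the pooled null.
  R <- p - rank(v, ties.method = "min") + 1L
  sp <- sort(null_pool)
  V <- (length(sp) - findInterval(v, sp, left.open = TRUE)) / n_perm
  fdr_raw <- pmin(1, V / R)
  ord <- order(v, decreasing = TRUE)
  fdr <- fdr_raw
  fdr[ord] <- rev(cummin(rev(fdr_raw[ord])))
  names(fdr) <- nm
  list(vip = v, fdr = fdr, ncomp = ncomp, n_perm = n_perm,
       n_partial = n_partial)
}

#' Monte Carlo regression-coefficient reliability
#'
#' Refits PLS1 on `n_subsets` random subsets of the samples (drawn without
#' replacement, each of size `floor(fraction * n)`) restricted to the
#' candidate genes, and summarises each gene's regression coefficient across
#' the subset models as a signal-to-noise ratio,
#' \deqn{reliability_j = mean_b(b_j^{(b)}) / sd_b(b_j^{(b)}),}
#' with the sample standard deviation (n - 1 denominator). A large absolute
#' reliability means the coefficient is both large and stable under
#' resampling. Coefficients are on the original (unscaled) gene scale.
#'
#' When the coefficient spread across subsets collapses below `1e-12` (for
#' example a gene that reproduces the response exactly), the reliability is
#' the documented sentinel `sign(mean) * 1e12`, which passes any finite
#' cutoff.
#'
#' @inheritParams permutation_vip_fdr
#' @param candidates candidate genes: column names, indices or a logical
#'   mask over the columns of `x`.
#' @param n_subsets number of Monte Carlo subsets, `>= 2`.
#' @param fraction fraction of samples per subset, in (0, 1); the subset
#'   size must be at least `ncomp + 2`.
#' @return Named numeric vector of reliabilities, one per candidate gene.
#' @export
mc_reliability <- function(x, y, candidates, ncomp, n_subsets = 100L,
                           fraction = 0.5, seed = 1L, scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  ncomp <- check_count(ncomp, "ncomp", lower = 1L)
  n_subsets <- check_count(n_subsets, "n_subsets")
  if (n_subsets < 2L) stop("`n_subsets` must be >= 2 (the coefficient spread is undefined otherwise)")
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  idx <- resolve_genes(x, candidates)
  if (length(idx) == 0L) stop("`candidates` is empty")
  m <- floor(fraction * n)
  if (m < ncomp + 2L) {
    stop(sprintf("subset size %d too small for ncomp = %d (need >= ncomp + 2)",
                 m, ncomp))
  }
  xc <- x[, idx, drop = FALSE]
  a_sub <- min(ncomp, m - 1L, length(idx))
  coefs <- matrix(NA_real_, length(idx), n_subsets)
  with_seed(seed, {
    for (b in seq_len(n_subsets)) {
      rows <- sample(n, m)
      sc <- scale_xy(xc[rows, , drop = FALSE], y[rows], scale)
      core <- pls1_core(sc$xs, sc$yc, a_sub, allow_partial = TRUE)
      coefs[, b] <- pls_coef(core$W, core$P, core$q) / sc$x_scale
    }
  })
  mu <- rowMeans(coefs)
  s <- apply(coefs, 1L, sd)
  rel <- mu / s
  degen <- s < 1e-12
  if (any(degen)) {
    message(sprintf("mc_reliability: %d gene(s) with zero coefficient spread; using sentinel reliability",
                    sum(degen)))
    rel[degen] <- sign(mu[degen]) * RELIABILITY_SENTINEL
  }
  nm <- colnames(xc)
  if (is.null(nm)) nm <- paste0("V", idx)
  setNames(rel, nm)
}

#' Choose the reliability cutoff by RMSECV
#'
#' Scans a grid of cutoff values over the candidates' absolute reliabilities
#' (`grid_size` quantiles plus the exact value 0), refits PLS1 on the genes
#' whose absolute reliability strictly exceeds each cutoff, and returns the
#' cutoff with the lowest k-fold RMSECV. The fold partition is drawn once and
#' shared across the scan so that cutoffs are compared on identical splits.
#' RMSECV ties are broken toward the larger cutoff (the sparser model);
#' cutoffs that would leave no gene are not considered.
#'
#' @inheritParams mc_reliability
#' @param reliability named reliability vector over the candidates, as from
#'   [mc_reliability()].
#' @param folds number of cross-validation folds.
#' @param grid_size number of quantile grid points.
#' @param sample_ids optional sample identifiers forwarded to [rmsecv()].
#' @return List with `cutoff` and `curve` (data.frame with columns `cutoff`,
#'   `n_genes`, `rmsecv`).
#' @export
select_reliability_cutoff <- function(x, y, candidates, reliability, ncomp,
                                      folds = 4L, seed = 1L, grid_size = 100L,
                                      scale = TRUE, sample_ids = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  idx <- resolve_genes(x, candidates)
  if (length(idx) < 2L) stop("need >= 2 candidate genes to scan a cutoff")
  if (length(reliability) != length(idx)) {
    stop("`reliability` must have one value per candidate")
  }
  grid_size <- check_count(grid_size, "grid_size", lower = 2L)
  ncomp <- check_count(ncomp, "ncomp", lower = 1L)
  ar <- abs(reliability)
  if (diff(range(ar)) == 0) {
    warning("all candidate reliabilities are equal; returning the common value")
    return(list(cutoff = ar[[1L]],
                curve = data.frame(cutoff = ar[[1L]], n_genes = 0L,
                                   rmsecv = NA_real_)))
  }
  grid <- sort(unique(c(0, quantile(ar, probs = seq(0, 1, length.out = grid_size),
                                    names = FALSE))))
  grid <- grid[grid < max(ar)]  # a cutoff must leave >= 1 gene
  fold_id <- make_folds(nrow(x), folds, seed, sample_ids)
  min_train <- nrow(x) - max(tabulate(fold_id))
  cache <- new.env(parent = emptyenv())
  n_genes <- integer(length(grid))
  rms <- numeric(length(grid))
  for (i in seq_along(grid)) {
    keep <- idx[ar > grid[i]]
    n_genes[i] <- length(keep)
    key <- paste(keep, collapse = ",")
    if (is.null(cache[[key]])) {
      a <- min(ncomp, length(keep), min_train - 1L)
      cache[[key]] <- as.numeric(rmsecv(x[, keep, drop = FALSE], y, ncomp = a,
                                        fold_id = fold_id, scale = scale))
    }
    rms[i] <- cache[[key]]
  }
  best <- max(grid[rms <= min(rms) + 1e-12])
  list(cutoff = best,
       curve = data.frame(cutoff = grid, n_genes = n_genes, rmsecv = rms))
}

#' Select phenotype-associated genes by PLS, permutation FDR and Monte Carlo
#' reliability
#'
#' The full selection procedure for a continuous phenotype: (1) choose the
#' number of latent components by k-fold RMSECV ([choose_ncomp()]); (2) score
#' every gene by VIP and estimate a permutation-based empirical FDR
#' ([permutation_vip_fdr()]); genes with `fdr < alpha` become candidates;
#' (3) compute Monte Carlo half-sample regression-coefficient reliability on
#' the candidates ([mc_reliability()]); (4) pick the absolute-reliability
#' cutoff with the lowest RMSECV ([select_reliability_cutoff()]). The
#' selected set is the candidates whose absolute reliability strictly
#' exceeds the cutoff.
#'
#' Defaults follow the published procedure: 4 folds, 1,000 permutations,
#' FDR threshold 0.05, 100 Monte Carlo subsets of half the samples.
#'
#' All randomness (fold partitions, permutations, subsets) derives from the
#' single `seed`, so a rerun with identical inputs reproduces the result
#' exactly.
#'
#' @inheritParams pls1.default
#' @param a_max largest number of latent components considered.
#' @param folds cross-validation folds for both component and cutoff choice.
#' @param n_perm permutation replicates for the VIP null.
#' @param alpha FDR threshold defining candidate genes.
#' @param n_subsets Monte Carlo subsets for the reliability.
#' @param fraction fraction of samples per Monte Carlo subset.
#' @param grid_size cutoff grid resolution.
#' @param rel_tol elbow tolerance for [choose_ncomp()].
#' @param order stage order. `"default"` chooses the component count first
#'   and computes VIP/FDR at that count; `"paper"` follows the published
#'   narrative, computing VIP/FDR at `a_max` components before the
#'   cross-validated count is chosen for the reliability stages. (VIP needs
#'   a fixed component count either way.)
#' @param seed master seed; per-stage seeds are derived from it.
#' @param sample_ids optional sample identifiers making fold partitions
#'   invariant to sample order.
#' @return An object of class `plsmc_selection`: a list with `genes` (a
#'   data.frame with columns `gene`, `vip`, `fdr`, `reliability`,
#'   `candidate`, `selected`), `a_star`, `cutoff`, the two RMSECV curves
#'   (`component_curve`, `cutoff_curve`), `counts` and `params`.
#' @export
#' @examples
#' sim <- simulate_study(n_samples = 40, n_genes = 60, n_informative = 5,
#'                       seed = 7)
#' sel <- select_genes(sim$data, a_max = 3, n_perm = 50, n_subsets = 20,
#'                     seed = 7)
#' sel
select_genes <- function(x, ...) UseMethod("select_genes")

#' @rdname select_genes
#' @export
select_genes.expression_dataset <- function(x, ...) {
  if (is.null(x$phenotype)) stop("dataset has no phenotype; use join_phenotype()")
  select_genes.default(t(x$values), x$phenotype, sample_ids = x$sample_ids, ...)
}

#' @rdname select_genes
#' @export
select_genes.default <- function(x, y, a_max = 10L, folds = 4L,
                                 n_perm = 1000L, alpha = 0.05,
                                 n_subsets = 100L, fraction = 0.5,
                                 grid_size = 100L, rel_tol = 0.01,
                                 scale = TRUE, order = c("default", "paper"),
                                 seed = 1L, sample_ids = NULL, ...) {
  order <- match.arg(order)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 8L) stop("need at least 8 samples for 4-fold cross-validation")
  if (p < 2L) stop("need at least 2 genes")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  nm <- colnames(x)
  if (is.null(nm)) {
    nm <- paste0("V", seq_len(p))
    colnames(x) <- nm
  }
  # Feasibility cap: every CV fold and every half-sample refit must support
  # the requested component count.
  min_train <- n - ceiling(n / folds)
  a_cap <- min(a_max, min_train - 1L, floor(fraction * n) - 2L, p)
  if (a_cap < a_max) {
    message(sprintf("select_genes: capping a_max at %d for feasibility", a_cap))
  }
  a_max <- a_cap
  if (a_max < 1L) stop("too few samples for any latent component")

  seed_cv <- derive_seed(seed, 1L)
  seed_perm <- derive_seed(seed, 2L)
  seed_mc <- derive_seed(seed, 3L)
  seed_cut <- derive_seed(seed, 4L)

  cn <- choose_ncomp(x, y, a_max = a_max, folds = folds, seed = seed_cv,
                     rel_tol = rel_tol, scale = scale, sample_ids = sample_ids)
  a_star <- cn$a_star
  a_fdr <- if (order == "paper") a_max else a_star
  pf <- permutation_vip_fdr(x, y, ncomp = a_fdr, n_perm = n_perm,
                            seed = seed_perm, scale = scale)
  candidate <- pf$fdr < alpha
  cand_ids <- nm[candidate]

  reliability <- setNames(rep(NA_real_, p), nm)
  cutoff <- NA_real_
  cutoff_curve <- NULL
  selected <- setNames(rep(FALSE, p), nm)
  if (length(cand_ids) >= 1L) {
    rel <- mc_reliability(x, y, candidates = cand_ids, ncomp = a_star,
                          n_subsets = n_subsets, fraction = fraction,
                          seed = seed_mc, scale = scale)
    reliability[cand_ids] <- rel
    if (length(cand_ids) >= 2L) {
      cut <- select_reliability_cutoff(x, y, candidates = cand_ids,
                                       reliability = rel, ncomp = a_star,
                                       folds = folds, seed = seed_cut,
                                       grid_size = grid_size, scale = scale,
                                       sample_ids = sample_ids)
      cutoff <- cut$cutoff
      cutoff_curve <- cut$curve
    } else {
      cutoff <- 0
    }
    selected[cand_ids] <- abs(rel) > cutoff
  }

  genes <- data.frame(gene = nm, vip = unname(pf$vip), fdr = unname(pf$fdr),
                      reliability = unname(reliability),
                      candidate = unname(candidate),
                      selected = unname(selected),
                      stringsAsFactors = FALSE)
  structure(list(
    genes = genes,
    a_star = a_star,
    cutoff = cutoff,
    component_curve = cn$curve,
    cutoff_curve = cutoff_curve,
    counts = c(genes = p, candidates = sum(candidate),
               selected = sum(selected)),
    params = list(a_max = a_max, folds = folds, n_perm = n_perm,
                  alpha = alpha, n_subsets = n_subsets, fraction = fraction,
                  grid_size = grid_size, rel_tol = rel_tol, scale = scale,
                  order = order, seed = seed, a_fdr = a_fdr,
                  n_partial_perm = pf$n_partial),
    n_samples = n
  ), class = "plsmc_selection")
}

#' @export
print.plsmc_selection <- function(x, ...) {
  cat("PLS + Monte Carlo gene selection\n")
  cat(sprintf("  %d samples, %d genes\n", x$n_samples, x$counts[["genes"]]))
  cat(sprintf("  latent components (RMSECV): %d\n", x$a_star))
  cat(sprintf("  candidates (VIP permutation FDR < %g): %d\n",
              x$params$alpha, x$counts[["candidates"]]))
  cat(sprintf("  reliability cutoff (RMSECV): %s\n",
              if (is.na(x$cutoff)) "NA" else format(x$cutoff, digits = 4)))
  cat(sprintf("  selected genes: %d\n", x$counts[["selected"]]))
  invisible(x)
}

#' @export
summary.plsmc_selection <- function(object, n_top = 10L, ...) {
  g <- object$genes[object$genes$selected, , drop = FALSE]
  g <- g[order(-abs(g$reliability), g$gene), , drop = FALSE]
  print(object)
  cat(sprintf("\nTop %d selected genes by |reliability|:\n",
              min(n_top, nrow(g))))
  print(head(g, n_top), row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
as.data.frame.plsmc_selection <- function(x, ...) x$genes

#' Selected gene identifiers
#'
#' @param x a `plsmc_selection` object.
#' @return Character vector of the selected genes.
#' @export
selected_genes <- function(x) {
  stopifnot(inherits(x, "plsmc_selection"))
  x$genes$gene[x$genes$selected]
}

#' @export
plot.plsmc_selection <- function(x, type = c("components", "cutoff", "vip"),
                                 ...) {
  type <- match.arg(type)
  if (type == "components") {
    plot(x$component_curve$ncomp, x$component_curve$rmsecv, type = "b",
         xlab = "latent components", ylab = "RMSECV", ...)
    abline(v = x$a_star, lty = 2)
  } else if (type == "cutoff") {
    if (is.null(x$cutoff_curve)) stop("no cutoff curve available")
    plot(x$cutoff_curve$cutoff, x$cutoff_curve$rmsecv, type = "b",
         xlab = "|reliability| cutoff", ylab = "RMSECV", ...)
    abline(v = x$cutoff, lty = 2)
  } else {
    plot(x$genes$vip, x$genes$fdr, xlab = "VIP", ylab = "empirical FDR",
         col = ifelse(x$genes$selected, 2L, 1L), ...)
    abline(h = x$params$alpha, lty = 2)
  }
  invisible(x)
}
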