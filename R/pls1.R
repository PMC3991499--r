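#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single continuous response on a
#' (typically wide) predictor matrix, computed by the non-linear iterative
#' partial least squares (NIPALS) algorithm. For a scalar response the NIPALS
#' inner loop converges in one pass, so the direct PLS1 recursion is used:
#' with `X` centred (and by default autoscaled to unit column variance) and
#' `y` centred, each component takes
#' \deqn{w_a = X^T y / \|X^T y\|,\quad t_a = X w_a,\quad
#'       p_a = X^T t_a / t_a^T t_a,\quad q_a = y^T t_a / t_a^T t_a,}
#' followed by deflation `X <- X - t_a p_a^T`, `y <- y - q_a t_a`. The
#' regression coefficients are `b = W (P^T W)^{-1} q`, mapped back through
#' the centring/scaling. Fitting is deterministic.
#'
#' @param x predictor matrix with samples in rows and genes (variables) in
#'   columns, or an [expression_dataset()] carrying a phenotype (rows are
#'   genes and are transposed internally).
#' @param y numeric response vector, one value per sample (ignored for the
#'   `expression_dataset` method, which uses the stored phenotype).
#' @param ncomp number of latent components, `1 <= ncomp <= min(n - 1, p)`.
#' @param scale autoscale predictor columns to unit variance (the
#'   conventional scaling under which VIP is defined). Zero-variance columns
#'   are an error when `TRUE`; filter them first with
#'   [drop_degenerate_genes()].
#' @param deflate_y deflate the response during fitting (classical NIPALS).
#'   For PLS1 the fit is identical without deflation; the switch exists to
#'   make that identity checkable.
#' @param ... passed between methods.
#'
#' @return An object of class `pls1`: a list with the weight matrix
#'   `weights` (p x A, unit-norm columns), `scores` (n x A, mutually
#'   orthogonal), `x_loadings`, `y_loadings`, per-component explained
#'   response variation `ssy` (`q_a^2 t_a^T t_a`), coefficients on the
#'   original predictor scale (`coefficients`) and on the centred/scaled
#'   scale (`coefficients_scaled`), the centring/scaling vectors, fitted
#'   values and residuals.
#' @seealso [vip()], [rmsecv()], [choose_ncomp()], [predict.pls1()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 15), 40, 15)
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(40, sd = 0.3)
#' fit <- pls1(x, y, ncomp = 2)
#' fit
#' head(coef(fit))
pls1 <- function(x, ...) UseMethod("pls1")

#' @rdname pls1
#' @export
pls1.expression_dataset <- function(x, ncomp = 2L, scale = TRUE, ...) {
  if (is.null(x$phenotype)) stop("dataset has no phenotype; use join_phenotype()")
  pls1.default(t(x$values), x$phenotype, ncomp = ncomp, scale = scale, ...)
}

#' @rdname pls1
#' @export
pls1.default <- function(x, y, ncomp = 2L, scale = TRUE, deflate_y = TRUE, ...) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("`y` must have one value per row of `x`")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  ncomp <- check_count(ncomp, "ncomp", lower = 1L)
  if (ncomp > min(n - 1L, p)) {
    stop(sprintf("ncomp = %d exceeds min(n - 1, p) = %d", ncomp, min(n - 1L, p)))
  }
  if (sd(y) == 0) stop("constant response: PLS1 and downstream statistics are undefined")
  sc <- scale_xy(x, y, scale)
  core <- pls1_core(sc$xs, sc$yc, ncomp, deflate_y = deflate_y)
  b_scaled <- pls_coef(core$W, core$P, core$q)
  b <- b_scaled / sc$x_scale
  gene_ids <- colnames(x)
  if (is.null(gene_ids)) gene_ids <- paste0("V", seq_len(p))
  fitted <- drop(sc$xs %*% b_scaled) + sc$y_center
  comp_ids <- paste0("comp", seq_len(core$ncomp))
  dimnames(core$W) <- list(gene_ids, comp_ids)
  dimnames(core$P) <- list(gene_ids, comp_ids)
  dimnames(core$T) <- list(rownames(x), comp_ids)
  structure(list(
    ncomp = core$ncomp,
    weights = core$W,
    scores = core$T,
    x_loadings = core$P,
    y_loadings = setNames(core$q, comp_ids),
    ssy = setNames(core$ssy, comp_ids),
    coefficients = setNames(b, gene_ids),
    coefficients_scaled = setNames(b_scaled, gene_ids),
    x_center = setNames(sc$x_center, gene_ids),
    x_scale = setNames(sc$x_scale, gene_ids),
    y_center = sc$y_center,
    scaled = scale,
    fitted.values = fitted,
    residuals = y - fitted,
    y = y,
    ss_y = sum(sc$yc^2),
    call = match.call()
  ), class = "pls1")
}

scale_xy <- function(x, y, scale) {
  x_center <- colMeans(x)
  xs <- sweep(x, 2L, x_center, "-")
  if (scale) {
    x_scale <- sqrt(colSums(xs^2) / (nrow(x) - 1L))
    zero <- x_scale <= .Machine$double.eps * 100 * pmax(abs(x_center), 1)
    if (any(zero)) {
      nm <- colnames(x)
      if (is.null(nm)) nm <- as.character(which(zero))
      stop("zero-variance predictor column(s) with scale = TRUE: ",
           paste(head(nm[zero], 5L), collapse = ", "))
    }
    xs <- sweep(xs, 2L, x_scale, "/")
  } else {
    x_scale <- rep(1, ncol(x))
  }
  y_center <- mean(y)
  list(xs = xs, yc = y - y_center, x_center = x_center, x_scale = x_scale,
       y_center = y_center)
}

# Direct PLS1 recursion on pre-centred (and pre-scaled) data.  Shared by the
# public fit and the permutation / Monte-Carlo loops, which re-centre y only.
pls1_core <- function(xs, yc, ncomp, allow_partial = FALSE, deflate_y = TRUE) {
  n <- nrow(xs)
  p <- ncol(xs)
  W <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xa <- xs
  ya <- yc
  s0 <- sqrt(sum(crossprod(xs, yc)^2))
  if (s0 == 0) stop("X'y is exactly zero: no covariance between predictors and response")
  a <- 0L
  for (k in seq_len(ncomp)) {
    s <- drop(crossprod(Xa, ya))
    ns <- sqrt(sum(s^2))
    if (ns <= 1e-12 * s0) {
      if (allow_partial) break
      stop(sprintf("deflated X'y numerically zero at component %d; use ncomp <= %d",
                   k, k - 1L))
    }
    w <- s / ns
    t <- drop(Xa %*% w)
    tt <- sum(t * t)
    if (tt <= 1e-24 * s0) {
      if (allow_partial) break
      stop(sprintf("degenerate score vector at component %d; use ncomp <= %d",
                   k, k - 1L))
    }
    pk <- drop(crossprod(Xa, t)) / tt
    qk <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pk)
    if (deflate_y) ya <- ya - qk * t
    W[, k] <- w
    Tm[, k] <- t
    P[, k] <- pk
    q[k] <- qk
    ssy[k] <- qk^2 * tt
    a <- k
  }
  keep <- seq_len(a)
  list(W = W[, keep, drop = FALSE], T = Tm[, keep, drop = FALSE],
       P = P[, keep, drop = FALSE], q = q[keep], ssy = ssy[keep], ncomp = a)
}

pls_coef <- function(W, P, q) {
  R <- crossprod(P, W)
  b <- tryCatch(W %*% solve(R, q),
                error = function(e) stop("singular P'W matrix: reduce ncomp",
                                         call. = FALSE))
  drop(b)
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 regression (NIPALS)\n")
  cat(sprintf("  %d samples, %d predictors, %d component(s)%s\n",
              length(x$y), length(x$coefficients), x$ncomp,
              if (x$scaled) ", autoscaled predictors" else ""))
  cat(sprintf("  cumulative response variation explained: %.1f%%\n",
              100 * sum(x$ssy) / x$ss_y))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, intercept = FALSE, ...) {
  b <- object$coefficients
  if (intercept) {
    c("(Intercept)" = object$y_center - sum(object$x_center * b), b)
  } else {
    b
  }
}

#' Predict from a fitted PLS1 model
#'
#' @param object a [pls1()] fit.
#' @param newdata matrix with the model's predictors as columns (in the
#'   fitted gene order), or an [expression_dataset()]; omitted, returns the
#'   training fitted values.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "expression_dataset")) newdata <- t(newdata$values)
  newdata <- as.matrix(newdata)
  p <- length(object$coefficients)
  if (ncol(newdata) != p) {
    stop(sprintf("`newdata` has %d columns; model was fitted with %d predictors",
                 ncol(newdata), p))
  }
  xs <- sweep(sweep(newdata, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  drop(xs %*% object$coefficients_scaled) + object$y_center
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
summary.pls1 <- function(object, ...) {
  prop <- object$ssy / object$ss_y
  tab <- data.frame(ncomp = seq_len(object$ncomp),
                    ssy = object$ssy,
                    prop_y_var = prop,
                    cum_y_var = cumsum(prop))
  rownames(tab) <- NULL
  structure(list(components = tab,
                 r_squared = 1 - sum(object$residuals^2) / object$ss_y,
                 n = length(object$y), p = length(object$coefficients),
                 scaled = object$scaled),
            class = "summary.pls1")
}

#' @export
print.summary.pls1 <- function(x, digits = 4L, ...) {
  cat(sprintf("PLS1 regression: %d samples, %d predictors%s\n", x$n, x$p,
              if (x$scaled) " (autoscaled)" else ""))
  print(format(x$components, digits = digits), row.names = FALSE)
  cat(sprintf("Training R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
plot.pls1 <- function(x, type = c("prediction", "variance", "scores"), ...) {
  type <- match.arg(type)
  if (type == "prediction") {
    plot(x$y, x$fitted.values, xlab = "observed response",
         ylab = "fitted response", main = "PLS1 training fit", ...)
    abline(0, 1, lty = 2)
  } else if (type == "variance") {
    barplot(100 * x$ssy / x$ss_y, names.arg = names(x$ssy),
            ylab = "% response variation explained", ...)
  } else {
    if (x$ncomp < 2L) stop("score plot needs >= 2 components")
    plot(x$scores[, 1L], x$scores[, 2L], xlab = "t1", ylab = "t2",
         main = "PLS1 scores", ...)
  }
  invisible(x)
}

#' Variable importance on the projection (VIP)
#'
#' Per-gene importance aggregating squared NIPALS weights across components,
#' each component weighted by the response variation it explains:
#' \deqn{VIP_j = \sqrt{p \sum_a ssy_a w_{aj}^2 / \sum_a ssy_a}}
#' (weight columns are unit-norm). The scores satisfy the normalisation
#' `sum(VIP^2) == p`, so VIP = 1 is the "average importance" reference line.
#'
#' @param model a fitted [pls1()] model.
#' @return Named numeric vector of VIP scores, one per gene.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls1"))
  tot <- sum(model$ssy)
  if (tot <= 0) stop("model explains zero response variance; VIP undefined")
  p <- nrow(model$weights)
  sqrt(p * drop(model$weights^2 %*% model$ssy) / tot)
}

# Fold assignment used by all cross-validation in the package.  When sample
# ids are given, folds are drawn against the ids in sorted order so that the
# partition attaches to samples, not to row positions.
make_folds <- function(n, folds, seed, sample_ids = NULL) {
  folds <- check_count(folds, "folds", lower = 2L)
  if (folds > n) stop("more folds than samples")
  f <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
      stop("`sample_ids` must be unique and one per sample")
    }
    f <- f[rank(sample_ids, ties.method = "first")]
  }
  f
}

#' Root mean square error of cross-validation
#'
#' Out-of-fold prediction error of PLS1,
#' \deqn{RMSECV = \sqrt{\frac1n \sum_i (y_i - \hat y_i^{(-fold(i))})^2},}
#' used both to pick the number of latent components and to pick the
#' reliability cutoff. The random fold partition is controlled entirely by
#' `seed` (or supplied explicitly via `fold_id`); `ncomp = 0` is allowed and
#' means prediction by the fold-training mean.
#'
#' @inheritParams pls1.default
#' @param ncomp vector of component counts to evaluate (each `>= 0`).
#'   Per-fold models are fitted once at `max(ncomp)`; smaller counts reuse
#'   the leading components (PLS1 models are nested).
#' @param folds number of folds, `>= 2`; every fold must leave at least two
#'   training samples.
#' @param seed integer seed for the fold partition.
#' @param sample_ids optional unique sample identifiers; when given, the
#'   partition is drawn against the sorted identifiers, making the result
#'   invariant to row reordering.
#' @param fold_id optional explicit fold assignment (length n, values in
#'   `1..folds`); overrides `seed`.
#' @return Numeric vector of RMSECV values named by `ncomp` (a bare scalar if
#'   a single `ncomp` was requested), with the fold assignment attached as
#'   attribute `"fold_id"`.
#' @export
rmsecv <- function(x, y, ncomp, folds = 4L, seed = 1L, scale = TRUE,
                   sample_ids = NULL, fold_id = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("`y` must have one value per row of `x`")
  ncomp <- vapply(ncomp, check_count, integer(1L), name = "ncomp")
  if (is.null(fold_id)) {
    fold_id <- make_folds(n, folds, seed, sample_ids)
  } else {
    if (length(fold_id) != n) stop("`fold_id` must have length n")
    fold_id <- as.integer(fold_id)
  }
  fold_levels <- sort(unique(fold_id))
  a_max <- max(ncomp)
  for (f in fold_levels) {
    n_train <- sum(fold_id != f)
    if (n_train < 2L) stop("fold too small: fewer than 2 training samples")
    if (a_max > min(n_train - 1L, ncol(x))) {
      stop(sprintf("ncomp = %d infeasible: a fold leaves only %d training samples",
                   a_max, n_train))
    }
  }
  pred <- matrix(NA_real_, n, length(ncomp))
  for (f in fold_levels) {
    test <- fold_id == f
    xtr <- x[!test, , drop = FALSE]
    ytr <- y[!test]
    sc <- scale_xy(xtr, ytr, scale)
    xte <- sweep(sweep(x[test, , drop = FALSE], 2L, sc$x_center, "-"),
                 2L, sc$x_scale, "/")
    # allow_partial: on (near-)exactly low-rank training data the deflation
    # exhausts early; larger counts then reuse the largest achievable model,
    # flattening the RMSECV curve instead of failing.
    core <- if (a_max >= 1L) pls1_core(sc$xs, sc$yc, a_max, allow_partial = TRUE)
            else NULL
    for (j in seq_along(ncomp)) {
      a <- ncomp[j]
      if (a == 0L) {
        pred[test, j] <- sc$y_center
      } else {
        ka <- seq_len(min(a, core$ncomp))
        b <- pls_coef(core$W[, ka, drop = FALSE], core$P[, ka, drop = FALSE],
                      core$q[ka])
        pred[test, j] <- drop(xte %*% b) + sc$y_center
      }
    }
  }
  out <- sqrt(colMeans((y - pred)^2))
  if (length(ncomp) > 1L) names(out) <- as.character(ncomp)
  attr(out, "fold_id") <- fold_id
  out
}

#' Choose the number of latent components by RMSECV
#'
#' Computes the RMSECV curve for `ncomp = 1..a_max` and returns the smallest
#' component count after which the relative improvement falls below
#' `rel_tol` (the "descending trend loses strength" elbow rule), capped at
#' the argmin of the curve. `rel_tol = 0` reduces to the argmin.
#'
#' @inheritParams rmsecv
#' @param a_max largest component count to consider, `>= 1`.
#' @param rel_tol relative-improvement threshold for the elbow rule.
#' @return List with `a_star` (chosen count) and `curve` (data.frame with
#'   columns `ncomp`, `rmsecv`).
#' @export
choose_ncomp <- function(x, y, a_max = 10L, folds = 4L, seed = 1L,
                         rel_tol = 0.01, scale = TRUE, sample_ids = NULL,
                         fold_id = NULL) {
  a_max <- check_count(a_max, "a_max", lower = 1L)
  check_scalar_number(rel_tol, "rel_tol", lower = 0)
  cv <- rmsecv(x, y, ncomp = seq_len(a_max), folds = folds, seed = seed,
               scale = scale, sample_ids = sample_ids, fold_id = fold_id)
  curve <- as.numeric(cv)
  a_star <- a_max
  if (a_max > 1L) {
    impr <- ifelse(curve[-a_max] <= 0, 0,
                   (curve[-a_max] - curve[-1L]) / curve[-a_max])
    flat <- which(impr < rel_tol)
    if (length(flat)) a_star <- flat[1L]
  }
  a_star <- min(a_star, which.min(curve))
  list(a_star = as.integer(a_star),
       curve = data.frame(ncomp = seq_len(a_max), rmsecv = curve))
}
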