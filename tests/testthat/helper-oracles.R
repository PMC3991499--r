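# Independent oracles the implementation is checked against.  Each one takes
# a different algorithmic route from the code under test.

# PLS1 via projection on the Krylov space span{s, Ms, M^2 s, ...} of
# M = X'X and s = X'y (Helland's formulation): the fitted coefficient vector
# with `a` components is the least-squares solution restricted to that
# subspace.  Built with Gram-Schmidt + reorthogonalisation; no deflation, no
# NIPALS recursion.
oracle_pls1_coef <- function(x, y, ncomp, scale = TRUE) {
  x <- as.matrix(x)
  x_center <- colMeans(x)
  xs <- sweep(x, 2, x_center)
  sds <- if (scale) sqrt(colSums(xs^2) / (nrow(x) - 1)) else rep(1, ncol(x))
  xs <- sweep(xs, 2, sds, "/")
  yc <- y - mean(y)
  s <- drop(crossprod(xs, yc))
  M <- crossprod(xs)
  K <- matrix(0, ncol(x), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    if (a > 1) v <- drop(M %*% K[, a - 1])
    prev <- K[, seq_len(a - 1), drop = FALSE]
    for (pass in 1:2) v <- v - drop(prev %*% crossprod(prev, v))
    K[, a] <- v / sqrt(sum(v^2))
  }
  b_scaled <- drop(K %*% solve(crossprod(K, M %*% K), crossprod(K, s)))
  b <- b_scaled / sds
  list(coef = b, intercept = mean(y) - sum(x_center * b))
}

# Tukey's median polish written directly from the algorithm description:
# alternate row-median and column-median sweeps (rows first), folding the
# medians of the running effects into the overall term, until the total
# absolute residual stabilises.
oracle_median_polish <- function(x, tol = 0.01, max_iter = 10) {
  z <- x
  overall <- 0
  rowe <- rep(0, nrow(x))
  cole <- rep(0, ncol(x))
  oldsum <- 0
  for (it in seq_len(max_iter)) {
    rd <- apply(z, 1, median)
    z <- z - rd
    rowe <- rowe + rd
    d <- median(cole)
    cole <- cole - d
    overall <- overall + d
    cd <- apply(z, 2, median)
    z <- sweep(z, 2, cd)
    cole <- cole + cd
    d <- median(rowe)
    rowe <- rowe - d
    overall <- overall + d
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, row_effects = rowe, col_effects = cole,
       residuals = z)
}

# Upper-tail hypergeometric probability by brute-force enumeration of every
# size-n draw from a background where genes 1..K carry the annotation.
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Degree of each node by direct neighbour counting over a deduplicated
# undirected edge list.
oracle_degrees <- function(edges, nodes) {
  vapply(nodes, function(g) {
    sum(edges$geneA == g) + sum(edges$geneB == g)
  }, integer(1))
}

# Small planted-signal regression problem used across selection tests.
make_planted <- function(n, p, planted = 1L, beta = 1, noise_sd = 1,
                         seed = 1L, y_noise_sd = 0) {
  set.seed(seed)
  y <- rnorm(n)
  x <- matrix(rnorm(n * p, sd = noise_sd), n, p)
  for (j in seq_len(planted)) x[, j] <- beta * y + rnorm(n, sd = y_noise_sd)
  colnames(x) <- sprintf("g%03d", seq_len(p))
  list(x = x, y = y, planted = colnames(x)[seq_len(planted)])
}
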