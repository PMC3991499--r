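test_that("a planted gene attains the top VIP and a near-zero FDR", {
  pl <- make_planted(n = 40, p = 100, planted = 1, seed = 31)
  pf <- permutation_vip_fdr(pl$x, pl$y, ncomp = 1, n_perm = 200, seed = 31)
  expect_equal(names(which.max(pf$vip)), pl$planted)
  expect_lt(pf$fdr[[pl$planted]], 0.05)
  expect_equal(unname(pf$fdr[[pl$planted]]), min(pf$fdr))
})

test_that("FDR estimates are monotone in VIP and properly bounded", {
  set.seed(17)
  x <- matrix(rnorm(30 * 60), 30, 60)
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(30)
  pf <- permutation_vip_fdr(x, y, ncomp = 2, n_perm = 100, seed = 4)
  expect_true(all(pf$fdr >= 0 & pf$fdr <= 1))
  ord <- order(pf$vip, decreasing = TRUE)
  expect_true(all(diff(pf$fdr[ord]) >= 0))
  expect_error(permutation_vip_fdr(x, y, ncomp = 2, n_perm = 0), "n_perm")
})

test_that("FDR estimates are deterministic in the seed and tighten with more permutations", {
  set.seed(23)
  x <- matrix(rnorm(30 * 50), 30, 50)
  y <- x[, 1] * 0.8 + rnorm(30)
  a <- permutation_vip_fdr(x, y, 1, n_perm = 100, seed = 9)
  b <- permutation_vip_fdr(x, y, 1, n_perm = 100, seed = 9)
  expect_identical(a, b)

  spread <- function(B) {
    reps <- vapply(1:8, function(r) {
      permutation_vip_fdr(x, y, 1, n_perm = B, seed = 100 + r)$fdr
    }, numeric(50))
    mean(apply(reps, 1, sd))
  }
  expect_lt(spread(400), spread(100))
})

test_that("Monte Carlo reliability separates a noise-free planted gene from noise", {
  wins <- 0L
  for (r in 1:20) {
    pl <- make_planted(n = 40, p = 20, planted = 1, seed = 200 + r)
    rel <- mc_reliability(pl$x, pl$y, candidates = colnames(pl$x), ncomp = 1,
                          n_subsets = 25, fraction = 0.5, seed = 200 + r)
    if (which.max(abs(rel)) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("reliability contracts: degenerate spread, argument validation, invariances", {
  # a gene exactly reproducing the response has zero coefficient spread
  y <- rnorm(20)
  x <- cbind(sig = y, n1 = rnorm(20), n2 = rnorm(20))
  expect_message(
    rel <- mc_reliability(x, y, candidates = "sig", ncomp = 1,
                          n_subsets = 10, seed = 1),
    "sentinel")
  expect_equal(unname(rel[["sig"]]), 1e12)

  expect_error(mc_reliability(x, y, colnames(x), 1, n_subsets = 1, seed = 1),
               "n_subsets")
  expect_error(mc_reliability(x, y, colnames(x), 1, fraction = 1.2, seed = 1),
               "fraction")
  expect_error(mc_reliability(x, y, character(), 1, seed = 1),
               "empty|unknown")

  # invariant to the order in which candidates are listed
  set.seed(8)
  x2 <- matrix(rnorm(40 * 10), 40, 10,
               dimnames = list(NULL, sprintf("g%02d", 1:10)))
  y2 <- x2[, 3] + rnorm(40)
  r1 <- mc_reliability(x2, y2, colnames(x2), ncomp = 2, n_subsets = 20, seed = 5)
  r2 <- mc_reliability(x2, y2, rev(colnames(x2)), ncomp = 2, n_subsets = 20,
                       seed = 5)
  expect_equal(r1, r2[names(r1)])
})

test_that("the RMSECV cutoff scan discards noise genes but keeps planted ones", {
  set.seed(55)
  n <- 60; p <- 200
  y <- rnorm(n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%03d", 1:p)))
  for (j in 1:5) x[, j] <- 1.5 * y + rnorm(n, sd = 0.6)
  rel <- mc_reliability(x, y, colnames(x), ncomp = 2, n_subsets = 40,
                        fraction = 0.5, seed = 55)
  cut <- select_reliability_cutoff(x, y, colnames(x), rel, ncomp = 2,
                                   folds = 4, seed = 55, grid_size = 60)
  kept <- names(rel)[abs(rel) > cut$cutoff]
  noise_kept <- setdiff(kept, sprintf("g%03d", 1:5))
  expect_lte(length(noise_kept), 0.1 * 195)
  expect_gte(length(intersect(kept, sprintf("g%03d", 1:5))), 4L)
  expect_true(all(c("cutoff", "n_genes", "rmsecv") %in% names(cut$curve)))
})

test_that("cutoff ties resolve toward the sparser model and degenerate grids warn", {
  set.seed(66)
  n <- 32
  y <- rnorm(n)
  x <- cbind(a = y + rnorm(n, sd = 0.1), b = y + rnorm(n, sd = 0.1),
             c = rnorm(n), d = rnorm(n))
  rel <- c(a = 5, b = 4, c = 1, d = 1)
  cut <- select_reliability_cutoff(x, y, colnames(x), rel, ncomp = 1,
                                   folds = 4, seed = 2, grid_size = 7)
  # every grid value in [1, 4) selects exactly {a, b}; if that set wins the
  # scan must return the largest such cutoff
  grid <- sort(unique(c(0, quantile(abs(rel), probs = seq(0, 1, length.out = 7),
                                    names = FALSE))))
  grid <- grid[grid < 5]
  sel_at <- function(th) names(rel)[abs(rel) > th]
  if (setequal(sel_at(cut$cutoff), c("a", "b"))) {
    expect_equal(cut$cutoff, max(grid[grid >= 1 & grid < 4]))
  }
  # identical gene sets must give identical rmsecv entries in the curve
  same <- vapply(cut$curve$cutoff,
                 function(th) paste(sel_at(th), collapse = ","), "")
  expect_true(all(tapply(cut$curve$rmsecv, same, function(v) diff(range(v)) == 0)))

  expect_warning(
    eq <- select_reliability_cutoff(x, y, colnames(x),
                                    c(a = 2, b = 2, c = 2, d = 2),
                                    ncomp = 1, folds = 4, seed = 2),
    "equal")
  expect_equal(eq$cutoff, 2)
})

test_that("the full selection is deterministic and controls a null dataset", {
  sim <- simulate_dataset(n_samples = 40, n_genes = 100, n_informative = 3,
                          effect_size = 2, seed = 12)
  s1 <- select_genes(sim$data, a_max = 3, n_perm = 100, n_subsets = 25,
                     seed = 12)
  s2 <- select_genes(sim$data, a_max = 3, n_perm = 100, n_subsets = 25,
                     seed = 12)
  expect_identical(s1, s2)
  expect_true(all(s1$genes$selected <= s1$genes$candidate))  # selected subset
  expect_s3_class(as.data.frame(s1), "data.frame")

  # with no planted genes almost nothing should survive the funnel
  frac <- vapply(1:10, function(r) {
    nullsim <- simulate_dataset(n_samples = 40, n_genes = 100,
                                n_informative = 0, seed = 300 + r)
    sel <- select_genes(nullsim$data, a_max = 2, n_perm = 100, n_subsets = 25,
                        seed = 300 + r)
    sel$counts[["selected"]] / 100
  }, numeric(1))
  expect_lte(mean(frac), 0.01)
})

test_that("selection defaults mirror the published procedure", {
  f <- formals(getS3method("select_genes", "default"))
  expect_equal(eval(f$alpha), 0.05)
  expect_equal(eval(f$n_perm), 1000L)
  expect_equal(eval(f$n_subsets), 100L)
  expect_equal(eval(f$fraction), 0.5)
  expect_equal(eval(f$folds), 4L)
})

test_that("the paper stage order computes VIP at a_max before choosing components", {
  sim <- simulate_dataset(n_samples = 30, n_genes = 40, n_informative = 3,
                          effect_size = 2, seed = 44)
  sp <- select_genes(sim$data, a_max = 3, n_perm = 60, n_subsets = 20,
                     order = "paper", seed = 44)
  expect_equal(sp$params$a_fdr, 3L)
  sd_ <- select_genes(sim$data, a_max = 3, n_perm = 60, n_subsets = 20,
                      order = "default", seed = 44)
  expect_equal(sd_$params$a_fdr, sd_$a_star)
})
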