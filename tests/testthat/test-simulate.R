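test_that("the dataset generator is bit-reproducible and respects its config", {
  s1 <- simulate_dataset(n_samples = 25, n_genes = 60, n_informative = 4,
                         seed = 3)
  s2 <- simulate_dataset(n_samples = 25, n_genes = 60, n_informative = 4,
                         seed = 3)
  expect_identical(s1, s2)
  expect_equal(dim(s1$data$values), c(60L, 25L))
  expect_length(s1$truth$informative, 4L)
  expect_true(all(s1$truth$effects[s1$truth$informative] != 0))
  expect_true(all(s1$truth$effects[setdiff(names(s1$truth$effects),
                                           s1$truth$informative)] == 0))

  s0 <- simulate_dataset(n_samples = 20, n_genes = 30, n_informative = 0,
                         seed = 4)
  expect_length(s0$truth$informative, 0L)

  expect_error(simulate_dataset(n_genes = 10, n_informative = 11), "<=")
  expect_error(simulate_dataset(noise_sd = 0), "noise_sd")
})

test_that("informative genes correlate with the phenotype more than null genes", {
  for (r in 1:20) {
    sim <- simulate_dataset(n_samples = 100, n_genes = 60, n_informative = 10,
                            effect_size = 1.5, noise_sd = 1, seed = 500 + r)
    cors <- abs(apply(sim$data$values, 1, cor, y = sim$data$phenotype))
    inf <- names(cors) %in% sim$truth$informative
    expect_gt(mean(cors[inf]), mean(cors[!inf]))
  }
})

test_that("batch factors add shared structure without phenotype association", {
  sb <- simulate_dataset(n_samples = 60, n_genes = 40, n_informative = 0,
                         n_batch_factors = 2, batch_sd = 2, seed = 6)
  s0 <- simulate_dataset(n_samples = 60, n_genes = 40, n_informative = 0,
                         n_batch_factors = 0, seed = 6)
  # nuisance factors inflate between-gene correlation
  c_b <- mean(abs(cor(t(sb$data$values))[upper.tri(diag(40))]))
  c_0 <- mean(abs(cor(t(s0$data$values))[upper.tri(diag(40))]))
  expect_gt(c_b, c_0)
})

test_that("the bimodal phenotype mode mixes a low and a high group", {
  sim <- simulate_dataset(n_samples = 80, n_genes = 10, n_informative = 0,
                          phenotype_mode = "bimodal",
                          phenotype_range = c(0, 100), seed = 8)
  y <- sim$data$phenotype
  expect_true(sum(y < 40) >= 35 && sum(y > 60) >= 35)
})

test_that("the annotation generator plants one enriched term", {
  genes <- sprintf("G%04d", 1:300)
  inf <- genes[1:20]
  ann <- simulate_annotation(genes, inf, n_terms = 10, coverage = 1.0, seed = 2)
  planted <- ann$gene[ann$term == "T000_enriched"]
  expect_true(all(inf %in% planted))  # full coverage
  expect_equal(anyDuplicated(ann), 0L)
  expect_identical(ann, simulate_annotation(genes, inf, n_terms = 10,
                                            coverage = 1.0, seed = 2))

  single <- simulate_annotation(genes, inf, n_terms = 1, seed = 3)
  expect_equal(unique(single$term), "T000_enriched")
  expect_error(simulate_annotation(genes[1:5], term_size_range = c(2, 9)),
               "exceeds")
})

test_that("the planted term is detected by the enrichment stage across seeds", {
  hits <- 0L
  for (r in 1:20) {
    genes <- sprintf("G%04d", 1:1000)
    set.seed(900 + r)
    inf <- sort(sample(genes, 25))
    ann <- simulate_annotation(genes, inf, n_terms = 30, coverage = 0.9,
                               seed = 900 + r)
    tab <- enrich(inf, ann, background = genes)
    if (tab$term_id[1] == "T000_enriched") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("the interaction generators realise the requested structure", {
  genes <- sprintf("G%03d", 1:20)
  want <- setNames(c(12L, rep(1L, 12), rep(0L, 7)), genes)
  star <- simulate_interactions(genes, model = "fixed_degree", degrees = want,
                                seed = 1)
  expect_equal(attr(star, "degrees"), want)
  net <- build_network(genes, star, hub_threshold = 10)
  expect_equal(find_hubs(net)$gene, "G001")

  none <- simulate_interactions(genes, model = "fixed_degree",
                                degrees = rep(0L, 20), seed = 1)
  expect_equal(nrow(none), 0L)
  expect_error(simulate_interactions(genes, model = "fixed_degree",
                                     degrees = c(19L, rep(1L, 5), rep(0L, 14))),
               "infeasible")

  pa1 <- simulate_interactions(genes, model = "preferential_attachment",
                               m = 2, seed = 9)
  pa2 <- simulate_interactions(genes, model = "preferential_attachment",
                               m = 2, seed = 9)
  expect_identical(pa1, pa2)
  deg <- attr(pa1, "degrees")
  expect_gt(max(deg), median(deg))
})

test_that("generated files pass the data_io round trips", {
  sim <- simulate_study(n_samples = 16, n_genes = 25, n_informative = 3,
                        n_terms = 5, term_size_range = c(3, 8), seed = 10)
  fx <- withr::local_tempfile(); fp <- withr::local_tempfile()
  fa <- withr::local_tempfile(); fi <- withr::local_tempfile()
  write_expression(sim$data, fx)
  write_phenotype(sim$data$phenotype, fp)
  write_annotation(sim$annotation, fa)
  write_interactions(sim$interactions, fi)
  ds <- join_phenotype(read_expression(fx), read_phenotype(fp))
  expect_equal(ds$values, sim$data$values, tolerance = 1e-12)
  expect_equal(ds$phenotype, sim$data$phenotype, tolerance = 1e-12)
  expect_equal(read_annotation(fa), sim$annotation, ignore_attr = TRUE)
  expect_equal(read_interactions(fi), sim$interactions, ignore_attr = TRUE)
})
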