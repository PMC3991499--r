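test_that("expression TSV round-trips and validates", {
  set.seed(42)
  m <- matrix(round(rnorm(60), 6), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  ds <- read_expression(f)
  expect_equal(ds$values, m)
  expect_equal(ds$gene_ids, rownames(m))
  expect_equal(ds$sample_ids, colnames(m))

  # transpose flag reads a samples x genes layout
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_expression(t(m), ft, id_column = "sample_id")
  expect_equal(read_expression(ft, transpose = TRUE)$values, m)

  # a small fixed fixture
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb\tc\td",
               "# a comment line",
               "g1\t1\t2\t3\t4",
               "g2\t5\t6\t7\t8",
               "g3\t9\t10\t11\t12"), f3)
  ds3 <- read_expression(f3)
  expect_equal(dim(ds3$values), c(3L, 4L))
  expect_equal(ds3$values["g2", "c"], 7)
})

test_that("malformed expression input is rejected with a located error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb", "g1\t1\tNA", "g2\t3\t4"), f)
  expect_error(read_expression(f), "non-numeric value 'NA'.*'g1'.*'b'")

  fd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb", "g1\t1\t2", "g1\t3\t4"), fd)
  expect_error(read_expression(fd), "duplicate gene ids: g1")

  expect_error(expression_dataset(matrix(c(1, NA), 1, 2)), "missing value")
})

test_that("phenotype join refuses silent drops and intersects on request", {
  m <- matrix(1:8 + 0.5, 2, 4,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  ds <- expression_dataset(m)
  ph4 <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  joined <- join_phenotype(ds, ph4)
  expect_equal(joined$phenotype, ph4)

  ph5 <- c(ph4, s5 = 5)
  expect_error(join_phenotype(ds, ph5), "do not match")
  expect_message(j5 <- join_phenotype(ds, ph5, intersect = TRUE),
                 "keeping 4 common samples, dropping 1")
  expect_equal(j5$sample_ids, c("s1", "s2", "s3", "s4"))
  expect_equal(unname(j5$phenotype), 1:4 + 0)

  expect_error(join_phenotype(ds, c(z1 = 1, z2 = 2), intersect = TRUE),
               "no samples in common")
  expect_error(join_phenotype(ds, c(s1 = 1, s1 = 2, s3 = 3, s4 = 4)),
               "duplicate")
})

test_that("sample alignment is invariant to input file row order", {
  set.seed(7)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ph <- c(s1 = 10, s2 = 20, s3 = 30, s4 = 40)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_phenotype(ph, f1)
  write_phenotype(ph[c(3, 1, 4, 2)], f2)
  d1 <- join_phenotype(expression_dataset(m), read_phenotype(f1))
  d2 <- join_phenotype(expression_dataset(m), read_phenotype(f2))
  expect_identical(d1$phenotype, d2$phenotype)
  expect_identical(d1$values, d2$values)
})

test_that("phenotype file round-trips and rejects duplicates", {
  ph <- c(a = 1.25, b = -2.5, c = 0)
  f <- withr::local_tempfile()
  write_phenotype(ph, f)
  expect_equal(read_phenotype(f), ph)

  fd <- withr::local_tempfile()
  writeLines(c("sample_id\tvalue", "a\t1", "a\t2"), fd)
  expect_error(read_phenotype(fd), "duplicate sample ids")
})

test_that("annotation reader collapses duplicates and allows empty tables", {
  f <- withr::local_tempfile()
  writeLines(c("gene\tterm", "g1\tt1", "g2\tt1", "g1\tt2", "g3\tt2",
               "g4\tt3", "g1\tt1"), f)
  expect_message(ann <- read_annotation(f), "collapsed 1 duplicate")
  expect_equal(nrow(ann), 5L)
  expect_true(!anyDuplicated(ann))

  fe <- withr::local_tempfile()
  writeLines("gene\tterm", fe)
  expect_equal(nrow(read_annotation(fe)), 0L)

  # round trip
  fr <- withr::local_tempfile()
  write_annotation(ann, fr)
  expect_equal(read_annotation(fr), ann)
})

test_that("interaction reader preserves order and defers deduplication", {
  f <- withr::local_tempfile()
  writeLines(c("geneA\tgeneB", "A\tB", "B\tA", "B\tC"), f)
  ints <- read_interactions(f)
  expect_equal(ints$geneA, c("A", "B", "B"))
  expect_equal(ints$geneB, c("B", "A", "C"))  # both orientations retained

  fr <- withr::local_tempfile()
  write_interactions(ints, fr)
  expect_equal(read_interactions(fr), ints)
})

test_that("rows with the wrong field count name the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("gene\tterm", "g1\tt1", "g2\tt1\textra"), f)
  expect_error(read_annotation(f), "line 3 .* has 3 fields")
})

test_that("max-mean probe collapsing keeps the brightest probe per gene", {
  m <- rbind(p1 = c(1, 1, 1), p2 = c(5, 5, 5), p3 = c(2, 2, 2))
  colnames(m) <- c("s1", "s2", "s3")
  ds <- expression_dataset(m)
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("GA", "GA", "GB"))
  out <- collapse_probes(ds, map)
  expect_equal(out$gene_ids, c("GA", "GB"))
  expect_equal(unname(out$values["GA", ]), c(5, 5, 5))
})
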