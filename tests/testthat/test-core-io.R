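test_that("expression matrix TSV round-trip preserves values and order", {
  m <- toy_matrix(30, 4, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(back, m, tolerance = 1e-12)

  # small literal file reads with identifiers in file order
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsB", "g1\t1.5\t2", "g2\t0\t-3.25", "g3\t4\t5"), p2)
  m2 <- read_expression_matrix(p2)
  expect_equal(dim(m2), c(3L, 2L))
  expect_identical(rownames(m2), c("g1", "g2", "g3"))
  expect_equal(m2["g2", "sB"], -3.25)
})

test_that("malformed matrices are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsA", "g1\t1\t2"), p)
  expect_error(read_expression_matrix(p), "duplicate sample.*sA")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA", "g1\t1", "g1\t2"), p2)
  expect_error(read_expression_matrix(p2), "duplicate gene.*g1")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsB", "g1\t1\t2", "g2\tNA\t3"), p3)
  expect_error(read_expression_matrix(p3), "non-numeric.*g2.*sA")
})

test_that("quantile normalization matches the sort-average oracle", {
  # hand example: columns (1,2) and (3,4) both become (2,3)
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2, 3))
  expect_equal(unname(qn[, "b"]), c(2, 3))

  # fixed point: identical columns are unchanged
  m2 <- matrix(rep(c(5, 1, 3), 3), 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(quantile_normalize(m2), m2)

  # property: every column shares one multiset of values, equal to oracle
  m3 <- toy_matrix(50, 6, seed = 7)
  qn3 <- quantile_normalize(m3)
  expect_equal(qn3, quantile_normalize_oracle(m3), tolerance = 1e-12)
  ref <- unname(sort(qn3[, 1L]))
  for (j in 2:6) {
    expect_equal(unname(sort(qn3[, j])), ref, tolerance = 1e-12)
  }

  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("probe collapse takes the per-sample median and checks the map", {
  m <- toy_matrix(6, 3, seed = 3)
  pm <- data.frame(probe_id = rownames(m),
                   gene_id = c("A", "A", "A", "B", "C", "C"),
                   stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(m, pm)
  expect_identical(rownames(out), c("A", "B", "C"))
  # brute-force per-sample medians
  for (j in 1:3) {
    expect_equal(out["A", j], median(m[1:3, j]))
    expect_equal(out["B", j], m[4, j])
    expect_equal(out["C", j], median(m[5:6, j]))
  }
  # one probe per gene: identity
  pm1 <- data.frame(probe_id = rownames(m), gene_id = rownames(m))
  expect_equal(collapse_probes_to_genes(m, pm1), m)
  # explicit median example
  m2 <- matrix(c(1, 2, 9), 3, 1, dimnames = list(c("p1", "p2", "p3"), "s1"))
  pm2 <- data.frame(probe_id = c("p1", "p2", "p3"), gene_id = "G")
  expect_equal(unname(collapse_probes_to_genes(m2, pm2)["G", 1]), 2)

  expect_error(collapse_probes_to_genes(m, pm[-1, ]), "unmapped probe")
})

test_that("covariate removal eliminates the fitted contribution exactly", {
  n <- 30
  rin <- seq(6, 10, length.out = n)
  meta <- flat_metadata(sprintf("s%03d", 1:n),
                        rep(c("brain", "extra_cerebral"), each = n / 2),
                        rin = rin)
  # noiseless linear gene: residualized to its mean
  m <- matrix(2 + 0.5 * rin, 1, n,
              dimnames = list("g1", meta$sample_id))
  out <- remove_covariate_effects(m, meta, "rin")
  expect_equal(unname(out[1, ]), rep(mean(m[1, ]), n), tolerance = 1e-10)

  # covariate uncorrelated with expression: output equals input
  set.seed(9)
  expr <- rnorm(n)
  expr_orth <- expr - cov(expr, rin) / var(rin) * (rin - mean(rin))
  m2 <- matrix(expr_orth, 1, n, dimnames = list("g1", meta$sample_id))
  expect_equal(remove_covariate_effects(m2, meta, "rin"), m2,
               tolerance = 1e-10)

  # planted slope, noisy: residual correlation with RIN vanishes
  cors <- vapply(1:100, function(i) {
    set.seed(i)
    g <- 2 + 0.5 * rin + rnorm(n, sd = 0.1)
    mm <- matrix(g, 1, n, dimnames = list("g1", meta$sample_id))
    out <- remove_covariate_effects(mm, meta, "rin")
    cor(out[1, ], rin)
  }, numeric(1L))
  expect_true(all(abs(cors) < 0.05))

  # idempotence
  m3 <- toy_matrix(20, n, seed = 5)
  colnames(m3) <- meta$sample_id
  once <- remove_covariate_effects(m3, meta, "rin")
  twice <- remove_covariate_effects(once, meta, "rin")
  expect_equal(twice, once, tolerance = 1e-10)

  # constant covariate skipped with warning
  expect_warning(out4 <- remove_covariate_effects(m3, meta, "center"),
                 "constant.*skipped")
  expect_equal(out4, m3)
})

test_that("aliased categorical covariates are detected and dropped", {
  n <- 12
  meta <- flat_metadata(sprintf("s%03d", 1:n),
                        rep(c("brain", "extra_cerebral"), each = 6),
                        rin = rnorm(n, 8.8, 0.5))
  meta$cancer_type <- rep(c("breast", "melanoma"), each = 6)
  meta$center <- ifelse(meta$cancer_type == "breast", "center_A", "center_B")
  m <- toy_matrix(10, n, seed = 2)
  colnames(m) <- meta$sample_id
  expect_warning(
    out <- remove_covariate_effects(m, meta, c("cancer_type", "center")),
    "aliased")
  expect_equal(dim(out), dim(m))
})
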