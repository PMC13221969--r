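test_that("Kruskal-Wallis filter reproduces the rank-statistic by hand", {
  m <- matrix(1:6, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  types <- rep(c("breast", "melanoma", "lymphoma"), each = 2)
  res <- kruskal_wallis_filter(m, types, alpha = 0.05)
  # groups {1,2},{3,4},{5,6}: H = 12/(6*7) * 2*((1.5-3.5)^2 + 0 + (5.5-3.5)^2)
  expect_equal(res$kw_H, 32 / 7, tolerance = 1e-10)
  expect_equal(res$kw_p, pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-10)

  # constant gene: H = 0, retained
  m2 <- rbind(m, g2 = rep(4, 6))
  res2 <- kruskal_wallis_filter(m2, types)
  expect_equal(res2$kw_H[2], 0)
  expect_true(res2$retained[2])
  # Bonferroni adjustment across the tested genes
  expect_equal(res2$kw_p_adj, pmin(1, res2$kw_p * 2))

  expect_error(kruskal_wallis_filter(m, rep("breast", 6)), ">= 2")
})

test_that("strong cross-type differences are removed, shared effects retained", {
  n <- c(13, 11, 5)
  types <- rep(c("breast", "melanoma", "lymphoma"), n)
  removed <- vapply(1:100, function(i) {
    set.seed(i)
    x <- rnorm(sum(n), mean = rep(c(0, 0, 8), n), sd = 0.1)
    m <- matrix(x, 1, dimnames = list("g1", sprintf("s%02d", seq_along(x))))
    !kruskal_wallis_filter(m, types, alpha = 0.05)$retained
  }, logical(1L))
  expect_gte(mean(removed), 0.95)

  # a gene identical across types survives the filter
  set.seed(1)
  x <- rnorm(sum(n), mean = 5, sd = 0.5)
  m <- matrix(x, 1, dimnames = list("g1", sprintf("s%02d", seq_along(x))))
  expect_true(kruskal_wallis_filter(m, types)$retained)
})

test_that("per-type SAM is restricted, deterministic, and calibrated on null labels", {
  cfg <- cohort_config(n_genes = 150, n_signature = 5, n_type_specific = 0,
                       signature_log2fc_range = c(3, 6), seed = 21)
  co <- generate_cohort(cfg)
  res <- per_type_sam(co$matrix, co$metadata, "breast", n_perm = 150, seed = 2)
  res_b <- per_type_sam(co$matrix, co$metadata, "breast", n_perm = 150, seed = 2)
  expect_identical(res, res_b)

  planted <- co$truth$signature_up_gene_ids
  expect_lt(median(res$q_value[res$gene_id %in% planted]),
            median(res$q_value[!res$gene_id %in% planted]))

  # null labels: few genes at q <= 0.05
  fp_rate <- vapply(1:20, function(i) {
    cfg0 <- cohort_config(n_genes = 150, n_signature = 0,
                          n_down_signature = 0, n_type_specific = 0,
                          seed = 300 + i)
    co0 <- generate_cohort(cfg0)
    r <- per_type_sam(co0$matrix, co0$metadata, "melanoma",
                      n_perm = 150, seed = i)
    mean(r$q_value <= 0.05)
  }, numeric(1L))
  expect_lte(mean(fp_rate), 0.05)

  meta_bad <- co$metadata
  meta_bad$cancer_type[meta_bad$cancer_type == "lymphoma" &
                         meta_bad$location == "brain"][-1] <- "breast"
  expect_error(per_type_sam(co$matrix, meta_bad, "lymphoma", n_perm = 150),
               "lymphoma")
})

test_that("consensus signature intersects directions and takes the median score", {
  mk <- function(genes, d, q, fc) {
    data.frame(gene_id = genes, d_score = d, log2fc = fc, q_value = q,
               s_gene = 1, stringsAsFactors = FALSE)
  }
  genes <- c("NKX6-2", "KLK6", "other")
  results <- list(
    breast = mk(genes, d = c(8.6, 4.2, 0.1), q = c(0.01, 0.01, 0.9),
                fc = c(5.2, 3.7, 0.01)),
    melanoma = mk(genes, d = c(10.9, 6.3, -0.2), q = c(0.01, 0.01, 0.8),
                  fc = c(5.6, 3.8, -0.05)),
    lymphoma = mk(genes, d = c(5.0, 3.8, 0.3), q = c(0.01, 0.01, 0.7),
                  fc = c(6.5, 3.9, 0.02)))
  sig <- consensus_signature(results, q_threshold = 0.05)
  expect_equal(sig$gene_id, c("NKX6-2", "KLK6"))
  expect_equal(sig$median_sam_score, c(8.6, 4.2))
  expect_equal(sig$rank, 1:2)
  expect_equal(sig$direction, c("up", "up"))
  expect_equal(sig$log2fc_breast, c(5.2, 3.7))

  # three disjoint significant sets: empty signature
  res_disjoint <- list(
    breast = mk(genes, d = c(5, 0, 0), q = c(0.01, 0.9, 0.9), fc = c(2, 0, 0)),
    melanoma = mk(genes, d = c(0, 5, 0), q = c(0.9, 0.01, 0.9), fc = c(0, 2, 0)),
    lymphoma = mk(genes, d = c(0, 0, 5), q = c(0.9, 0.9, 0.01), fc = c(0, 0, 2)))
  expect_equal(nrow(consensus_signature(res_disjoint)), 0L)

  # shared down-regulation is reported unranked
  res_down <- lapply(results, function(r) {
    r$log2fc <- -r$log2fc; r$d_score <- -r$d_score; r
  })
  sig_down <- consensus_signature(res_down)
  expect_equal(sig_down$direction, c("down", "down"))
  expect_true(all(is.na(sig_down$rank)))

  # tie compatibility mode assigns shared min-ranks
  res_tie <- results
  for (ct in names(res_tie)) res_tie[[ct]]$d_score <- c(5, 5, 0.1)
  sig_tie <- consensus_signature(res_tie, ties = "min")
  expect_equal(sig_tie$rank, c(1L, 1L))
  sig_lex <- consensus_signature(res_tie, ties = "lexicographic")
  expect_equal(sig_lex$gene_id, c("KLK6", "NKX6-2"))  # tie broken by id
  expect_equal(sig_lex$rank, 1:2)

  # mismatched universes are an error listing the difference
  res_bad <- results
  res_bad$lymphoma <- mk(c("NKX6-2", "KLK6", "extra"), c(5, 3.8, 0.3),
                         c(0.01, 0.01, 0.7), c(6.5, 3.9, 0.02))
  expect_error(consensus_signature(res_bad), "universes differ")
})

test_that("gaussian confirmation reduces to the mean difference without covariates", {
  n <- 16
  meta <- flat_metadata(sprintf("s%02d", 1:n),
                        rep(c("brain", "extra_cerebral"), each = n / 2))
  m <- toy_matrix(20, n, seed = 13)
  colnames(m) <- meta$sample_id
  res <- suppressWarnings(glm_confirm(m, meta, "gaussian"))
  diffs <- rowMeans(m[, 1:8]) - rowMeans(m[, 9:16])
  expect_equal(res$coefficient, unname(diffs), tolerance = 1e-10)
  expect_true(all(res$converged))
  expect_equal(res$fdr_q, fdr_adjust(res$wald_p))
})

test_that("null gaussian fits cover zero at the nominal rate", {
  n <- 30
  meta <- flat_metadata(sprintf("s%02d", 1:n),
                        rep(c("brain", "extra_cerebral"), each = n / 2),
                        cancer_type = rep(c("breast", "melanoma"), n / 2),
                        rin = rnorm(n, 8.8, 0.5))
  m <- toy_matrix(200, n, seed = 77)
  colnames(m) <- meta$sample_id
  res <- suppressWarnings(glm_confirm(m, meta, "gaussian"))
  covered <- mean(res$wald_p > 0.05)
  expect_gt(covered, 0.90)
  expect_lt(covered, 0.99)
})

test_that("binomial confirmation matches a likelihood-grid oracle", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  eta <- 0.4 + 1.2 * x
  y <- rbinom(n, 1, plogis(eta))
  meta <- flat_metadata(sprintf("s%02d", 1:n),
                        ifelse(y == 1, "brain", "extra_cerebral"))
  m <- matrix(x, 1, n, dimnames = list("g1", meta$sample_id))
  res <- suppressWarnings(glm_confirm(m, meta, "binomial"))
  expect_true(res$converged)
  oracle <- logistic_grid_oracle(x, y)
  expect_equal(res$coefficient, unname(oracle["b1"]), tolerance = 1e-4)

  # perfectly separated expression: flagged, coefficient unreported
  m2 <- matrix(ifelse(y == 1, 5, -5) + rnorm(n, sd = 0.01), 1, n,
               dimnames = list("g1", meta$sample_id))
  res2 <- suppressWarnings(glm_confirm(m2, meta, "binomial"))
  expect_false(res2$converged)
  expect_true(is.na(res2$coefficient))
  expect_true(is.na(res2$fdr_q))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("PCA projections expose planted structure", {
  # rank-1 data: a single direction of variance
  v <- rnorm(20); w <- seq(-1, 1, length.out = 6)
  m <- outer(v, w) + 5
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:6))
  pc <- pca_projection(m)
  expect_equal(pc$variance_explained[1], 1.0, tolerance = 1e-10)
  expect_lte(sum(pc$variance_explained), 1 + 1e-10)

  # signature genes separate brain from extra-cerebral samples
  sil_loc <- vapply(1:5, function(i) {
    cfg <- cohort_config(n_genes = 400, n_type_specific = 50,
                         signature_log2fc_range = c(2, 6.5), seed = 40 + i)
    co <- generate_cohort(cfg)
    pc <- pca_projection(co$matrix,
                         gene_subset = co$truth$signature_up_gene_ids)
    mean_silhouette(pc$scores[, 1, drop = FALSE], co$metadata$location)
  }, numeric(1L))
  expect_true(all(sil_loc > 0.5))

  # the full gene set clusters by tumor of origin, not location
  cfg <- cohort_config(n_genes = 1000, n_type_specific = 300, seed = 50)
  co <- generate_cohort(cfg)
  pc <- pca_projection(co$matrix)
  sil_type <- mean_silhouette(pc$scores[, 1:2], co$metadata$cancer_type)
  sil_site <- mean_silhouette(pc$scores[, 1:2], co$metadata$location)
  expect_gt(sil_type, sil_site)

  expect_error(pca_projection(m[, 1, drop = FALSE]), "2 distinct samples")
  expect_error(pca_projection(m, gene_subset = "nope"), "unknown gene")
})
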