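#' Configuration for a synthetic metastasis cohort
#'
#' Defaults mirror the three-cancer study design: 133 samples split into
#' breast 13/18/27, melanoma 11/18/33 and lymphoma 5/0/8 across groups 1-3
#' (group 1 = brain metastasis biopsy; groups 2 and 3 = extra-cerebral), a
#' planted set of 23 genes up-regulated in brain metastases of all three
#' cancer types with log2 fold changes in `[1.2, 6.5]`, 3 shared
#' down-regulated genes, a block of cancer-type-specific genes that the
#' cross-type filter should discard, and additive RIN and center nuisance
#' effects on top of i.i.d. Gaussian noise on the log2 scale.
#'
#' @param n_genes Number of genes.
#' @param group_sizes 3x3 integer matrix, rows = cancer types (breast,
#'   melanoma, lymphoma), columns = groups 1-3.
#' @param n_signature Number of planted shared brain-up genes.
#' @param signature_log2fc_range Range the planted log2 fold changes are
#'   drawn from (uniform); lower bound must be positive.
#' @param n_down_signature Number of planted shared brain-down genes.
#' @param n_type_specific Number of genes with a cancer-type (not location)
#'   effect, present in both locations of exactly one type.
#' @param type_log2fc Magnitude of the cancer-type effect.
#' @param noise_sd Gene-wise residual standard deviation (log2 units).
#' @param heteroscedastic If `TRUE`, gene-wise variances are drawn from a
#'   scaled inverse-gamma so some genes are noisier than others.
#' @param rin_slope_sd Standard deviation of the per-gene RIN slope.
#' @param center_effect_sd Standard deviation of per-gene center offsets.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 16000L,
                          group_sizes = default_group_sizes(),
                          n_signature = 23L,
                          signature_log2fc_range = c(1.2, 6.5),
                          n_down_signature = 3L,
                          n_type_specific = 1000L,
                          type_log2fc = 4,
                          noise_sd = 1,
                          heteroscedastic = FALSE,
                          rin_slope_sd = 0.1,
                          center_effect_sd = 0.5,
                          seed = 1L) {
  group_sizes <- as.matrix(group_sizes)
  stopifnot(nrow(group_sizes) == 3L, ncol(group_sizes) == 3L,
            all(group_sizes >= 0L))
  dimnames(group_sizes) <- list(CANCER_TYPES, paste0("group", 1:3))
  if (n_signature < 0L || n_down_signature < 0L || n_type_specific < 0L) {
    stop("gene class counts must be >= 0")
  }
  if (n_signature + n_down_signature + n_type_specific > n_genes) {
    stop("planted gene classes exceed n_genes")
  }
  if (signature_log2fc_range[1L] <= 0) {
    stop("signature_log2fc_range lower bound must be > 0")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    group_sizes = group_sizes,
    n_signature = as.integer(n_signature),
    signature_log2fc_range = as.numeric(signature_log2fc_range),
    n_down_signature = as.integer(n_down_signature),
    n_type_specific = as.integer(n_type_specific),
    type_log2fc = type_log2fc,
    noise_sd = noise_sd,
    heteroscedastic = isTRUE(heteroscedastic),
    rin_slope_sd = rin_slope_sd,
    center_effect_sd = center_effect_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Study-design sample counts
#'
#' The per-(cancer type, group) biopsy counts of the 133-patient design:
#' group 1 brain metastases 13/11/5, extra-cerebral groups 2 and 3 filling
#' the remainder (lymphoma has no group-2 samples).
#' @return 3x3 integer matrix, rows breast/melanoma/lymphoma, columns groups.
#' @export
default_group_sizes <- function() {
  m <- rbind(breast = c(13L, 18L, 27L),
             melanoma = c(11L, 18L, 33L),
             lymphoma = c(5L, 0L, 8L))
  colnames(m) <- paste0("group", 1:3)
  m
}

#' Generate a synthetic cohort
#'
#' Draws a gene-by-sample log2 expression matrix, its sample sheet and the
#' ground truth of planted effects. Per-gene baselines are drawn once;
#' brain samples of all three cancer types receive `+log2FC` on planted
#' signature-up genes and `-log2FC` on signature-down genes; type-specific
#' genes receive an offset for exactly one cancer type in both locations;
#' RIN enters linearly with a per-gene slope and centers as per-gene
#' categorical offsets; residual noise is i.i.d. Gaussian.
#'
#' @param cfg A [cohort_config()].
#' @return List with elements `matrix` (expression matrix), `metadata`
#'   (sample sheet data.frame) and `truth` (list with planted gene ids,
#'   per-gene planted log2 fold changes, RIN slopes and center offsets).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_brain <- sum(cfg$group_sizes[, 1L])
  n_extra <- sum(cfg$group_sizes[, 2:3])
  if (n_brain < 2L || n_extra < 2L) {
    stop("each location needs >= 2 samples for any contrast")
  }
  set.seed(cfg$seed)

  ## sample sheet
  rows <- list()
  for (ct in CANCER_TYPES) {
    for (g in 1:3) {
      n <- cfg$group_sizes[ct, g]
      if (n > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          cancer_type = ct, group = g,
          location = if (g == 1L) "brain" else "extra_cerebral",
          stringsAsFactors = FALSE)[rep(1L, n), ]
      }
    }
  }
  meta <- do.call(rbind, rows)
  n_samples <- nrow(meta)
  meta$sample_id <- sprintf("S%03d", seq_len(n_samples))
  meta$center <- sample(c("center_A", "center_B"), n_samples,
                        replace = TRUE, prob = c(0.6, 0.4))
  meta$rin <- pmin(10, pmax(6, round(stats::rnorm(n_samples, 8.8, 0.8), 1)))
  meta <- meta[, c("sample_id", "cancer_type", "location", "group",
                   "center", "rin")]
  rownames(meta) <- NULL

  ## gene classes
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  n_planted <- cfg$n_signature + cfg$n_down_signature + cfg$n_type_specific
  planted_idx <- if (n_planted > 0L) sample.int(cfg$n_genes, n_planted) else integer()
  up_idx <- utils::head(planted_idx, cfg$n_signature)
  down_idx <- planted_idx[seq_len(cfg$n_down_signature) + cfg$n_signature]
  ts_idx <- utils::tail(planted_idx, cfg$n_type_specific)

  planted_fc <- numeric(cfg$n_genes)
  planted_fc[up_idx] <- stats::runif(length(up_idx),
                                     cfg$signature_log2fc_range[1L],
                                     cfg$signature_log2fc_range[2L])
  planted_fc[down_idx] <- -stats::runif(length(down_idx),
                                        cfg$signature_log2fc_range[1L],
                                        cfg$signature_log2fc_range[2L])
  ts_type <- character(0)
  if (length(ts_idx)) {
    ts_type <- sample(CANCER_TYPES, length(ts_idx), replace = TRUE)
  }

  ## assemble matrix
  baseline <- stats::rnorm(cfg$n_genes, 8, 2)
  rin_slope <- stats::rnorm(cfg$n_genes, 0, cfg$rin_slope_sd)
  center_offset <- stats::rnorm(cfg$n_genes, 0, cfg$center_effect_sd)
  x <- matrix(baseline, cfg$n_genes, n_samples)
  is_brain <- meta$location == "brain"
  x[up_idx, is_brain] <- x[up_idx, is_brain] + planted_fc[up_idx]
  x[down_idx, is_brain] <- x[down_idx, is_brain] + planted_fc[down_idx]
  for (ct in CANCER_TYPES) {
    sel_g <- ts_idx[ts_type == ct]
    sel_s <- meta$cancer_type == ct
    if (length(sel_g) && any(sel_s)) {
      x[sel_g, sel_s] <- x[sel_g, sel_s] + cfg$type_log2fc
    }
  }
  rin_c <- meta$rin - mean(meta$rin)
  x <- x + outer(rin_slope, rin_c)
  x <- x + outer(center_offset, as.numeric(meta$center == "center_B"))
  gene_sd <- rep(cfg$noise_sd, cfg$n_genes)
  if (cfg$heteroscedastic) {
    # scaled inverse-gamma variances, mean kept at noise_sd^2 (shape 3)
    gene_sd <- sqrt(cfg$noise_sd^2 * 2 / stats::rgamma(cfg$n_genes, shape = 3))
  }
  x <- x + matrix(stats::rnorm(cfg$n_genes * n_samples), cfg$n_genes) * gene_sd
  dimnames(x) <- list(gene_ids, meta$sample_id)

  truth <- list(
    signature_up_gene_ids = gene_ids[sort(up_idx)],
    signature_down_gene_ids = gene_ids[sort(down_idx)],
    type_specific_gene_ids = gene_ids[sort(ts_idx)],
    planted_log2fc = stats::setNames(planted_fc, gene_ids),
    rin_slope = stats::setNames(rin_slope, gene_ids),
    center_offset = stats::setNames(center_offset, gene_ids)
  )
  list(matrix = x, metadata = validate_sample_metadata(meta, x), truth = truth)
}

#' Generate synthetic external-study effect tables
#'
#' Emulates per-gene differential-expression effect tables extracted from
#' independent public datasets: each dataset reports, per gene, a log2 fold
#' change drawn as the true value plus Gaussian noise with the dataset's
#' standard error, the SE itself drawn uniformly from `se_range`. Genes can
#' be missing at random per dataset to emulate platform coverage.
#'
#' @param n_datasets Number of datasets (>= 1).
#' @param gene_ids Character vector of gene identifiers.
#' @param true_log2fc Per-gene true log2 fold change (recycled scalar ok).
#' @param se_range Length-2 interval SEs are drawn from.
#' @param missing_prob Per (gene, dataset) probability that the gene is
#'   absent from the dataset.
#' @param seed Integer seed.
#' @return data.frame with columns `dataset_id`, `gene_id`, `log2fc`, `se`
#'   (one row per present gene/dataset pair).
#' @export
generate_meta_datasets <- function(n_datasets, gene_ids, true_log2fc,
                                   se_range = c(0.2, 0.8),
                                   missing_prob = 0, seed = 1L) {
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  if (!length(gene_ids)) stop("gene_ids must be non-empty")
  true_log2fc <- rep_len(true_log2fc, length(gene_ids))
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(n_datasets)) {
    present <- stats::runif(length(gene_ids)) >= missing_prob
    se <- stats::runif(sum(present), se_range[1L], se_range[2L])
    out[[i]] <- data.frame(
      dataset_id = sprintf("study_%02d", i),
      gene_id = gene_ids[present],
      log2fc = true_log2fc[present] + stats::rnorm(sum(present), 0, se),
      se = se,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `matrix.tsv`, `samples.tsv` and `truth.tsv` (gene_id, class,
#' planted_log2fc) in the package's TSV formats.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, "matrix.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_expression_matrix(cohort$matrix, paths[["matrix"]])
  write_sample_sheet(cohort$metadata, paths[["samples"]])
  gene_ids <- rownames(cohort$matrix)
  cls <- rep("null", length(gene_ids))
  cls[gene_ids %in% cohort$truth$signature_up_gene_ids] <- "signature_up"
  cls[gene_ids %in% cohort$truth$signature_down_gene_ids] <- "signature_down"
  cls[gene_ids %in% cohort$truth$type_specific_gene_ids] <- "type_specific"
  truth <- data.frame(gene_id = gene_ids, class = cls,
                      planted_log2fc = unname(cohort$truth$planted_log2fc),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
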