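# Per-gene fixed-effects inverse-variance meta-analysis of log2 fold
# changes across independent datasets.

#' Read a study-effect table
#'
#' @param path TSV with columns `dataset_id`, `gene_id`, `log2fc`, `se`
#'   (one row per dataset/gene pair).
#' @return data.frame of study effects.
#' @export
read_study_effects <- function(path) {
  eff <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("dataset_id", "gene_id", "log2fc", "se")
  miss <- setdiff(needed, colnames(eff))
  if (length(miss)) {
    stop("study-effect table missing column(s): ", paste(miss, collapse = ", "))
  }
  eff
}

#' Fixed-effects inverse-variance pooling of log2 fold changes
#'
#' For each gene `g`, pools the per-dataset estimates with weights
#' `w_{g,i} = 1 / SE_{g,i}^2`:
#' \deqn{\widehat{FC}_{g,FE} = \frac{\sum_i w_{g,i} FC_{g,i}}{\sum_i w_{g,i}},
#'   \qquad SE_{g,FE} = \Big(\sum_i w_{g,i}\Big)^{-1/2}}
#' with a two-sided Wald Z-test (`Z = FC_FE / SE_FE`) and 95% confidence
#' interval `FC_FE +/- 1.96 * SE_FE`. Genes missing from a dataset simply
#' contribute nothing to that gene's pool (complete-case pooling).
#'
#' @param effects data.frame with columns `dataset_id`, `gene_id`,
#'   `log2fc`, `se` (`se > 0` and finite for every row).
#' @return data.frame with one row per gene: `gene_id`,
#'   `n_datasets_present`, `weight_sum`, `pooled_log2fc`, `pooled_se`, `z`,
#'   `p`, `ci_low`, `ci_high`.
#' @export
pool_fixed_effects <- function(effects) {
  needed <- c("dataset_id", "gene_id", "log2fc", "se")
  stopifnot(all(needed %in% colnames(effects)))
  bad <- which(!is.finite(effects$se) | effects$se <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite SE at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (dataset ", effects$dataset_id[bad[1L]],
         ", gene ", effects$gene_id[bad[1L]], ")")
  }
  if (any(!is.finite(effects$log2fc))) {
    stop("non-finite log2fc in study-effect table")
  }
  g <- factor(effects$gene_id, levels = unique(effects$gene_id))
  w <- 1 / effects$se^2
  weight_sum <- as.vector(rowsum(w, g))
  wfc_sum <- as.vector(rowsum(w * effects$log2fc, g))
  n_present <- as.vector(rowsum(rep(1L, length(w)), g))
  pooled <- wfc_sum / weight_sum
  pooled_se <- weight_sum^(-0.5)
  z <- pooled / pooled_se
  data.frame(gene_id = levels(g),
             n_datasets_present = as.integer(n_present),
             weight_sum = weight_sum,
             pooled_log2fc = pooled,
             pooled_se = pooled_se,
             z = z,
             p = 2 * stats::pnorm(-abs(z)),
             ci_low = pooled - 1.96 * pooled_se,
             ci_high = pooled + 1.96 * pooled_se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature concordance across external datasets
#'
#' Summarizes how a consensus signature behaves in the pooled external
#' evidence: which signature genes were present in every dataset, and how
#' many of those are pooled in the same (positive) direction.
#'
#' @param pooled Result of [pool_fixed_effects()].
#' @param signature_genes Character vector of signature gene ids (the
#'   up-regulated consensus set); must be non-empty.
#' @param n_datasets Total number of datasets pooled over.
#' @return List with `n_signature`, `present_in_all` (gene ids),
#'   `n_present_in_all`, `n_concordant` (present in all and pooled
#'   `log2fc > 0`), `agreement_fraction`, `absent_genes` and
#'   `discordant_genes`.
#' @export
concordance_report <- function(pooled, signature_genes, n_datasets) {
  if (!length(signature_genes)) stop("signature must be non-empty")
  idx <- match(signature_genes, pooled$gene_id)
  present_all <- !is.na(idx) & pooled$n_datasets_present[idx] == n_datasets
  present_genes <- signature_genes[present_all]
  pfc <- pooled$pooled_log2fc[idx[present_all]]
  concordant <- present_genes[pfc > 0]
  list(
    n_signature = length(signature_genes),
    present_in_all = present_genes,
    n_present_in_all = length(present_genes),
    n_concordant = length(concordant),
    agreement_fraction =
      if (length(present_genes)) length(concordant) / length(present_genes)
      else 0,
    absent_genes = signature_genes[!present_all],
    discordant_genes = setdiff(present_genes, concordant)
  )
}
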