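# End-to-end orchestration of the discovery workflow with a fixed artifact
# layout and a run manifest. The exported functions are the interface; no
# shell wrapper is needed to drive them.

#' Pipeline run configuration
#'
#' @param matrix_path,sample_sheet_path Paths to the expression matrix and
#'   sample sheet TSVs (required unless in-memory objects are passed to
#'   [run_pipeline()]).
#' @param probe_map_path Optional probe-to-gene map TSV; when given, probes
#'   are collapsed to genes after quantile normalization.
#' @param effect_table_path Optional external study-effect TSV for the
#'   meta-analysis stage.
#' @param alpha_kw Kruskal-Wallis removal level (default 0.05).
#' @param kw_adjust `"bonferroni"` or `"none"` (raw-p filter mode).
#' @param q_threshold Per-type SAM q-value cutoff (default 0.05).
#' @param n_perm Permutations per cancer type (default 1000, minimum 100).
#' @param seed Master seed; per-type permutation seeds are derived from it.
#' @param covariates Nuisance covariates removed before analysis (default
#'   RIN).
#' @param rank_ties Tie handling in the signature ranking
#'   (`"lexicographic"` or `"min"`).
#' @param run_glm Fit the confirmation GLMs (default `TRUE`).
#' @param out_dir Output directory for artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix_path = NULL, sample_sheet_path = NULL,
                       probe_map_path = NULL, effect_table_path = NULL,
                       alpha_kw = 0.05, kw_adjust = "bonferroni",
                       q_threshold = 0.05, n_perm = 1000L, seed = 1L,
                       covariates = "rin",
                       rank_ties = "lexicographic",
                       run_glm = TRUE, out_dir = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (alpha_kw <= 0 || alpha_kw >= 1 || q_threshold <= 0 || q_threshold >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  structure(list(matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 probe_map_path = probe_map_path,
                 effect_table_path = effect_table_path,
                 alpha_kw = alpha_kw, kw_adjust = kw_adjust,
                 q_threshold = q_threshold, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), covariates = covariates,
                 rank_ties = rank_ties, run_glm = isTRUE(run_glm),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full discovery pipeline
#'
#' Executes, in order: quantile normalization, optional probe-to-gene
#' collapse, nuisance-covariate removal, the cross-type Kruskal-Wallis
#' filter on brain samples, per-cancer-type SAM on the retained genes,
#' consensus intersection, optional GLM confirmation (both models) and,
#' when an external effect table is supplied, fixed-effects meta-analysis
#' with a concordance report. All result tables and a manifest recording
#' every random decision are written to `cfg$out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @param m,meta Optional in-memory expression matrix and sample sheet,
#'   overriding the configured paths.
#' @return Invisibly, a list with elements `normalized`, `filter`, `sam`
#'   (per-type list), `signature`, `glm_binomial`, `glm_gaussian`,
#'   `pooled`, `concordance` and `manifest`.
#' @export
run_pipeline <- function(cfg, m = NULL, meta = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(m)) {
    if (is.null(cfg$matrix_path) || !file.exists(cfg$matrix_path)) {
      stop("expression matrix path missing or not found: ",
           if (is.null(cfg$matrix_path)) "<unset>" else cfg$matrix_path)
    }
    m <- read_expression_matrix(cfg$matrix_path)
  }
  if (is.null(meta)) {
    if (is.null(cfg$sample_sheet_path) || !file.exists(cfg$sample_sheet_path)) {
      stop("sample sheet path missing or not found")
    }
    meta <- read_sample_sheet(cfg$sample_sheet_path)
  }
  meta <- validate_sample_metadata(meta, m)

  norm <- quantile_normalize(m)
  if (!is.null(cfg$probe_map_path)) {
    pm <- read_probe_map(cfg$probe_map_path)
    norm <- collapse_probes_to_genes(norm, pm)
  }
  warn_log <- character(0)
  norm <- withCallingHandlers(
    remove_covariate_effects(norm, meta, cfg$covariates),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  brain <- meta$location == "brain"
  m_brain <- norm[, meta$sample_id[brain], drop = FALSE]
  filt <- kruskal_wallis_filter(m_brain, meta$cancer_type[brain],
                                alpha = cfg$alpha_kw, adjust = cfg$kw_adjust)
  retained <- filt$gene_id[filt$retained]
  m_ret <- norm[retained, , drop = FALSE]

  sam <- list()
  s0_used <- numeric(0)
  for (i in seq_along(CANCER_TYPES)) {
    ct <- CANCER_TYPES[i]
    sam[[ct]] <- per_type_sam(m_ret, meta, ct, n_perm = cfg$n_perm,
                              seed = cfg$seed + i)
    s0_used[ct] <- attr(sam[[ct]], "s0")
  }
  signature <- consensus_signature(sam, q_threshold = cfg$q_threshold,
                                   ties = cfg$rank_ties)

  glm_b <- glm_g <- NULL
  if (cfg$run_glm) {
    glm_b <- withCallingHandlers(
      glm_confirm(norm, meta, "binomial"),
      warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    glm_g <- withCallingHandlers(
      glm_confirm(norm, meta, "gaussian"),
      warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  pooled <- conc <- NULL
  if (!is.null(cfg$effect_table_path)) {
    eff <- read_study_effects(cfg$effect_table_path)
    pooled <- pool_fixed_effects(eff)
    up_genes <- signature$gene_id[signature$direction == "up"]
    if (length(up_genes)) {
      conc <- concordance_report(pooled, up_genes,
                                 length(unique(eff$dataset_id)))
    }
  }

  cfg_rec <- cfg[setdiff(names(cfg), "out_dir")]   # analysis parameters only
  cfg_json <- jsonlite::toJSON(cfg_rec[!vapply(cfg_rec, is.null, logical(1L))],
                               auto_unbox = TRUE)
  manifest <- list(
    seed = cfg$seed,
    n_perm = cfg$n_perm,
    per_type_seed = stats::setNames(cfg$seed + seq_along(CANCER_TYPES),
                                    CANCER_TYPES),
    s0 = as.list(s0_used),
    alpha_kw = cfg$alpha_kw,
    kw_adjust = cfg$kw_adjust,
    q_threshold = cfg$q_threshold,
    n_genes_input = nrow(m),
    n_genes_retained = length(retained),
    n_signature_up = sum(signature$direction == "up"),
    n_signature_down = sum(signature$direction == "down"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("brainmetsig")),
    config = unclass(jsonlite::fromJSON(cfg_json)),
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                        seq_along(utf8ToInt(cfg_json))) %%
                            .Machine$integer.max),
    warnings = warn_log
  )

  res <- list(normalized = norm, filter = filt, sam = sam,
              signature = signature, glm_binomial = glm_b,
              glm_gaussian = glm_g, pooled = pooled, concordance = conc,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_pipeline_artifacts(res, cfg$out_dir)
  }
  invisible(res)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(res$normalized,
                          file.path(out_dir, "normalized_matrix.tsv"))
  write_tsv(res$filter, file.path(out_dir, "filter_results.tsv"))
  for (ct in names(res$sam)) {
    write_sam_results(res$sam[[ct]],
                      file.path(out_dir, paste0("sam_", ct, ".tsv")))
  }
  write_tsv(res$signature, file.path(out_dir, "signature.tsv"))
  if (!is.null(res$glm_binomial)) {
    write_tsv(res$glm_binomial, file.path(out_dir, "glm_binomial.tsv"))
  }
  if (!is.null(res$glm_gaussian)) {
    write_tsv(res$glm_gaussian, file.path(out_dir, "glm_gaussian.tsv"))
  }
  if (!is.null(res$pooled)) {
    write_tsv(res$pooled, file.path(out_dir, "pooled_effects.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a cohort and write its fixture files
#'
#' Convenience wrapper: [generate_cohort()] followed by [write_cohort()].
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Output directory.
#' @return Named paths of the written files, invisibly.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  write_cohort(generate_cohort(cfg), out_dir)
}
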