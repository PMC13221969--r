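# Two-step consensus signature selection: cross-type Kruskal-Wallis filter
# on brain samples, per-type SAM, intersection across cancer types, GLM
# confirmation with FDR, PCA separation check.

#' Cross-cancer-type Kruskal-Wallis filter
#'
#' Tests, among brain-metastasis samples only, whether each gene's
#' expression differs across the three cancer types (Kruskal-Wallis rank
#' test with tie correction, chi-squared reference with 2 df). Genes that
#' differ significantly after Bonferroni correction are removed; the
#' retained "common" genes are comparable across cancer types.
#'
#' @param m_brain Expression matrix restricted to brain (group 1) samples.
#' @param type_labels Cancer type per column of `m_brain`; all three types
#'   must be represented.
#' @param alpha Significance level for removal (default 0.05).
#' @param adjust `"bonferroni"` (default) adjusts p-values across genes
#'   before applying `alpha`; `"none"` applies `alpha` to raw p-values.
#' @return data.frame with columns `gene_id`, `kw_H`, `kw_p`, `kw_p_adj`,
#'   `retained` (`TRUE` when the gene is NOT significantly type-different).
#' @export
kruskal_wallis_filter <- function(m_brain, type_labels, alpha = 0.05,
                                  adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  m_brain <- validate_expression_matrix(m_brain)
  g <- factor(type_labels)
  if (length(g) != ncol(m_brain)) {
    stop("type_labels length must match sample count")
  }
  missing_types <- setdiff(CANCER_TYPES, levels(g))
  if (length(missing_types) && all(CANCER_TYPES %in% c(levels(g), missing_types))) {
    if (length(missing_types) == 3L) stop("no recognized cancer types")
  }
  if (nlevels(g) < 2L) stop("need >= 2 cancer types among brain samples")
  if (any(table(g) == 0L)) stop("a cancer type has zero brain samples")

  kw <- apply(m_brain, 1L, function(x) {
    if (length(unique(x)) == 1L) {
      return(c(H = 0, p = 1))
    }
    k <- stats::kruskal.test(x, g)
    c(H = unname(k$statistic), p = k$p.value)
  })
  kw_H <- kw["H", ]
  kw_p <- kw["p", ]
  n_tested <- nrow(m_brain)
  kw_p_adj <- pmin(1, kw_p * n_tested)
  crit <- if (adjust == "bonferroni") kw_p_adj else kw_p
  data.frame(gene_id = rownames(m_brain),
             kw_H = kw_H, kw_p = kw_p, kw_p_adj = kw_p_adj,
             retained = crit >= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cancer-type SAM contrast
#'
#' Restricts the matrix to one cancer type's samples and runs
#' [sam_permutation_q()] for the brain vs extra-cerebral contrast (groups 2
#' and 3 pooled as extra-cerebral).
#'
#' @param m Expression matrix (typically already restricted to
#'   filter-retained genes).
#' @param meta Sample metadata covering the matrix samples.
#' @param cancer_type One of `"breast"`, `"melanoma"`, `"lymphoma"`.
#' @param n_perm,seed,s0 Passed to [sam_permutation_q()].
#' @return A SAM result table (see [sam_permutation_q()]).
#' @export
per_type_sam <- function(m, meta, cancer_type, n_perm = 1000L, seed = 1L,
                         s0 = NULL) {
  stopifnot(cancer_type %in% CANCER_TYPES)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("sample sheet does not cover all matrix samples")
  }
  sel <- meta$cancer_type == cancer_type
  labels <- meta$location[sel] == "brain"
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("cancer type '", cancer_type, "' needs >= 2 brain and >= 2 ",
         "extra-cerebral samples (got ", sum(labels), " and ", sum(!labels), ")")
  }
  sam_permutation_q(m[, sel, drop = FALSE], labels, n_perm = n_perm,
                    seed = seed, s0 = s0)
}

#' Consensus signature across cancer types
#'
#' Intersects per-type SAM results: the up-regulated signature is the set of
#' genes with `q <= q_threshold` and positive log2 fold change in every
#' cancer type; the down-regulated set is the analogue with negative fold
#' changes. Each signature gene's `median_sam_score` is the median of its
#' per-type d-scores; the up set is ranked by descending median score.
#'
#' @param results Named list of per-type SAM result tables sharing one gene
#'   universe (names are the cancer types).
#' @param q_threshold Per-type q-value cutoff (default 0.05).
#' @param ties `"lexicographic"` (default) breaks equal median scores by
#'   gene id into distinct ranks; `"min"` assigns tied genes the minimum
#'   (shared) rank.
#' @return data.frame with columns `gene_id`, `direction`, `rank` (NA for
#'   the down set, which is reported unranked), `median_sam_score`, and
#'   per-type `log2fc_<type>` / `sam_score_<type>` columns.
#' @export
consensus_signature <- function(results, q_threshold = 0.05,
                                ties = c("lexicographic", "min")) {
  ties <- match.arg(ties)
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list (names = cancer types)")
  }
  universe <- results[[1L]]$gene_id
  for (nm in names(results)[-1L]) {
    extra <- setdiff(results[[nm]]$gene_id, universe)
    miss <- setdiff(universe, results[[nm]]$gene_id)
    if (length(extra) || length(miss)) {
      stop("gene universes differ for '", nm, "': ",
           length(extra), " extra, ", length(miss), " missing (e.g. ",
           paste(utils::head(c(extra, miss), 3L), collapse = ", "), ")")
    }
  }
  aligned <- lapply(results, function(r) r[match(universe, r$gene_id), ])
  qmat <- sapply(aligned, `[[`, "q_value")
  fcmat <- sapply(aligned, `[[`, "log2fc")
  dmat <- sapply(aligned, `[[`, "d_score")
  sig <- qmat <= q_threshold
  up <- rowSums(sig & fcmat > 0) == length(results)
  down <- rowSums(sig & fcmat < 0) == length(results)

  build <- function(keep, direction) {
    if (!any(keep)) {
      return(NULL)
    }
    med <- apply(dmat[keep, , drop = FALSE], 1L, stats::median)
    df <- data.frame(gene_id = universe[keep],
                     direction = direction,
                     rank = NA_integer_,
                     median_sam_score = med,
                     stringsAsFactors = FALSE)
    for (nm in names(results)) {
      df[[paste0("log2fc_", nm)]] <- fcmat[keep, nm]
      df[[paste0("sam_score_", nm)]] <- dmat[keep, nm]
    }
    df
  }
  up_df <- build(up, "up")
  if (!is.null(up_df)) {
    ord <- order(-up_df$median_sam_score, up_df$gene_id)
    up_df <- up_df[ord, , drop = FALSE]
    if (ties == "min") {
      up_df$rank <- as.integer(rank(-up_df$median_sam_score,
                                    ties.method = "min"))
    } else {
      up_df$rank <- seq_len(nrow(up_df))
    }
  }
  down_df <- build(down, "down")
  if (!is.null(down_df)) {
    down_df <- down_df[order(down_df$gene_id), , drop = FALSE]
  }
  out <- rbind(up_df, down_df)
  if (is.null(out)) {
    out <- build(rep(TRUE, 0), character(0))
    out <- data.frame(gene_id = character(0), direction = character(0),
                      rank = integer(0), median_sam_score = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Gene-wise GLM confirmation
#'
#' Fits, per gene, one of the two multivariable confirmation models:
#' * `binomial` — logistic regression of metastasis location (brain = 1) on
#'   the gene's expression, adjusted for cancer type and center; the
#'   coefficient is the log-odds of brain location per log2-expression unit.
#' * `gaussian` — linear regression of the gene's expression on location,
#'   adjusted for cancer type and center; the coefficient is the adjusted
#'   brain minus extra-cerebral log2-expression difference.
#'
#' Wald p-values (coefficient / SE) are adjusted across genes by
#' Benjamini-Hochberg; non-converged or separated binomial fits are flagged
#' and excluded from the adjustment.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata covering the matrix samples.
#' @param model `"binomial"` or `"gaussian"`.
#' @param covariates Adjustment covariates (default cancer type and center);
#'   columns aliased with earlier ones are dropped with a warning.
#' @return data.frame with columns `gene_id`, `model`, `coefficient`, `se`,
#'   `wald_p`, `fdr_q`, `converged`.
#' @export
glm_confirm <- function(m, meta, model = c("binomial", "gaussian"),
                        covariates = c("cancer_type", "center")) {
  model <- match.arg(model)
  m <- validate_expression_matrix(m)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  y_loc <- as.numeric(meta$location == "brain")
  Z <- build_covariate_design(meta, covariates)
  n <- ncol(m)

  if (model == "gaussian") {
    X <- cbind(`(Intercept)` = 1, location = y_loc, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      keep <- sort(qx$pivot[seq_len(qx$rank)])
      if (!2L %in% keep) stop("location is aliased with covariates")
      warning("dropping aliased design column(s): ",
              paste(colnames(X)[-keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
      qx <- qr(X)
    }
    p <- ncol(X)
    loc_col <- which(colnames(X) == "location")
    XtXinv <- chol2inv(qr.R(qx))
    B <- t(qr.coef(qx, t(m)))            # genes x p
    resid <- m - B %*% t(X)
    sigma2 <- rowSums(resid * resid) / (n - p)
    coef <- B[, loc_col]
    se <- sqrt(sigma2 * XtXinv[loc_col, loc_col])
    tval <- coef / se
    wald_p <- 2 * stats::pt(-abs(tval), df = n - p)
    converged <- rep(TRUE, nrow(m))
  } else {
    Xbase <- cbind(`(Intercept)` = rep(1, n), expr = 0, Z)
    p <- ncol(Xbase)
    coef <- se <- wald_p <- rep(NA_real_, nrow(m))
    converged <- rep(FALSE, nrow(m))
    fam <- stats::binomial()
    for (i in seq_len(nrow(m))) {
      X <- Xbase
      X[, "expr"] <- m[i, ]
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(X, y_loc, family = fam)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged || fit$boundary) next
      # (quasi-)separation: fitted probabilities numerically pinned at 0/1
      if (max(abs(fit$linear.predictors)) > 15) next
      Rp <- qr.R(fit$qr)
      covu <- tryCatch(chol2inv(Rp), error = function(e) NULL)
      if (is.null(covu)) next
      j <- which(colnames(X) == "expr")
      # glm.fit's qr is on sqrt(W) X with possible pivoting
      piv <- fit$qr$pivot
      jj <- which(piv == j)
      coef[i] <- fit$coefficients[j]
      se[i] <- sqrt(covu[jj, jj])
      wald_p[i] <- 2 * stats::pnorm(-abs(coef[i] / se[i]))
      converged[i] <- TRUE
    }
  }
  fdr_q <- rep(NA_real_, nrow(m))
  fdr_q[converged] <- fdr_adjust(wald_p[converged])
  data.frame(gene_id = rownames(m), model = model,
             coefficient = coef, se = se, wald_p = wald_p,
             fdr_q = fdr_q, converged = converged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) via
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' PCA projection of samples
#'
#' Gene-centered principal component analysis of the samples, optionally on
#' a gene subset (e.g. the consensus signature), used to check whether
#' samples separate by metastasis location or cluster by tumor of origin.
#'
#' @param m Expression matrix.
#' @param gene_subset Optional character vector of gene ids to restrict to.
#' @param n_comp Number of components to return (default up to 10).
#' @return List with `scores` (samples x components) and
#'   `variance_explained` (fractions, descending, summing to <= 1).
#' @export
pca_projection <- function(m, gene_subset = NULL, n_comp = 10L) {
  m <- validate_expression_matrix(m)
  if (!is.null(gene_subset)) {
    miss <- setdiff(gene_subset, rownames(m))
    if (length(miss)) {
      stop("gene_subset contains unknown gene(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    m <- m[gene_subset, , drop = FALSE]
  }
  if (ncol(m) < 2L || ncol(unique(t(m))) < 2L) {
    stop("need >= 2 distinct samples for PCA")
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_comp, ncol(pc$x))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = vf[seq_len(k)])
}
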