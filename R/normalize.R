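#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common intensity distribution: after
#' normalization each column's sorted values equal the vector of row-wise
#' means of the column-sorted input. Delegates to
#' [limma::normalizeQuantiles()], the standard implementation for log2
#' single-channel intensities.
#'
#' @param m Expression matrix (genes x samples), no missing values.
#' @return Matrix of the same shape with identical gene/sample identifiers.
#' @export
quantile_normalize <- function(m) {
  m <- validate_expression_matrix(m)
  if (ncol(m) < 2L) {
    stop("quantile normalization needs >= 2 samples")
  }
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  out
}

# Build the covariate part of the nuisance design matrix. Continuous
# covariates are mean-centered so the retained gene-wise intercept equals the
# gene's mean at the average covariate value; categorical covariates become
# treatment-coded indicator columns. Constant covariates are skipped with a
# warning; columns aliased with earlier ones are dropped by a rank-revealing
# QR, with a warning naming them.
build_covariate_design <- function(meta, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (!cv %in% colnames(meta)) {
      stop("covariate not found in sample metadata: ", cv)
    }
    v <- meta[[cv]]
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) {
        warning("covariate '", cv, "' is constant; skipped")
        next
      }
      cols[[cv]] <- matrix(v - mean(v), ncol = 1L,
                           dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) {
        warning("covariate '", cv, "' is constant; skipped")
        next
      }
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1L])
      cols[[cv]] <- mm
    }
  }
  if (!length(cols)) {
    return(NULL)
  }
  X <- do.call(cbind, cols)
  full <- cbind(`(Intercept)` = 1, X)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    keep <- qr_full$pivot[seq_len(qr_full$rank)]
    dropped <- colnames(full)[setdiff(seq_len(ncol(full)), keep)]
    warning("dropping covariate column(s) aliased with others: ",
            paste(dropped, collapse = ", "))
    X <- full[, setdiff(keep, 1L), drop = FALSE]
    if (ncol(X) == 0L) return(NULL)
  }
  X
}

#' Remove nuisance covariate effects from an expression matrix
#'
#' Fits, for every gene, a linear model of expression on the listed nuisance
#' covariates (e.g. RIN as a continuous covariate, center as a categorical
#' one) and subtracts the fitted covariate contribution, retaining the
#' intercept. Continuous covariates are centered before fitting. The least
#' squares removal is delegated to [limma::removeBatchEffect()].
#'
#' @param m Expression matrix (genes x samples).
#' @param meta Sample metadata with one row per matrix sample.
#' @param covariates Character vector of metadata column names to remove.
#' @return Residualized matrix of the same shape; for each gene the result is
#'   uncorrelated with each removed continuous covariate.
#' @export
remove_covariate_effects <- function(m, meta, covariates) {
  m <- validate_expression_matrix(m)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) {
    stop("sample sheet does not cover all matrix samples")
  }
  X <- build_covariate_design(meta, covariates)
  if (is.null(X)) {
    return(m)
  }
  out <- limma::removeBatchEffect(m, covariates = X,
                                  design = matrix(1, ncol(m), 1L))
  dimnames(out) <- dimnames(m)
  out
}
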