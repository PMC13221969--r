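# Downstream quantification statistics used on qPCR, immunohistochemistry
# and mouse-model readouts.

#' Relative quantification by the 2^-ddCt method
#'
#' Normalizes a target gene's Ct against the mean of the reference genes'
#' Ct (two reference genes are combined by the arithmetic mean of their Ct,
#' i.e. the geometric mean on the linear scale), then expresses abundance
#' relative to a calibrator:
#' `dCt = ct_target - mean(ct_refs)`; `RQ = 2^-(dCt - calibrator_delta_ct)`.
#'
#' @param ct_target Target-gene Ct (cycles, 0-45).
#' @param ct_refs Numeric vector of reference-gene Ct values (e.g. TBP and
#'   GAPDH); must be non-empty.
#' @param calibrator_delta_ct The comparator sample's dCt.
#' @return List with `delta_ct`, `delta_delta_ct` and `rq`.
#' @export
relative_quantification <- function(ct_target, ct_refs, calibrator_delta_ct) {
  if (!length(ct_refs)) stop("reference Ct list must be non-empty")
  cts <- c(ct_target, ct_refs)
  if (any(!is.finite(cts)) || any(cts < 0 | cts > 45)) {
    stop("Ct values must lie within the instrument range [0, 45]")
  }
  delta_ct <- ct_target - mean(ct_refs)
  ddct <- delta_ct - calibrator_delta_ct
  list(delta_ct = delta_ct, delta_delta_ct = ddct, rq = 2^(-ddct))
}

#' Immunohistochemistry score
#'
#' Product of the staining intensity grade (0 = none, 1 = low, 2 = medium,
#' 3 = strong) and the numerical code of the percentage of positive cells
#' (0 = 0%; 1 = under 10%; 2 = 10-50%; 3 = 51-80%; 4 = over 81%). The
#' maximum score is 12 (strong staining in more than 81% of cells). The
#' printed percentage bins leave boundaries ambiguous; they are implemented
#' as `[0]`, `(0,10)`, `[10,50]`, `(50,80]`, `(80,100]`.
#'
#' @param intensity_grade Integer grade(s) in 0..3.
#' @param percent_positive Percentage(s) of positive cells in `[0, 100]`.
#' @return Integer score(s) in 0..12.
#' @export
ihc_score <- function(intensity_grade, percent_positive) {
  if (any(!intensity_grade %in% 0:3)) {
    stop("intensity grade must be 0, 1, 2 or 3")
  }
  if (any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent positive must lie in [0, 100]")
  }
  code <- ifelse(percent_positive == 0, 0L,
          ifelse(percent_positive < 10, 1L,
          ifelse(percent_positive <= 50, 2L,
          ifelse(percent_positive <= 80, 3L, 4L))))
  as.integer(intensity_grade) * code
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two raters over the same items:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the chance agreement from the raters' marginal frequencies.
#'
#' @param ratings_a,ratings_b Equal-length categorical rating vectors.
#' @return Scalar kappa. If both raters are constant and identical
#'   (`p_e = 1`), agreement is perfect and 1 is returned with a warning.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length")
  }
  if (!length(ratings_a)) stop("rating vectors must be non-empty")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    warning("both raters constant and identical; kappa defined as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Metastatic surface-area ratio
#'
#' Percentage of brain surface occupied by metastases over a set of
#' consecutive sections: `100 * sum(metastatic area) / sum(brain area)`.
#'
#' @param met_areas Per-section metastatic areas (same units^2 as
#'   `brain_areas`).
#' @param brain_areas Per-section whole-brain areas; total must be > 0.
#' @return Scalar percentage in `[0, 100]`.
#' @export
metastatic_surface_ratio <- function(met_areas, brain_areas) {
  if (!length(met_areas) || length(met_areas) != length(brain_areas)) {
    stop("need equal-length non-empty area vectors")
  }
  if (any(met_areas < 0 | brain_areas < 0)) stop("areas must be >= 0")
  if (sum(brain_areas) <= 0) stop("total brain area must be > 0")
  over <- which(met_areas > brain_areas)
  if (length(over)) {
    stop("metastatic area exceeds brain area on section(s): ",
         paste(over, collapse = ", "))
  }
  100 * sum(met_areas) / sum(brain_areas)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample location test on ranks with tie correction. The U statistic
#' is computed from the rank sum of `x`; the two-sided p-value is exact
#' (full enumeration of rank assignments, correct under ties) when the
#' combined sample size is at most 12, and uses the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p = 1))
  }
  mu <- n1 * n2 / 2
  if (n <= 12L) {
    combos <- utils::combn(n, n1)
    u_null <- apply(combos, 2L, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(u_null - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = U, p = p)
}

#' Pearson correlation test
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' with `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, `n >= 3`, both with non-zero variance.
#' @return List with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
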