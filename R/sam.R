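# Significance analysis of microarrays (SAM) for a two-class unpaired
# contrast: modified t-statistic d = (mean1 - mean2) / (s + s0), fudge
# factor s0 chosen by coefficient-of-variation minimization, and empirical
# per-gene q-values from balanced label permutations.

# Normalize labels to a logical "in class 1 (brain)" vector.
as_class1 <- function(labels) {
  if (is.logical(labels)) {
    if (!any(labels) || all(labels)) {
      stop("labels must contain exactly 2 classes, got 1")
    }
    return(labels)
  }
  u <- unique(labels)
  if (length(u) != 2L) {
    stop("labels must contain exactly 2 classes, got ", length(u))
  }
  if ("brain" %in% u) return(labels == "brain")
  labels == u[1L]
}

# Per-gene numerator (difference of class means) and pooled standard error
# of that difference, with unequal class sizes (Tusher-style s_gene).
sam_moments <- function(m, class1) {
  n1 <- sum(class1); n2 <- sum(!class1)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs >= 2 samples (got ", n1, " and ", n2, ")")
  }
  x1 <- m[, class1, drop = FALSE]
  x2 <- m[, !class1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums(x1 * x1) - n1 * m1 * m1
  ss2 <- rowSums(x2 * x2) - n2 * m2 * m2
  s <- sqrt((1 / n1 + 1 / n2) * pmax(ss1 + ss2, 0) / (n1 + n2 - 2))
  list(numerator = m1 - m2, s = s)
}

#' SAM modified t-statistic
#'
#' Computes, per gene, `d = (mean_brain - mean_extra) / (s + s0)` where `s`
#' is the unequal-n pooled standard error of the mean difference and `s0` a
#' shared fudge factor damping inflation of `d` at low variance.
#'
#' @param m Expression matrix (genes x samples, log2 scale).
#' @param labels Two-class sample labels (logical, or a vector whose classes
#'   include `"brain"`; the brain/first class is the numerator's first term).
#' @param s0 Fudge factor, a non-negative scalar.
#' @return data.frame with columns `gene_id`, `d_score`, `s_gene`.
#' @export
sam_d_statistic <- function(m, labels, s0 = 0) {
  stopifnot(is.numeric(s0), length(s0) == 1L, s0 >= 0)
  class1 <- as_class1(labels)
  mom <- sam_moments(m, class1)
  data.frame(gene_id = rownames(m),
             d_score = mom$numerator / (mom$s + s0),
             s_gene = mom$s,
             stringsAsFactors = FALSE)
}

#' Estimate the SAM fudge factor s0
#'
#' Searches the percentiles of the gene-wise standard errors `s` (0th to
#' 100th in steps of 5) for the candidate that minimizes the coefficient of
#' variation of the median absolute deviation of `d` computed within
#' s-quantile windows, so that the spread of `d` is as independent of `s` as
#' possible. Deterministic given its inputs.
#'
#' @param numerators Per-gene mean differences.
#' @param s_values Per-gene pooled standard errors (>= 0).
#' @return The selected `s0` (scalar >= 0).
#' @export
estimate_s0 <- function(numerators, s_values) {
  stopifnot(length(numerators) == length(s_values), all(s_values >= 0))
  if (length(unique(s_values)) == 1L) {
    warning("all gene-wise standard errors identical; s0 = 0")
    return(0)
  }
  candidates <- unique(stats::quantile(s_values, probs = seq(0, 1, by = 0.05),
                                       names = FALSE))
  # windows: ~20 equal-count bins of genes by s
  n_bins <- min(20L, max(2L, floor(length(s_values) / 10)))
  bins <- cut(rank(s_values, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  cv <- vapply(candidates, function(s0c) {
    d <- numerators / (s_values + s0c)
    v <- vapply(split(d, bins),
                function(z) stats::median(abs(z - stats::median(z))),
                numeric(1L))
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  candidates[which.min(cv)]
}

# All or sampled distinct two-class label assignments, excluding the
# observed one. Returns a list of logical vectors (class-1 membership).
permutation_set <- function(class1, n_perm, seed) {
  n <- length(class1)
  n1 <- sum(class1)
  obs_key <- paste(which(class1), collapse = ",")
  total <- choose(n, n1)
  if (total - 1 <= n_perm) {
    all_sets <- utils::combn(n, n1, simplify = FALSE)
    keys <- vapply(all_sets, paste, character(1L), collapse = ",")
    all_sets <- all_sets[keys != obs_key]
    perms <- all_sets
  } else {
    set.seed(as.integer(seed))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    assign(obs_key, TRUE, envir = seen)
    perms <- vector("list", n_perm)
    k <- 0L
    while (k < n_perm) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        k <- k + 1L
        perms[[k]] <- cand
      }
    }
  }
  lapply(perms, function(idx) {
    cl <- rep(FALSE, n); cl[idx] <- TRUE; cl
  })
}

#' SAM with permutation-based empirical q-values
#'
#' Runs the full two-class SAM analysis: observed modified t-statistics with
#' a fudge factor estimated once on the observed data, a null distribution
#' of statistics from distinct label permutations (the observed labeling is
#' excluded; all distinct assignments are enumerated when there are no more
#' than `n_perm` of them), and per-gene empirical q-values
#' \deqn{q_g = \hat\pi_0 \cdot \frac{\mathrm{mean}_{perm}\,\#\{|d^*| \ge |d_g|\}}
#'   {\#\{|d| \ge |d_g|\}}}
#' clipped to `[0, 1]` and made monotone non-increasing in `|d|`.
#' `pi0` is estimated as `min(1, 2 * P(|d_obs| < median |d*|))`.
#'
#' @param m Expression matrix (genes x samples).
#' @param labels Two-class labels (see [sam_d_statistic()]).
#' @param n_perm Number of permutations (>= 100 unless fewer distinct
#'   assignments exist).
#' @param seed Integer seed; fully determines the permutation set.
#' @param s0 Optional fudge factor; estimated via [estimate_s0()] if `NULL`.
#' @return data.frame with columns `gene_id`, `d_score`, `log2fc`,
#'   `q_value`, `s_gene`; attributes `s0`, `n_perm`, `seed`, `pi0` record
#'   the analysis parameters.
#' @export
sam_permutation_q <- function(m, labels, n_perm = 1000L, seed = 1L,
                              s0 = NULL) {
  m <- validate_expression_matrix(m)
  class1 <- as_class1(labels)
  total <- choose(length(class1), sum(class1))
  if (n_perm < 100L && total - 1 > n_perm) {
    stop("n_perm must be >= 100 (or all distinct assignments enumerable)")
  }
  mom <- sam_moments(m, class1)
  if (is.null(s0)) {
    s0 <- estimate_s0(mom$numerator, mom$s)
  }
  d_obs <- mom$numerator / (mom$s + s0)
  abs_d <- abs(d_obs)
  n_genes <- nrow(m)

  perms <- permutation_set(class1, n_perm, seed)
  n_used <- length(perms)

  # null |d*| pooled across permutations and genes, in blocks
  msq <- m * m
  null_abs <- numeric(n_used * n_genes)
  block <- 200L
  pos <- 0L
  n1 <- sum(class1); n2 <- length(class1) - n1
  for (start in seq(1L, n_used, by = block)) {
    idx <- start:min(start + block - 1L, n_used)
    P <- vapply(perms[idx], as.numeric, numeric(length(class1)))
    S1 <- m %*% P; S2 <- rowSums(m) - S1
    Q1 <- msq %*% P; Q2 <- rowSums(msq) - Q1
    M1 <- S1 / n1; M2 <- S2 / n2
    ss <- pmax((Q1 - n1 * M1 * M1) + (Q2 - n2 * M2 * M2), 0)
    s_star <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    d_star <- (M1 - M2) / (s_star + s0)
    null_abs[pos + seq_along(d_star)] <- abs(d_star)
    pos <- pos + length(d_star)
  }

  # comparisons are tolerance-robust: permutation statistics can tie with
  # observed ones exactly (e.g. the complement labeling negates d), and the
  # two are computed through different floating-point paths
  eps <- 1e-9 * max(1, max(abs_d))
  pi0 <- min(1, 2 * mean(abs_d < stats::median(null_abs) - eps))

  sorted_null <- sort(null_abs)
  # count of null |d*| >= |d_g| (ties included)
  cnt_null <- length(sorted_null) -
    findInterval(abs_d - eps, sorted_null, left.open = TRUE)
  mean_null <- cnt_null / n_used
  # observed count of |d| >= |d_g|
  sorted_obs <- sort(abs_d)
  cnt_obs <- n_genes - findInterval(abs_d - eps, sorted_obs, left.open = TRUE)
  q_raw <- pmin(1, pi0 * mean_null / cnt_obs)
  # q-value convention: minimum raw FDR over thresholds at least as loose
  ord <- order(abs_d, decreasing = TRUE)
  q <- numeric(n_genes)
  q[ord] <- rev(cummin(rev(q_raw[ord])))

  out <- data.frame(gene_id = rownames(m),
                    d_score = d_obs,
                    log2fc = mom$numerator,
                    q_value = q,
                    s_gene = mom$s,
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "n_perm") <- n_used
  attr(out, "seed") <- as.integer(seed)
  attr(out, "pi0") <- pi0
  out
}

#' Log2 fold change between classes
#'
#' Difference of class means on the log2 scale (brain minus extra-cerebral).
#'
#' @param m Expression matrix (genes x samples, log2 scale).
#' @param labels Two-class labels (see [sam_d_statistic()]).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(m, labels) {
  class1 <- as_class1(labels)
  if (sum(class1) == 0L || sum(!class1) == 0L) {
    stop("both classes must be non-empty")
  }
  rowMeans(m[, class1, drop = FALSE]) - rowMeans(m[, !class1, drop = FALSE])
}

#' Serialize a SAM result table
#'
#' Writes the per-gene table as TSV preceded by comment lines recording the
#' fudge factor, permutation count and seed. Exact zero q-values are floored
#' at `1 / (n_perm * n_genes)` in the serialized output (zero is retained in
#' the in-memory table).
#'
#' @param res Result of [sam_permutation_q()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_results <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# s0=%.10g", attr(res, "s0")), con)
  writeLines(sprintf("# n_perm=%d", attr(res, "n_perm")), con)
  writeLines(sprintf("# seed=%d", attr(res, "seed")), con)
  out <- res
  floor_q <- 1 / (attr(res, "n_perm") * nrow(res))
  out$q_value <- pmax(out$q_value, floor_q)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
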