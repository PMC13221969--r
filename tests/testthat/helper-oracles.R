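# Shared fixtures and independent oracles used across the suite.

toy_matrix <- function(n_genes, n_samples, seed = 1, sd = 1, mean = 8) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean, sd), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# quantile normalization by explicit sort / row-mean / rank mapping
quantile_normalize_oracle <- function(m) {
  sorted <- apply(m, 2L, sort)
  target <- rowMeans(sorted)
  out <- apply(m, 2L, function(x) target[rank(x, ties.method = "first")])
  dimnames(out) <- dimnames(m)
  out
}

# plain-loop SAM d-statistic
sam_d_oracle <- function(m, class1, s0) {
  n1 <- sum(class1); n2 <- sum(!class1)
  vapply(seq_len(nrow(m)), function(i) {
    x1 <- m[i, class1]; x2 <- m[i, !class1]
    sp <- sqrt((1 / n1 + 1 / n2) *
                 (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) /
                 (n1 + n2 - 2))
    (mean(x1) - mean(x2)) / (sp + s0)
  }, numeric(1L))
}

# exhaustive-enumeration SAM q-values for small designs, written with
# explicit loops over all distinct label assignments (observed excluded)
sam_q_oracle_exhaustive <- function(m, class1, s0) {
  n <- length(class1); n1 <- sum(class1)
  d_obs <- sam_d_oracle(m, class1, s0)
  abs_d <- abs(d_obs)
  combos <- utils::combn(n, n1, simplify = FALSE)
  obs <- which(class1)
  combos <- Filter(function(idx) !identical(idx, obs), combos)
  null_abs <- unlist(lapply(combos, function(idx) {
    cl <- rep(FALSE, n); cl[idx] <- TRUE
    abs(sam_d_oracle(m, cl, s0))
  }))
  pi0 <- min(1, 2 * mean(abs_d < stats::median(null_abs)))
  q_raw <- vapply(abs_d, function(a) {
    min(1, pi0 * (sum(null_abs >= a) / length(combos)) / sum(abs_d >= a))
  }, numeric(1L))
  # q-value: minimum raw estimate over all thresholds at least as loose
  vapply(seq_along(abs_d), function(i) {
    min(q_raw[abs_d <= abs_d[i]])
  }, numeric(1L))
}

# mean silhouette width of a labeling in a score space
mean_silhouette <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1L)))
    (b - a) / max(a, b)
  }, numeric(1L)))
}

# iterated grid search for the binomial log-likelihood maximum in a
# two-parameter (intercept, slope) logistic model
logistic_grid_oracle <- function(x, y, b0_range = c(-10, 10),
                                 b1_range = c(-10, 10), rounds = 5L,
                                 grid_n = 41L) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(rounds)) {
    b0s <- seq(b0_range[1L], b0_range[2L], length.out = grid_n)
    b1s <- seq(b1_range[1L], b1_range[2L], length.out = grid_n)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    step0 <- diff(b0_range) / (grid_n - 1)
    step1 <- diff(b1_range) / (grid_n - 1)
    b0_range <- b0s[best[1L]] + c(-2, 2) * step0
    b1_range <- b1s[best[2L]] + c(-2, 2) * step1
  }
  c(b0 = mean(b0_range), b1 = mean(b1_range))
}

# minimal metadata sheet for a matrix whose columns are all one cancer type
flat_metadata <- function(sample_ids, location,
                          cancer_type = "breast", center = "center_A",
                          rin = 8.8) {
  data.frame(sample_id = sample_ids,
             cancer_type = cancer_type,
             location = location,
             group = ifelse(location == "brain", 1L, 3L),
             center = center, rin = rin,
             stringsAsFactors = FALSE)
}
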