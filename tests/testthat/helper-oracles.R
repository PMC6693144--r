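# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# tiny labelled beta matrix
make_betas <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%03d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_sheet <- function(n, age = NULL, sex = NULL, batch = "b1",
                       group = "control", ids = NULL) {
  data.frame(sample_id = ids %||% sprintf("s%03d", seq_len(n)),
             age = age %||% seq(1, 50, length.out = n),
             sex = sex %||% rep(c("male", "female"), length.out = n),
             batch = rep(batch, length.out = n),
             group = rep(group, length.out = n),
             stringsAsFactors = FALSE)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  rks <- rank(pooled)
  stats <- apply(combs, 2, function(idx) sum(rks[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}

# per-base window mean: value 0 on uncovered bases within [0, chrom_end)
oracle_window_mean <- function(track, pos, half_width = 200) {
  chrom_end <- max(track$end)
  lo <- max(0, pos - half_width)
  hi <- min(chrom_end, pos + half_width + 1)
  if (hi <= lo) return(NA_real_)
  bases <- lo:(hi - 1)
  vals <- numeric(length(bases))
  for (i in seq_len(nrow(track))) {
    inside <- bases >= track$start[i] & bases < track$end[i]
    vals[inside] <- track$value[i]
  }
  mean(vals)
}

# scree elbow: max perpendicular distance to the first--last chord
oracle_elbow <- function(y) {
  n <- length(y)
  p1 <- c(1, y[1]); p2 <- c(n, y[n])
  d <- vapply(seq_len(n), function(i) {
    v <- p2 - p1; w <- c(i, y[i]) - p1
    abs(v[2] * w[1] - v[1] * w[2]) / sqrt(sum(v^2))
  }, numeric(1))
  if (max(d) < 1e-12) 1L else which.max(d)
}

# grid search for 2-type constrained least squares at 1e-3 resolution
oracle_grid_deconv2 <- function(R, y, sum_to_one = FALSE) {
  g <- seq(0, 1, by = 1e-3)
  best <- c(NA, NA); best_obj <- Inf
  for (p1 in g) {
    p2s <- if (sum_to_one) 1 - p1 else g[g <= 1 - p1 + 1e-12]
    for (p2 in p2s) {
      obj <- sum((R %*% c(p1, p2) - y)^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(p1, p2) }
    }
  }
  best
}

# direct Spearman rho with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# hand evaluation of normalized methylation entropy
oracle_entropy <- function(b) {
  term <- function(p) ifelse(p <= 0 | p >= 1, 0, p * log2(p))
  sum(term(b) + term(1 - b)) / (length(b) * log2(0.5))
}
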