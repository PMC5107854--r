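# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive quantities through different code paths
# (vectorised pure R, brute-force enumeration, closed forms) so they can
# stand as references for the package implementations.

# Uniform sinusoid trace: x = a * sin(2 pi f t) (+ offset)
sine_trace <- function(f = 0.25, duration = 60, fs = 25, a = 1, offset = 0) {
  t <- (0:(round(duration * fs) - 1)) / fs
  resp_trace(t = t, x = offset + a * sin(2 * pi * f * t), fs = fs)
}

# Brute-force ROC AUC: count concordant positive-negative pairs, ties half.
auc_bruteforce <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Independent Rosenstein implementation: vectorised pure R, full distance
# matrix, same definitions as the package kernel but none of its code.
lle_oracle <- function(x, m, tau, theiler, max_steps, fs) {
  M <- length(x) - (m - 1L) * tau
  emb <- sapply(0:(m - 1L), function(k) x[(1:M) + k * tau])
  d2 <- as.matrix(stats::dist(emb))^2
  sep <- abs(outer(1:M, 1:M, "-"))
  d2[sep <= theiler] <- Inf
  nn <- apply(d2, 1L, which.min)
  followable <- which((1:M) + max_steps <= M & nn + max_steps <= M)
  curve <- vapply(0:max_steps, function(s) {
    i <- followable + s
    j <- nn[followable] + s
    d <- sqrt(rowSums((emb[i, , drop = FALSE] - emb[j, , drop = FALSE])^2))
    d <- d[d > 0]
    if (length(d) == 0L) NA_real_ else mean(log(d))
  }, numeric(1))
  steps <- 0:max_steps
  ok <- is.finite(curve)
  slope <- stats::cov(steps[ok], curve[ok]) / stats::var(steps[ok])
  list(lle = slope * fs, curve = curve)
}

# Closed-form one-way ANOVA F for a list of group vectors.
anova_f_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all) - length(groups)
  (ssb / df1) / (ssw / df2)
}
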