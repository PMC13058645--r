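# Independent reference implementations used as oracles. These deliberately
# use different algebra / control flow from the package code paths.

# Hand-rolled Pearson correlation via centered deviations.
pearson_hand <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Fisher Z via the log form.
fisher_hand <- function(r) 0.5 * log((1 + r) / (1 - r))

# Naive triple-loop windowed cross-correlation: all windows x all lags,
# hand-rolled Pearson, Fisher Z via logs. Returns the Fisher-Z matrix.
naive_wcc <- function(p, a, window, stride, max_lag) {
  n <- length(p)
  starts <- seq(1L, n - window + 1L, by = stride)
  lags <- seq(-max_lag, max_lag)
  z <- matrix(NA_real_, length(starts), length(lags))
  for (wi in seq_along(starts)) {
    s <- starts[wi]
    for (li in seq_along(lags)) {
      L <- lags[li]
      t_lo <- s + max(L, 0L)
      t_hi <- s + window - 1L + min(L, 0L)
      x <- p[t_lo:t_hi]
      y <- a[(t_lo - L):(t_hi - L)]
      if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
      r <- pearson_hand(x, y)
      r <- min(max(r, -(1 - 1e-12)), 1 - 1e-12)
      z[wi, li] <- fisher_hand(r)
    }
  }
  z
}

# Exhaustive per-row argmax with the smallest-|lag|-then-negative tie rule.
naive_peaks <- function(z, lags) {
  t(apply(z, 1, function(row) {
    if (all(is.na(row))) return(c(NA_real_, NA_real_))
    m <- max(row, na.rm = TRUE)
    cand <- lags[!is.na(row) & row == m]
    cand <- cand[order(abs(cand), cand)]
    c(m, cand[1])
  }))
}

# Brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k/n * q by scanning; adjusted p by direct definition
# p_adj_(i) = min over j >= i of min(1, n/j * p_(j)).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(vapply(i:n, function(j) n / j * ps[j], numeric(1))))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Closed-form paired t statistic.
paired_t_hand <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(t = m / (s / sqrt(n)), df = n - 1)
}

# Textbook one-way ANOVA F from sums of squares.
anova_oneway_hand <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Textbook balanced two-way ANOVA sums of squares (equal cell sizes), where
# Type-II equals the classical decomposition.
anova_twoway_hand <- function(y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  grand <- mean(y)
  n <- length(y)
  ss_a <- sum(tapply(y, a, function(v) length(v) * (mean(v) - grand)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - grand)^2))
  cell_means <- tapply(y, list(a, b), mean)
  cell_n <- tapply(y, list(a, b), length)
  ss_cells <- sum(cell_n * (cell_means - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_cells
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  Fs <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_res / df_res)
  list(
    ss = c(ss_a, ss_b, ss_ab), df = c(df_a, df_b, df_ab),
    F = Fs,
    p = pf(Fs, c(df_a, df_b, df_ab), df_res, lower.tail = FALSE),
    ges = c(ss_a, ss_b, ss_ab) / (c(ss_a, ss_b, ss_ab) + ss_res)
  )
}

# Truncated-window running median (direct definition).
median_filter_hand <- function(v, order) {
  h <- (order - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    median(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Write a small keypoint CSV for io tests; returns the path.
write_toy_keypoints <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
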