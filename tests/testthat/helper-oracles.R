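# Independent oracles and small fixture builders. Each oracle is a
# literal, loop-level transcription of the defining formulas, kept free
# of any code path it is used to check.

# random strictly-decreasing positive boundary vector for K grades
rand_boundaries <- function(K) {
  sort(stats::runif(K - 1, min = 0.5, max = 100), decreasing = TRUE)
}

rand_simplex <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}

toy_standard <- function() {
  standard_matrix(
    data.frame(index = c("A", "B"), units = c("%", "mg/kg"),
               orientation = "higher_is_better"),
    list(A = c(4, 3, 2, 1), B = c(150, 90, 60, 30)))
}

# --- attribute measure: dense-grid evaluation of the piecewise-linear
# membership curves, built directly from hand-placed vertex lists
grid_measure_oracle <- function(x, boundaries, npts = 1e5) {
  b <- boundaries
  K <- length(b) + 1
  t <- c(b[1] + (b[1] - b[2]) / 2,
         (b[-(K - 1)] + b[-1]) / 2,
         b[K - 1] - (b[K - 2] - b[K - 1]) / 2)
  grid <- seq(t[K] - 1, t[1] + 1, length.out = npts)
  vapply(seq_len(K), function(k) {
    # vertices of grade k's curve: 0 at neighbouring anchors, 0.5 at its
    # boundaries, 1 at its own anchor, saturated beyond the edge anchors
    xs <- c(if (k < K) c(t[k + 1], b[k]), t[k], if (k > 1) c(b[k - 1], t[k - 1]))
    ys <- c(if (k < K) c(0, 0.5), 1, if (k > 1) c(0.5, 0))
    yl <- if (k == K) 1 else 0
    yr <- if (k == 1) 1 else 0
    f <- stats::approx(xs, ys, xout = grid, yleft = yl, yright = yr)$y
    stats::approx(grid, f, xout = x)$y
  }, numeric(1))
}

# --- entropy weights: literal transcription of H_j, d_j, w_j
entropy_oracle <- function(p, constant_flags = rep(FALSE, ncol(p))) {
  n <- nrow(p); m <- ncol(p)
  H <- numeric(m)
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j])
    H[j] <- -s / log(n)
  }
  d <- 1 - H
  d[d < 0] <- 0
  d[constant_flags] <- 0
  if (sum(d) < 1e-12) rep(1 / m, m) else d / sum(d)
}

# --- synthesis: direct double loop over indexes and grades
synthesize_oracle <- function(mt, w) {
  n <- dim(mt)[1]; m <- dim(mt)[2]; K <- dim(mt)[3]
  out <- matrix(0, n, K)
  for (i in seq_len(n)) for (k in seq_len(K)) {
    s <- 0
    for (j in seq_len(m)) s <- s + w[j] * mt[i, j, k]
    out[i, k] <- s
  }
  out
}

# --- confidence criterion: linear scan
classify_oracle <- function(mu, lambda) {
  s <- 0
  for (k in seq_along(mu)) {
    s <- s + mu[k]
    if (s >= lambda) return(k)
  }
  length(mu)
}

# --- one-way ANOVA from group summary statistics
anova_oracle <- function(values, groups) {
  g <- unique(groups)
  ni <- sapply(g, function(gg) sum(groups == gg))
  mi <- sapply(g, function(gg) mean(values[groups == gg]))
  si <- sapply(g, function(gg) stats::sd(values[groups == gg]))
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((ni - 1) * si^2)
  df1 <- length(g) - 1
  df2 <- N - length(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# random sample table over the two-index toy standard
rand_toy_table <- function(n_groups = 3, n = 4) {
  do.call(rbind, lapply(seq_len(n_groups), function(g)
    data.frame(sample_id = paste0("g", g, "_", seq_len(n)),
               group = paste0("grp", g),
               A = stats::runif(n, 0.5, 6),
               B = stats::runif(n, 10, 180))))
}
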