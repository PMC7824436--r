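# Independent oracles used across the suite. Deliberately written in the
# most literal way possible (explicit loops, normal equations) so they
# share no code with the implementation they check.

# Brute-force two-way ANOVA mean squares via explicit double loops.
oracle_two_way_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  rowm <- numeric(n); colm <- numeric(k)
  for (i in 1:n) {
    s <- 0
    for (j in 1:k) s <- s + x[i, j]
    rowm[i] <- s / k
  }
  for (j in 1:k) {
    s <- 0
    for (i in 1:n) s <- s + x[i, j]
    colm[j] <- s / n
  }
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in 1:n) ssr <- ssr + k * (rowm[i] - grand)^2
  for (j in 1:k) ssc <- ssc + n * (colm[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - rowm[i] - colm[j] + grand)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

oracle_icc_consistency <- function(x) {
  ms <- oracle_two_way_ms(x)
  (ms$msr - ms$mse) / (ms$msr + (ncol(x) - 1) * ms$mse)
}

oracle_icc_agreement <- function(x) {
  ms <- oracle_two_way_ms(x)
  n <- nrow(x); k <- ncol(x)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# Normal-equations least squares: coefficients and standard errors.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(beta), se = se, df = df)
}

# Small two-structure phantom shared by inference tests.
tiny_phantom <- function(seed = 1L, grid = 32L) {
  spec <- phantom_spec(
    grid_shape = rep(grid, 3L), spacing = 1,
    structures = data.frame(
      label = c(2L, 1L), roi = c("other", "hippocampus"),
      hemisphere = c(NA, "L"), tissue = c("wm", "gm"),
      cx = grid / 2, cy = grid / 2, cz = grid / 2,
      a = c(grid * 0.40, grid * 0.16), b = c(grid * 0.36, grid * 0.14),
      c = c(grid * 0.38, grid * 0.17), stringsAsFactors = FALSE),
    jitter_mm = 1)
  generate_phantom(spec, seed = seed)
}
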