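# Independent oracles used across the suite.

# all permutations of 1..n as a matrix (n! rows), built by insertion
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(p) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    idx <- seq.int(r + 1L, r + nrow(p))
    if (k > 1L) out[idx, seq_len(k - 1L)] <- p[, seq_len(k - 1L)]
    out[idx, k] <- n
    if (k < n) out[idx, seq.int(k + 1L, n)] <- p[, seq.int(k, n - 1L)]
    r <- r + nrow(p)
  }
  out
}

# brute-force null pmf of the Kendall score S against a reference with the
# given tie-group sizes, by enumerating every ranking of the data
brute_force_null <- function(tie_sizes) {
  n <- sum(tie_sizes)
  ref <- rep(seq_along(tie_sizes), tie_sizes)
  perms <- perm_matrix(n)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  # only reference-untied pairs contribute
  keep <- ref[pairs[, 1]] != ref[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  rsign <- sign(ref[pairs[, 2]] - ref[pairs[, 1]])
  S <- numeric(nrow(perms))
  for (k in seq_len(nrow(pairs))) {
    S <- S + rsign[k] * sign(perms[, pairs[k, 2]] - perms[, pairs[k, 1]])
  }
  tab <- table(S)
  data.frame(S = as.integer(names(tab)),
             prob = as.numeric(tab) / nrow(perms))
}

# noiseless cosine series on a design
cosine_series <- function(design, b = 100, A = 50, phase = 16, period = 24) {
  b + A * cos(2 * pi * (design$time_h - phase) / period)
}

# shortest circular distance between two phases, hours
circ_dist <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
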