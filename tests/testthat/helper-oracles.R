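# Independent brute-force oracles used to check the implementation.
# These deliberately re-derive each quantity from first principles in plain
# R, sharing no code with the package internals.

# Median over a disk neighbourhood, symmetric border reflection, pixel by
# pixel.
oracle_disk_median <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
  }
  out <- img
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- mapply(function(a, b) {
        img[reflect(i + a, nr), reflect(j + b, nc)]
      }, offs$a, offs$b)
      out[i, j] <- median(vals)
    }
  }
  out
}

# Exhaustive between-class variance maximization over histogram cut points.
# Returns the index of the last background bin (first maximum).
oracle_otsu_cut <- function(counts, mids) {
  n <- sum(counts)
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(length(counts) - 1L)) {
    w0 <- sum(counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / sum(counts[1:k])
    mu1 <- sum(counts[(k + 1):length(counts)] * mids[(k + 1):length(counts)]) /
      sum(counts[(k + 1):length(counts)])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  best_k
}

# Per-method outlier rules, written independently of the package.
oracle_zscore_flags <- function(x, cut = 3.29) {
  med <- median(x)
  madn <- median(abs(x - med)) * 1.4826
  if (madn == 0) return(rep(FALSE, length(x)))
  abs(x - med) / madn >= cut
}

oracle_iqr_flags <- function(x, factor = 1.7) {
  q1 <- quantile(x, 0.25, names = FALSE)
  q3 <- quantile(x, 0.75, names = FALSE)
  spread <- q3 - q1
  x < q1 - factor * spread | x > q3 + factor * spread
}

oracle_eti_flags <- function(x, level = 0.999) {
  lo <- quantile(x, (1 - level) / 2, names = FALSE)
  hi <- quantile(x, 1 - (1 - level) / 2, names = FALSE)
  x < lo | x > hi
}

# Majority vote: flagged by at least half (ceiling) of the methods.
oracle_consensus <- function(flag_matrix) {
  apply(flag_matrix, 1, function(r) sum(r) >= ceiling(length(r) / 2))
}
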