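# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_biofilmq <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "biofilmq_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_biofilmq(sprintf("`%s` must be a single positive finite number", name),
                  "biofilmq_validation_error")
  }
  invisible(x)
}

# Separable Gaussian smoothing of a matrix with symmetric (reflect) borders.
gaussian_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- conv_reflect_rows(m, k)
  t(conv_reflect_rows(t(m), k))
}

conv_reflect_rows <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- seq(1L - r, n + r)
  # symmetric reflection (0 -> 1, -1 -> 2, ...), folded repeatedly so
  # kernels wider than the image stay in range
  while (any(idx < 1L | idx > n)) {
    idx[idx < 1L] <- 1L - idx[idx < 1L]
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]
  }
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[seq(j, j + n - 1L), , drop = FALSE]
  }
  out
}

# Render filled disks into a logical matrix. Centres may lie anywhere inside
# the image; disks are clipped at the borders.
render_disks <- function(nrow, ncol, cx, cy, radius) {
  mask <- matrix(FALSE, nrow, ncol)
  radius <- rep_len(radius, length(cx))
  for (i in seq_along(cx)) {
    r <- radius[i]
    xr <- max(1L, floor(cx[i] - r)):min(nrow, ceiling(cx[i] + r))
    yr <- max(1L, floor(cy[i] - r)):min(ncol, ceiling(cy[i] + r))
    if (!length(xr) || !length(yr)) next
    dx <- xr - cx[i]
    dy <- yr - cy[i]
    hit <- outer(dx^2, dy^2, `+`) <= r^2
    mask[xr, yr] <- mask[xr, yr] | hit
  }
  mask
}
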