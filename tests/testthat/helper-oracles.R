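# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately share no code with the package
# internals they check.

# naive per-pixel window mean with replicated edges
local_mean_oracle <- function(img, n) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -n:n) {
        for (dj in -n:n) {
          ii <- min(max(i + di, 1), nr)
          jj <- min(max(j + dj, 1), nc)
          acc <- acc + img[ii, jj]
        }
      }
      out[i, j] <- acc / (2 * n + 1)^2
    }
  }
  out
}

# per-pixel evaluation of the two-condition binarization rule
binarize_oracle <- function(img, n, use_smoothed = FALSE) {
  th <- numeric(ncol(img))
  for (x in seq_len(ncol(img))) th[x] <- sum(img[, x]) / nrow(img)
  ibar <- local_mean_oracle(img, n)
  iuse <- if (use_smoothed) ibar else img
  out <- matrix(1L, nrow(img), ncol(img))
  for (y in seq_len(nrow(img))) {
    for (x in seq_len(ncol(img))) {
      if (iuse[y, x] < th[x] && ibar[y, x] < th[x]) out[y, x] <- 0L
    }
  }
  out
}

# all-pairs concordance AUC (malignant-high)
auc_oracle <- function(scores, labels) {
  m <- scores[labels == "malignant"]
  b <- scores[labels == "benign"]
  tot <- 0
  for (i in seq_along(m)) {
    for (j in seq_along(b)) {
      tot <- tot + if (m[i] > b[j]) 1 else if (m[i] == b[j]) 0.5 else 0
    }
  }
  tot / (length(m) * length(b))
}

# naive NRL summary loops (closed profile)
nrl_oracle <- function(dh, closed = TRUE) {
  n <- length(dh)
  m <- sum(dh) / n
  s2 <- 0
  for (v in dh) s2 <- s2 + (v - m)^2
  s <- sqrt(s2 / (n - 1))
  ar <- 0
  for (v in dh) if (v > m) ar <- ar + (v - m)
  ar <- ar / (m * n)
  ri <- 0
  if (closed) {
    for (i in seq_len(n)) ri <- ri + abs(dh[i] - dh[if (i == n) 1 else i + 1])
    ri <- ri / n
  } else {
    for (i in seq_len(n - 1)) ri <- ri + abs(dh[i] - dh[i + 1])
    ri <- ri / (n - 1)
  }
  list(nrl_m = m, nrl_std = s, ar = ar, ri = ri)
}

# two-pass population standard deviation
sdd_oracle <- function(theta) {
  m <- sum(theta) / length(theta)
  sqrt(sum((theta - m)^2) / length(theta))
}

# rasterized disk mask in a square raster
disk_mask <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  ((xg - c0)^2 + (yg - c0)^2 <= r^2) * 1L
}

# star-shaped (spiculated) mask via the package generator, fixed seed
star_mask <- function(r = 40, a = 0.3, lobes = 12, seed = 3, size = c(192, 192)) {
  make_shape_mask(
    shape_spec(base_radius_px = r, aspect_ratio = 1,
               spiculation_amplitude = a, spiculation_lobes = lobes,
               center = c(x = size[2] / 2, y = size[1] / 2), rng_seed = seed),
    size)
}

# contour of a mask, skipping segmentation
mask_contour <- function(mask) {
  trace_contour(list(mask = mask) |> structure(class = "hc_region"))
}
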