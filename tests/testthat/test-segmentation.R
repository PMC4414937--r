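# Column-threshold binarization, region extraction and contour tracing.

test_that("column thresholds are exact per-column means", {
  expect_equal(column_thresholds(matrix(7, 10, 5)), rep(7, 5))

  m <- matrix(50, 4, 3)
  m[, 2] <- c(0, 100, 0, 100)
  expect_equal(column_thresholds(m)[2], 50)

  set.seed(1)
  img <- matrix(runif(2500), 50, 50)
  oracle <- vapply(seq_len(50), function(x) sum(img[, x]) / 50, numeric(1))
  expect_lt(max(abs(column_thresholds(img) - oracle)), 1e-12)
})

test_that("local mean matches the naive window oracle with replicated edges", {
  expect_equal(local_mean(matrix(3.5, 8, 8), 2), matrix(3.5, 8, 8))

  z <- matrix(0, 3, 3); z[2, 2] <- 9
  expect_equal(local_mean(z, 1)[2, 2], 1.0)

  set.seed(2)
  img <- matrix(runif(900), 30, 30)
  for (n in c(1, 2, 3)) {
    expect_lt(max(abs(local_mean(img, n) - local_mean_oracle(img, n))), 1e-12)
  }
  expect_error(local_mean(img, 0), "halfwidth")
})

test_that("adaptive binarization implements the strict two-condition rule", {
  # no pixel is strictly below its column mean in a constant image
  expect_true(all(adaptive_binarize(matrix(4, 9, 9)) == 1))

  # noise-free hypoechoic disk: dark exactly on and near the disk
  # (generous background margin, as in a scan where the mass is small
  # relative to the field of view)
  mask <- disk_mask(15, pad = 30)
  img <- render_phantom(mask, echo_spec(speckle_scale = 0, texture_scale = 0), 1)
  b <- adaptive_binarize(img, n = 2)
  expect_true(all(b[mask == 1] == 0))            # lesion is dark
  far <- which(local_mean(mask, 3) == 0)          # pixels with no lesion in reach
  expect_true(all(b[far] == 1))

  # exact equality with the per-pixel oracle on random images
  set.seed(3)
  for (i in 1:20) {
    img <- matrix(runif(1600, 0, 255), 40, 40)
    n <- sample(1:3, 1)
    sm <- i %% 2 == 0
    got <- adaptive_binarize(img, n = n, use_smoothed = sm)
    expect_true(all(got == binarize_oracle(img, n, sm)),
                info = paste("instance", i))
  }
})

test_that("tumor region extraction selects, fills and is idempotent", {
  # single dark blob is returned as foreground, holes filled
  m <- matrix(1L, 40, 40)
  m[10:20, 10:20] <- 0L
  m[15, 15] <- 1L  # interior hole in the dark blob
  reg <- extract_tumor_region(m, open_radius = 0)
  expect_equal(sum(reg$mask), 11 * 11)
  expect_equal(reg$mask[15, 15], 1)

  # seeded selection picks the component containing the seed
  m2 <- matrix(1L, 60, 60)
  m2[5:30, 5:30] <- 0L      # large blob
  m2[45:52, 45:52] <- 0L    # small blob
  reg_small <- extract_tumor_region(m2, seed = c(48, 48), open_radius = 0)
  expect_equal(sum(reg_small$mask), 8 * 8)
  reg_large <- extract_tumor_region(m2, open_radius = 0)
  expect_equal(sum(reg_large$mask), 26 * 26)

  # a seed on a non-candidate pixel warns and falls back
  expect_warning(reg_fb <- extract_tumor_region(m2, seed = c(40, 40), open_radius = 0),
                 "nearest")
  expect_true(sum(reg_fb$mask) %in% c(8 * 8, 26 * 26))

  expect_error(extract_tumor_region(matrix(1L, 10, 10)), "no candidate")

  # idempotence: re-extracting the inverted output reproduces the region
  mask <- star_mask(r = 30, a = 0.2, seed = 5, size = c(128, 128))
  img <- render_phantom(mask, echo_spec(), 5)
  reg1 <- extract_tumor_region(adaptive_binarize(img))
  reg2 <- extract_tumor_region(1 - reg1$mask)
  expect_identical(reg1$mask, reg2$mask)
})

test_that("contour tracing is ordered, closed and complete", {
  sq <- matrix(0L, 5, 5)
  sq[2:4, 2:4] <- 1L
  ct <- trace_contour(structure(list(mask = sq), class = "hc_region"))
  expect_equal(nrow(ct$points), 8)
  expect_equal(ct$points[1, ], c(x = 2, y = 2))
  # clockwise in image coordinates: the second point moves right along the top
  expect_equal(ct$points[2, ], c(x = 3, y = 2))
  expect_false(any(duplicated(ct$points)))

  # boundary set equality against the brute-force definition on a disk:
  # an 8-connected traced contour consists exactly of the foreground
  # pixels with a 4-neighbor background contact (pixels whose only
  # background contact is diagonal are corner-cut), and is contained in
  # the 8-contact boundary set
  dm <- disk_mask(10)
  ct2 <- mask_contour(dm)
  has_bg_neighbor <- function(mask, diag) {
    nr <- nrow(mask); nc <- ncol(mask)
    out <- matrix(FALSE, nr, nc)
    for (i in which(mask == 1)) {
      r <- (i - 1) %% nr + 1; cc <- (i - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (!diag && abs(dr) + abs(dc) == 2) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc || mask[rr, c2] == 0) out[r, cc] <- TRUE
      }
    }
    which(out)
  }
  traced <- sort(unique(as.integer((ct2$points[, "x"] - 1) * nrow(dm) + ct2$points[, "y"])))
  expect_identical(traced, sort(has_bg_neighbor(dm, diag = FALSE)))
  expect_true(all(traced %in% has_bg_neighbor(dm, diag = TRUE)))

  expect_identical(mask_contour(dm)$points, ct2$points)
  expect_error(trace_contour(structure(list(mask = matrix(0L, 5, 5)),
                                       class = "hc_region")), "degenerate")
})

test_that("consecutive contour points are 8-neighbors and the curve closes", {
  for (sd in c(2, 9)) {
    mask <- star_mask(r = 35, a = 0.25, seed = sd, size = c(160, 160))
    p <- mask_contour(mask)$points
    steps <- cbind(diff(c(p[, "x"], p[1, "x"])), diff(c(p[, "y"], p[1, "y"])))
    expect_true(all(abs(steps) <= 1))
    expect_true(all(rowSums(abs(steps)) >= 1))
  }
})

test_that("segmentation recovers the truth mask on rendered phantoms", {
  mask <- make_shape_mask(shape_spec(30, 1.2, 0.05, 12, rng_seed = 2), c(256, 192))
  clean <- render_phantom(mask, echo_spec(speckle_scale = 0, texture_scale = 0), 2)
  expect_gt(dice(segment_image(clean)$region$mask, mask), 0.95)
  speckled <- render_phantom(mask, echo_spec(), 2)
  expect_gt(dice(segment_image(speckled)$region$mask, mask), 0.85)
})
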