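# Adaptive-threshold segmentation of hypoechoic lesions.
#
# The binarization is column-wise: every column x of the image gets its own
# threshold TH_x (the column mean), and a pixel is set to 0 (candidate tumor)
# only when both its own gray value and the local window mean around it fall
# strictly below TH_x. The two-condition rule suppresses isolated dark
# speckle pixels whose neighborhood is bright.

#' Per-column binarization thresholds
#'
#' For an image with columns indexed by the lateral position x, the
#' threshold for column x is the arithmetic mean of that column's gray
#' values: \eqn{TH_x = \frac{1}{N}\sum_{y=1}^{N} I(x, y)} where N is the
#' number of rows.
#'
#' @param image numeric matrix; rows are depth y, columns are lateral x.
#' @return Numeric vector of length `ncol(image)` of column thresholds.
#' @seealso [adaptive_binarize()]
#' @export
column_thresholds <- function(image) {
  check_image(image)
  colMeans(image)
}

#' Local window mean with replicated edges
#'
#' Mean gray value in the (2n+1) x (2n+1) window centered on each pixel.
#' At the image border the window is filled by edge replication so that the
#' local mean is defined for every pixel. The box filter is applied as two
#' separable passes of shifted sums, so each output is a plain sum of
#' (2n+1)^2 addends.
#'
#' @param image numeric matrix.
#' @param n window half-width (window side is 2n+1); integer >= 1.
#' @return Matrix of the same shape as `image`.
#' @export
local_mean <- function(image, n = 2) {
  check_image(image)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("window halfwidth n must be >= 1", call. = FALSE)
  nr <- nrow(image)
  nc <- ncol(image)
  pad <- image[c(rep(1L, n), seq_len(nr), rep(nr, n)),
               c(rep(1L, n), seq_len(nc), rep(nc, n)), drop = FALSE]
  w <- 2L * n + 1L
  rowpass <- matrix(0, nr, nc + 2L * n)
  for (di in seq_len(w)) {
    rowpass <- rowpass + pad[(di - 1L) + seq_len(nr), , drop = FALSE]
  }
  sums <- matrix(0, nr, nc)
  for (dj in seq_len(w)) {
    sums <- sums + rowpass[, (dj - 1L) + seq_len(nc), drop = FALSE]
  }
  sums / (w * w)
}

#' Adaptive column-wise binarization
#'
#' Produces the binary image B with
#' \deqn{B(x,y) = 0 \iff I(x,y) < TH_x \;\mathrm{and}\; \bar I(x,y) < TH_x,}
#' and 1 otherwise, where \eqn{TH_x} is the column mean
#' ([column_thresholds()]) and \eqn{\bar I} the local window mean
#' ([local_mean()]). Both inequalities are strict, so a constant image maps
#' to an all-ones mask. Dark (hypoechoic) structures such as lesions and
#' posterior shadows come out as 0.
#'
#' @param image numeric matrix.
#' @param n window half-width passed to [local_mean()]; default 2 (5x5).
#' @param use_smoothed if `TRUE`, the first condition tests the smoothed
#'   image \eqn{\bar I} instead of the raw image. Default `FALSE` (raw).
#' @return 0/1 integer matrix with attribute `window_halfwidth = n`.
#' @export
adaptive_binarize <- function(image, n = 2, use_smoothed = FALSE) {
  check_image(image)
  th <- column_thresholds(image)
  ibar <- local_mean(image, n)
  thmat <- matrix(th, nrow = nrow(image), ncol = ncol(image), byrow = TRUE)
  iuse <- if (use_smoothed) ibar else image
  b <- matrix(1L, nrow(image), ncol(image))
  b[iuse < thmat & ibar < thmat] <- 0L
  attr(b, "window_halfwidth") <- as.integer(n)
  b
}

#' Extract the tumor region from a binary mask
#'
#' Selects one connected dark (0) component of an adaptively binarized
#' image as the tumor region. The candidate field is first cleaned by a
#' morphological opening with a small disk, which removes speckle-induced
#' specks and thin bridges; then the 8-connected component containing the
#' seed is taken (default seed: the largest component, ties broken by the
#' smaller top-left bounding-box corner), and its interior holes are
#' filled (background taken 4-connected).
#'
#' @param mask 0/1 matrix from [adaptive_binarize()]: tumor candidates are 0.
#' @param seed optional `c(x, y)` pixel inside the tumor. If the seed falls
#'   on a non-candidate pixel the nearest candidate component is used, with
#'   a warning.
#' @param open_radius radius (pixels) of the disk used for the opening;
#'   0 disables the opening.
#' @return An object of class `hc_region`: list with `mask` (0/1 matrix,
#'   tumor = 1, exactly one 8-connected component, holes filled) and `seed`
#'   (the pixel that selected the component).
#' @export
extract_tumor_region <- function(mask, seed = NULL, open_radius = 3) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  dark <- (mask == 0) * 1
  if (!any(dark == 1)) stop("no candidate region: mask has no 0 pixels", call. = FALSE)
  opened <- dark
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L, shape = "disc")
    opened <- EBImage::opening(dark, brush)
    if (!any(opened == 1)) opened <- dark  # opening removed everything; fall back
  }
  lab <- label_components_8(opened)
  ncomp <- max(lab)
  counts <- tabulate(lab[lab > 0L], nbins = ncomp)

  pick_largest <- function() {
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      # tie-break: smaller top-left bounding box corner (row, then column)
      key <- vapply(best, function(l) {
        idx <- which(lab == l, arr.ind = TRUE)
        min(idx[, 1]) * (ncol(lab) + 1) + min(idx[, 2])
      }, numeric(1))
      best <- best[which.min(key)]
    }
    best[1]
  }

  if (is.null(seed)) {
    chosen <- pick_largest()
    idx <- which(lab == chosen, arr.ind = TRUE)
    seed_used <- c(x = round(mean(idx[, 2])), y = round(mean(idx[, 1])))
  } else {
    sx <- as.integer(seed[1])
    sy <- as.integer(seed[2])
    if (sx < 1 || sx > ncol(mask) || sy < 1 || sy > nrow(mask)) {
      stop("seed outside image bounds", call. = FALSE)
    }
    if (lab[sy, sx] > 0L) {
      chosen <- lab[sy, sx]
    } else {
      warning("seed does not lie on a candidate pixel; using nearest candidate component")
      idx <- which(lab > 0L, arr.ind = TRUE)
      d2 <- (idx[, 1] - sy)^2 + (idx[, 2] - sx)^2
      dmin <- vapply(seq_len(ncomp), function(l) {
        sel <- lab[cbind(idx[, 1], idx[, 2])] == l
        sqrt(min(d2[sel]))
      }, numeric(1))
      # among components essentially as near as the nearest one, take the
      # largest: a speckle speck a pixel closer must not beat the lesion
      near <- which(dmin <= min(dmin) + 4)
      chosen <- near[which.max(counts[near])]
    }
    seed_used <- c(x = sx, y = sy)
  }

  region <- lab == chosen
  filled <- region | !flood_from_border(region)
  out <- list(mask = filled * 1, seed = seed_used)
  class(out) <- "hc_region"
  out
}

#' @export
print.hc_region <- function(x, ...) {
  cat("Tumor region:", sum(x$mask), "pixels,",
      paste(dim(x$mask), collapse = " x "), "mask, seed (x,y) =",
      paste(x$seed, collapse = ","), "\n")
  invisible(x)
}

#' Trace the closed boundary of a region
#'
#' Moore-neighbor boundary tracing: starting at the topmost (then leftmost)
#' boundary pixel, the 8-neighborhood of the current pixel is scanned
#' clockwise from the backtrack position until the next foreground pixel is
#' found. The trace stops when the start pixel is re-entered from the
#' initial direction, yielding an ordered, clockwise (in image coordinates,
#' y down) closed pixel sequence in which consecutive points are
#' 8-neighbors.
#'
#' @param region an `hc_region`, or a 0/1 matrix with foreground = 1.
#' @return An object of class `hc_contour`: list with `points` (integer
#'   matrix, columns `x`, `y`; the closing edge back to the first point is
#'   implicit) and `closed = TRUE`.
#' @export
trace_contour <- function(region) {
  mask <- if (inherits(region, "hc_region")) region$mask else region
  if (!is.matrix(mask)) stop("region must be an hc_region or a matrix", call. = FALSE)
  fg <- mask != 0
  if (sum(fg) < 4) stop("degenerate region: fewer than 4 foreground pixels", call. = FALSE)
  nr <- nrow(fg)
  nc <- ncol(fg)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && fg[r, c]

  # start: topmost row, then leftmost column
  start_idx <- which(fg)
  rr <- ((start_idx - 1L) %% nr) + 1L
  cc <- ((start_idx - 1L) %/% nr) + 1L
  ord <- order(rr, cc)
  sr <- rr[ord[1]]
  sc <- cc[ord[1]]

  # clockwise Moore neighborhood, starting north: N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

  # backtrack starts at the (background) pixel north of the start pixel
  pr <- sr; pc <- sc
  bdir <- 1L  # direction from p to backtrack pixel (north)
  xs <- integer(0)
  ys <- integer(0)
  first_move <- NULL
  max_steps <- 4L * sum(fg) + 8L
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) stop("contour tracing failed to close", call. = FALSE)
    xs <- c(xs, pc)
    ys <- c(ys, pr)
    found <- FALSE
    d <- bdir
    for (i in seq_len(8L)) {
      d <- (d %% 8L) + 1L  # next clockwise direction
      qr <- pr + dr[d]
      qc <- pc + dc[d]
      if (at(qr, qc)) {
        # new backtrack: the previously examined (background) neighbor
        prevd <- ((d - 2L) %% 8L) + 1L
        br <- pr + dr[prevd]
        bc <- pc + dc[prevd]
        pr <- qr
        pc <- qc
        # direction from the new p back to the backtrack pixel
        bdir <- which(dr == (br - pr) & dc == (bc - pc))
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster; cannot happen for >=4 px blobs with opening
    if (is.null(first_move)) {
      first_move <- c(pr, pc)
    } else if (pr == sr && pc == sc) {
      # about to repeat the start; check the next move replicates the first
      d <- bdir
      for (i in seq_len(8L)) {
        d <- (d %% 8L) + 1L
        if (at(pr + dr[d], pc + dc[d])) break
      }
      if (pr + dr[d] == first_move[1] && pc + dc[d] == first_move[2]) break
      # else: start pixel is revisited on a different branch; continue
    }
  }
  # drop duplicate visits of the start pixel at the end, if any
  pts <- cbind(x = xs, y = ys)
  out <- list(points = pts, closed = TRUE)
  class(out) <- "hc_contour"
  out
}

#' @export
print.hc_contour <- function(x, ...) {
  cat("Closed contour:", nrow(x$points), "pixels, x in [",
      min(x$points[, "x"]), ",", max(x$points[, "x"]), "], y in [",
      min(x$points[, "y"]), ",", max(x$points[, "y"]), "]\n")
  invisible(x)
}

#' Segment one image end to end
#'
#' Convenience wrapper: adaptive binarization, tumor-region extraction and
#' contour tracing in one call.
#'
#' @inheritParams adaptive_binarize
#' @inheritParams extract_tumor_region
#' @return List with `mask` (binary image), `region` (`hc_region`) and
#'   `contour` (`hc_contour`).
#' @export
segment_image <- function(image, n = 2, seed = NULL, open_radius = 3,
                          use_smoothed = FALSE) {
  b <- adaptive_binarize(image, n = n, use_smoothed = use_smoothed)
  region <- extract_tumor_region(b, seed = seed, open_radius = open_radius)
  contour <- trace_contour(region)
  list(mask = b, region = region, contour = contour)
}
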