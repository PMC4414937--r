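# Internal raster utilities shared by the segmentation and feature modules.
#
# Conventions used throughout the package:
#   * an image is a numeric matrix; rows index depth y (increasing downward),
#     columns index the lateral position x, so I(x, y) == img[y, x]
#   * coordinates are 1-based (x = column, y = row), matching R indexing
#   * binary masks are 0/1 matrices of the same shape as their source image

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < 3 || ncol(img) < 3) {
    stop(what, " must be at least 3x3", call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(img)
}

# Label 8-connected foreground (non-zero) components by breadth-first
# frontier expansion. Written here because the labeling in EBImage uses
# 4-connectivity; foreground components in this package are 8-connected
# (with 4-connected background, the standard complementary pair).
label_components_8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  remaining <- mask != 0
  fg <- which(remaining)
  cur <- 0L
  for (s in fg) {
    if (!remaining[s]) next
    cur <- cur + 1L
    lab[s] <- cur
    remaining[s] <- FALSE
    frontier <- s
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      rr <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
      cc <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- unique(idx[remaining[idx]])
      if (length(idx) > 0L) {
        lab[idx] <- cur
        remaining[idx] <- FALSE
      }
      frontier <- idx
    }
  }
  lab
}

# 4-connected reachability from the matrix border through !blocked cells.
# An 8-connected digital curve cannot be crossed by a 4-connected flood,
# so this is the region-filling primitive for chord-closed half contours
# and for interior hole detection.
flood_from_border <- function(blocked) {
  nr <- nrow(blocked)
  nc <- ncol(blocked)
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- !blocked[1, ]
  reach[nr, ] <- !blocked[nr, ]
  reach[, 1] <- !blocked[, 1]
  reach[, nc] <- !blocked[, nc]
  repeat {
    grow <- matrix(FALSE, nr, nc)
    grow[-1, ] <- grow[-1, ] | reach[-nr, ]
    grow[-nr, ] <- grow[-nr, ] | reach[-1, ]
    grow[, -1] <- grow[, -1] | reach[, -nc]
    grow[, -nc] <- grow[, -nc] | reach[, -1]
    grow <- grow & !blocked & !reach
    if (!any(grow)) break
    reach <- reach | grow
  }
  reach
}

# Bresenham rasterization of the segment (x0,y0)-(x1,y1), endpoints included.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0)
  dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  xs <- integer(n)
  ys <- integer(n)
  x <- x0
  y <- y0
  i <- 0L
  repeat {
    i <- i + 1L
    xs[i] <- x
    ys[i] <- y
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) {
      err <- err - dy
      x <- x + sx
    }
    if (e2 < dx) {
      err <- err + dx
      y <- y + sy
    }
  }
  cbind(x = xs[seq_len(i)], y = ys[seq_len(i)])
}

# Dice overlap coefficient between two binary masks of equal shape.

#' Dice coefficient between two binary masks
#'
#' Computes \eqn{2|X \cap Y| / (|X| + |Y|)} for two 0/1 masks of identical
#' shape; the standard overlap score for judging segmentation quality
#' against a ground-truth mask.
#'
#' @param a,b binary (0/1 or logical) matrices of identical dimensions.
#' @return A number in \[0, 1\]; 1 for identical non-empty masks.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share dimensions", call. = FALSE)
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
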