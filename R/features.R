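# Contour shape features for full and half tumor contours.
#
# Six parameters summarize boundary irregularity: tumor circularity
# (TC = P^2/A), the mean and standard deviation of the normalized radial
# length (NRL), the area ratio (AR), the roughness index (RI), and the
# standard deviation of degree (SDD) of vertex angles formed with contour
# neighbors at pixel offset +/-k. Half mode analyzes only the upper arc of
# the contour, between its leftmost and rightmost pixels, which in shadowed
# ultrasound images is the part least affected by the posterior acoustic
# shadow.

#' Split a closed contour into its upper half
#'
#' Finds the leftmost pixel \eqn{P_l} (minimum x, ties broken by smaller y)
#' and rightmost pixel \eqn{P_r} of the contour, splits the closed sequence
#' at those two points and returns the arc with the smaller mean row (the
#' upper arc, since rows grow with depth), together with the Bresenham
#' rasterization of the chord \eqn{L_{lr}} joining \eqn{P_l} to \eqn{P_r}.
#'
#' When the contour near the lateral extremes is corrupted by a posterior
#' acoustic shadow, an exclusion interval of columns can be supplied;
#' contour pixels whose x lies inside it are ignored when locating
#' \eqn{P_l}/\eqn{P_r} (the programmatic counterpart of excluding the
#' shadowed portion by hand).
#'
#' @param contour an `hc_contour` (closed, >= 8 pixels).
#' @param exclusion optional column interval(s) to ignore when locating
#'   the endpoints: a vector `c(min_x, max_x)` or a two-column matrix with
#'   one interval per row.
#' @param endpoint_tol optional tolerance band, in columns, for the
#'   endpoint search: when positive, the endpoint is the shallowest
#'   (smallest y) contour pixel within `endpoint_tol` columns of the
#'   extreme column, which keeps a segmented shadow bulging a pixel or two
#'   past the mass's true lateral extent from dragging an endpoint deep
#'   into the shadow. The default 0 applies the plain rule: the extreme-x
#'   pixel, ties broken toward smaller y.
#' @return An object of class `hc_half_contour`: list with `arc` (ordered
#'   pixel matrix from \eqn{P_l} to \eqn{P_r}), `p_left`, `p_right`, and
#'   `chord` (pixel matrix of \eqn{L_{lr}}).
#' @export
split_half_contour <- function(contour, exclusion = NULL, endpoint_tol = 0) {
  if (!inherits(contour, "hc_contour")) stop("contour must be an hc_contour", call. = FALSE)
  pts <- contour$points
  np <- nrow(pts)
  if (np < 8) stop("contour too short to split (need >= 8 pixels)", call. = FALSE)
  elig <- rep(TRUE, np)
  if (!is.null(exclusion)) {
    if (!is.matrix(exclusion)) exclusion <- matrix(exclusion, ncol = 2, byrow = TRUE)
    for (r in seq_len(nrow(exclusion))) {
      elig <- elig & !(pts[, "x"] >= exclusion[r, 1] & pts[, "x"] <= exclusion[r, 2])
    }
    if (!any(elig)) stop("exclusion removes contour: no pixels left", call. = FALSE)
  }
  idx <- which(elig)
  xe <- pts[idx, "x"]
  ye <- pts[idx, "y"]
  cand_l <- idx[xe <= min(xe) + endpoint_tol]
  il <- cand_l[order(pts[cand_l, "y"], pts[cand_l, "x"])][1]
  cand_r <- idx[xe >= max(xe) - endpoint_tol]
  ir <- cand_r[order(pts[cand_r, "y"], -pts[cand_r, "x"])][1]
  if (il == ir) stop("degenerate contour: leftmost and rightmost pixel coincide", call. = FALSE)

  cyc <- function(from, to) {
    if (from <= to) from:to else c(from:np, 1:to)
  }
  arc1 <- cyc(il, ir)  # follows the stored (clockwise) order
  arc2 <- cyc(ir, il)
  m1 <- mean(pts[arc1, "y"])
  m2 <- mean(pts[arc2, "y"])
  upper <- if (m1 <= m2) arc1 else arc2
  arc <- pts[upper, , drop = FALSE]
  # store left-to-right: from P_l to P_r
  if (!(arc[1, "x"] == pts[il, "x"] && arc[1, "y"] == pts[il, "y"])) {
    arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
  }
  out <- list(
    arc = arc,
    p_left = pts[il, ],
    p_right = pts[ir, ],
    chord = bresenham(pts[il, "x"], pts[il, "y"], pts[ir, "x"], pts[ir, "y"])
  )
  class(out) <- "hc_half_contour"
  out
}

#' @export
print.hc_half_contour <- function(x, ...) {
  cat("Half contour:", nrow(x$arc), "arc pixels, P_l = (",
      x$p_left["x"], ",", x$p_left["y"], "), P_r = (",
      x$p_right["x"], ",", x$p_right["y"], "), chord of",
      nrow(x$chord), "pixels\n")
  invisible(x)
}

boundary_pixels <- function(x) {
  if (inherits(x, "hc_contour")) {
    x$points
  } else if (inherits(x, "hc_half_contour")) {
    unique(rbind(x$arc, x$chord))
  } else {
    stop("expected an hc_contour or hc_half_contour", call. = FALSE)
  }
}

#' Pixel-count perimeter and area of a closed curve
#'
#' The perimeter P is the number of distinct boundary pixels (for a half
#' contour, the arc plus its closing chord, deduplicated); the area A is
#' the number of pixels enclosed by the closed curve, boundary included.
#' Enclosure is decided by a 4-connected flood from outside the curve's
#' bounding box, which an 8-connected digital curve cannot leak through.
#'
#' @param x an `hc_contour` or `hc_half_contour`.
#' @return An object of class `hc_metrics`: list with `perimeter_px`,
#'   `area_px`, and `region` (integer matrix of all enclosed pixel
#'   coordinates, columns `x`, `y`, boundary included) used downstream for
#'   the centroid.
#' @export
close_and_measure <- function(x) {
  bpx <- boundary_pixels(x)
  x0 <- min(bpx[, "x"]) - 1L
  y0 <- min(bpx[, "y"]) - 1L
  nc <- max(bpx[, "x"]) - x0 + 2L
  nr <- max(bpx[, "y"]) - y0 + 2L
  blocked <- matrix(FALSE, nr, nc)
  blocked[cbind(bpx[, "y"] - y0, bpx[, "x"] - x0)] <- TRUE
  outside <- flood_from_border(blocked)
  inside <- !outside  # boundary pixels included
  reg <- which(inside, arr.ind = TRUE)
  region <- cbind(x = reg[, 2] + x0, y = reg[, 1] + y0)
  out <- list(
    perimeter_px = nrow(unique(bpx)),
    area_px = nrow(region),
    region = region
  )
  class(out) <- "hc_metrics"
  out
}

#' Tumor circularity
#'
#' \eqn{TC = P^2 / A} with P the pixel-count perimeter and A the enclosed
#' pixel-count area. TC is minimized by a disk (continuum limit \eqn{4\pi})
#' and grows with boundary irregularity; it is dimensionless and
#' scale-invariant in the continuum.
#'
#' @param m an `hc_metrics`, or a numeric perimeter (then `area` required).
#' @param area area count, when `m` is given as a plain perimeter.
#' @return TC as a single number.
#' @export
tumor_circularity <- function(m, area = NULL) {
  if (inherits(m, "hc_metrics")) {
    p <- m$perimeter_px
    a <- m$area_px
  } else {
    p <- m
    a <- area
  }
  if (is.null(a) || a <= 0) stop("area must be positive", call. = FALSE)
  p^2 / a
}

#' Normalized radial length profile
#'
#' Distances \eqn{d(i)} from each boundary pixel to the region centroid
#' (mean coordinate of all enclosed pixels), normalized by their maximum:
#' \eqn{\hat d(i) = d(i) / \max(d)}. In half mode the centroid is that of
#' the chord-closed half region and the profile runs over the arc pixels.
#'
#' @param metrics an `hc_metrics` from [close_and_measure()] (supplies the
#'   region pixels for the centroid).
#' @param boundary ordered boundary pixel matrix (columns `x`, `y`): the
#'   full contour points, or the open arc in half mode.
#' @return An object of class `hc_radial`: list with `d`, `d_hat`
#'   (max exactly 1), and `centroid` (`c(x, y)`, fractional).
#' @export
radial_profile <- function(metrics, boundary) {
  if (!inherits(metrics, "hc_metrics")) stop("metrics must be an hc_metrics", call. = FALSE)
  cen <- c(x = mean(metrics$region[, "x"]), y = mean(metrics$region[, "y"]))
  cp <- c(round(cen["x"]), round(cen["y"]))
  inreg <- any(metrics$region[, "x"] == cp[1] & metrics$region[, "y"] == cp[2])
  if (!inreg) warning("centroid falls outside the region (crescent-like shape)")
  d <- sqrt((boundary[, "x"] - cen["x"])^2 + (boundary[, "y"] - cen["y"])^2)
  out <- list(d = d, d_hat = d / max(d), centroid = cen)
  class(out) <- "hc_radial"
  out
}

#' NRL summary features
#'
#' From a normalized radial length profile \eqn{\hat d}:
#' * `nrl_m`: the mean \eqn{\bar d};
#' * `nrl_std`: the sample standard deviation (1/(N-1) normalization);
#' * `ar`: the area ratio \eqn{\frac{1}{\bar d N}\sum_i (\hat d(i)-\bar d)}
#'   with terms where \eqn{\hat d(i) \le \bar d} set to zero — the one-sided
#'   average excess of the radial length over its mean, a measure of how
#'   much of the shape protrudes beyond the mean-radius circle;
#' * `ri`: the roughness index, the mean absolute difference of consecutive
#'   \eqn{\hat d} values. On a closed profile the sum wraps around
#'   (\eqn{\hat d(N+1) = \hat d(1)}, N terms); on an open arc it runs over
#'   the N-1 gaps and divides by N-1.
#'
#' @param profile an `hc_radial`, or a bare numeric \eqn{\hat d} vector.
#' @param closed `TRUE` for a full (cyclic) contour profile, `FALSE` for an
#'   open half-contour arc.
#' @return Named list `(nrl_m, nrl_std, ar, ri)`.
#' @export
nrl_features <- function(profile, closed = TRUE) {
  dh <- if (inherits(profile, "hc_radial")) profile$d_hat else profile
  n <- length(dh)
  if (n < 3) stop("need at least 3 profile values", call. = FALSE)
  m <- mean(dh)
  s <- stats::sd(dh)
  ar <- sum(pmax(dh - m, 0)) / (m * n)
  ri <- if (closed) {
    sum(abs(diff(c(dh, dh[1])))) / n
  } else {
    sum(abs(diff(dh))) / (n - 1)
  }
  list(nrl_m = m, nrl_std = s, ar = ar, ri = ri)
}

#' Vertex angles along a contour
#'
#' For each boundary pixel \eqn{M_s}, the angle \eqn{\theta_s} between the
#' position vectors to the pixels k steps behind and k steps ahead:
#' \deqn{\theta_s = \arccos\frac{\vec{M_s M_{s-k}} \cdot \vec{M_s M_{s+k}}}
#'   {|\vec{M_s M_{s-k}}||\vec{M_s M_{s+k}}|}.}
#' A straight stretch gives 180 degrees; sharp spicules give small angles.
#' On a closed contour the indices wrap; on an open arc only pixels with
#' both neighbors available are used. The cosine is clamped to \[-1, 1\]
#' before the arccos; pixels where either vector degenerates to zero are
#' skipped with a warning.
#'
#' @param boundary ordered pixel matrix (columns `x`, `y`), or an
#'   `hc_contour` / `hc_half_contour`.
#' @param k pixel offset (>= 1); the sequence must have more than 2k points.
#' @param closed whether the sequence is cyclic. Defaults to `TRUE` for an
#'   `hc_contour`, `FALSE` for an `hc_half_contour`.
#' @return An object of class `hc_angles`: list with `theta` (degrees, in
#'   \[0, 180\]) and `k`.
#' @export
vertex_angles <- function(boundary, k = 5, closed = NULL) {
  if (inherits(boundary, "hc_contour")) {
    if (is.null(closed)) closed <- TRUE
    boundary <- boundary$points
  } else if (inherits(boundary, "hc_half_contour")) {
    if (is.null(closed)) closed <- FALSE
    boundary <- boundary$arc
  } else if (is.null(closed)) {
    closed <- TRUE
  }
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(boundary)
  if (n <= 2L * k) stop("need more than 2k boundary pixels", call. = FALSE)
  if (closed) {
    s <- seq_len(n)
    sm <- ((s - 1L - k) %% n) + 1L
    sp <- ((s - 1L + k) %% n) + 1L
  } else {
    s <- (k + 1L):(n - k)
    sm <- s - k
    sp <- s + k
  }
  ux <- boundary[sm, "x"] - boundary[s, "x"]
  uy <- boundary[sm, "y"] - boundary[s, "y"]
  vx <- boundary[sp, "x"] - boundary[s, "x"]
  vy <- boundary[sp, "y"] - boundary[s, "y"]
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  ok <- nu > 0 & nv > 0
  if (!all(ok)) warning("skipping ", sum(!ok), " vertex angle(s) with coincident points")
  cosang <- pmin(1, pmax(-1, (ux * vx + uy * vy)[ok] / (nu * nv)[ok]))
  out <- list(theta = acos(cosang) * 180 / pi, k = k)
  class(out) <- "hc_angles"
  out
}

#' Standard deviation of degree (SDD)
#'
#' The population standard deviation (1/N normalization) of the vertex
#' angle series \eqn{\theta_s}, in degrees. A smooth boundary has nearly
#' constant vertex angles and hence a small SDD; spiculated, irregular
#' boundaries mix sharp and flat vertices and score high.
#'
#' @param angles an `hc_angles`, or a bare numeric vector of angles in
#'   degrees (at least 2 values).
#' @return SDD in degrees.
#' @export
sdd <- function(angles) {
  th <- if (inherits(angles, "hc_angles")) angles$theta else angles
  if (length(th) < 2) stop("need at least 2 angles", call. = FALSE)
  sqrt(mean((th - mean(th))^2))
}

#' Compute the six-feature vector for a contour
#'
#' Composes the elementary operations into the feature set for one contour
#' in either mode. Full mode uses the closed contour throughout. Half mode
#' uses the chord-closed upper-half region for the perimeter, area and
#' centroid, and the open arc for the radial profile, roughness index and
#' vertex angles (no wraparound across the chord).
#'
#' @param contour an `hc_contour`.
#' @param mode `"full"` or `"half"`.
#' @param k vertex-angle pixel offset for SDD (default 5).
#' @param exclusion optional column interval passed to
#'   [split_half_contour()] (half mode only).
#' @return An object of class `hc_features`: named list with `tc`, `nrl_m`,
#'   `nrl_std`, `ar`, `ri`, `sdd`, plus `mode` and `k`.
#' @export
feature_vector <- function(contour, mode = c("full", "half"), k = 5,
                           exclusion = NULL) {
  mode <- match.arg(mode)
  if (mode == "full") {
    obj <- contour
    boundary <- contour$points
    closed <- TRUE
  } else {
    obj <- split_half_contour(contour, exclusion = exclusion)
    boundary <- obj$arc
    closed <- FALSE
  }
  m <- close_and_measure(obj)
  prof <- radial_profile(m, boundary)
  nrl <- nrl_features(prof, closed = closed)
  ang <- vertex_angles(boundary, k = k, closed = closed)
  out <- c(list(tc = tumor_circularity(m)), nrl,
           list(sdd = sdd(ang), mode = mode, k = k))
  class(out) <- "hc_features"
  out
}

#' @export
print.hc_features <- function(x, digits = 4, ...) {
  cat(sprintf(
    "%s-contour features (k = %d):\n  TC = %.*g  NRL_M = %.*g  NRL_STD = %.*g\n  AR = %.*g  RI = %.*g  SDD = %.*g deg\n",
    x$mode, x$k, digits, x$tc, digits, x$nrl_m, digits, x$nrl_std,
    digits, x$ar, digits, x$ri, digits, x$sdd))
  invisible(x)
}

#' @export
as.data.frame.hc_features <- function(x, ...) {
  data.frame(mode = x$mode, tc = x$tc, nrl_m = x$nrl_m, nrl_std = x$nrl_std,
             ar = x$ar, ri = x$ri, sdd = x$sdd, k = x$k,
             stringsAsFactors = FALSE)
}
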