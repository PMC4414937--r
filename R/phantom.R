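# Synthetic B-mode breast phantoms.
#
# Each phantom is a speckled two-level intensity field containing one
# hypoechoic lesion whose boundary is an ellipse modulated by sinusoidal
# radial undulations: low amplitude emulates the smooth margin of a
# benign-like mass (fibroadenoma), high amplitude the spiculated margin of
# a malignant-like mass (invasive ductal carcinoma). An optional posterior
# acoustic shadow (PAS) multiplicatively darkens the columns beneath the
# lesion, emulating the attenuation artifact that corrupts the lower
# lesion boundary in clinical images.

#' Lesion shape specification
#'
#' @param base_radius_px semi-minor axis of the base ellipse, pixels (> 0).
#' @param aspect_ratio lateral-to-axial elongation of the base ellipse
#'   (width/height); 1 gives a circle.
#' @param spiculation_amplitude fractional amplitude `a` of the radial
#'   undulations, in \[0, 1); 0 gives a smooth ellipse. This is the single
#'   "malignancy" knob of the generator.
#' @param spiculation_lobes number of angular undulations (integer >= 0).
#' @param center lesion center `c(x, y)` in pixels, or `NULL` to place it
#'   at the image default (laterally centered, upper-middle in depth).
#' @param rng_seed seed for the undulation phases.
#' @return An object of class `hc_shape_spec`.
#' @export
shape_spec <- function(base_radius_px = 30, aspect_ratio = 1.2,
                       spiculation_amplitude = 0, spiculation_lobes = 12,
                       center = NULL, rng_seed = 1) {
  if (base_radius_px <= 0) stop("base_radius_px must be > 0", call. = FALSE)
  if (spiculation_amplitude < 0 || spiculation_amplitude >= 1) {
    stop("spiculation_amplitude must be in [0, 1)", call. = FALSE)
  }
  if (spiculation_lobes < 0) stop("spiculation_lobes must be >= 0", call. = FALSE)
  out <- list(base_radius_px = base_radius_px, aspect_ratio = aspect_ratio,
              spiculation_amplitude = spiculation_amplitude,
              spiculation_lobes = as.integer(spiculation_lobes),
              center = center, rng_seed = as.integer(rng_seed))
  class(out) <- "hc_shape_spec"
  out
}

#' Echogenicity specification
#'
#' Intensity model for rendering: a two-level mean field (hypoechoic lesion
#' on a brighter background) under multiplicative unit-mean speckle.
#'
#' @param background_mean mean background intensity (0-255 scale).
#' @param lesion_mean mean lesion intensity; must be below
#'   `background_mean` (lesions are hypoechoic).
#' @param speckle_scale standard deviation of the unit-mean multiplicative
#'   speckle factor; 0 disables noise.
#' @param texture_scale standard deviation of a second, spatially smooth
#'   unit-mean multiplicative field emulating large-scale tissue
#'   inhomogeneity (fat lobules, ligaments, beam non-uniformity).
#'   Tissue-related texture is one of the stated difficulties of breast
#'   ultrasound; it makes column-threshold binarization messy away from
#'   the lesion. Off (0) by default: the standard phantom has a
#'   homogeneous background so that segmentation behavior is attributable
#'   to speckle and shadow alone.
#' @param texture_window half-width of the smoothing window defining the
#'   texture correlation length (patches of roughly `2*texture_window`
#'   pixels).
#' @param intensity_range clipping bounds `c(lo, hi)` for rendered values.
#' @return An object of class `hc_echo_spec`.
#' @export
echo_spec <- function(background_mean = 120, lesion_mean = 50,
                      speckle_scale = 0.3, texture_scale = 0,
                      texture_window = 15, intensity_range = c(0, 255)) {
  if (lesion_mean >= background_mean) {
    stop("lesion_mean must be below background_mean (hypoechoic lesion)",
         call. = FALSE)
  }
  if (speckle_scale < 0) stop("speckle_scale must be >= 0", call. = FALSE)
  if (texture_scale < 0) stop("texture_scale must be >= 0", call. = FALSE)
  out <- list(background_mean = background_mean, lesion_mean = lesion_mean,
              speckle_scale = speckle_scale, texture_scale = texture_scale,
              texture_window = as.integer(texture_window),
              intensity_range = intensity_range)
  class(out) <- "hc_echo_spec"
  out
}

#' Posterior acoustic shadow specification
#'
#' @param attenuation_factor multiplicative intensity factor in \[0, 1\]
#'   applied to pixels below the lesion; smaller is a darker shadow.
#' @param lateral_coverage fraction in (0, 1\] of the lesion's column span
#'   that is shadowed (centered).
#' @param depth_decay per-row multiplicative decay in (0, 1\]; 1 keeps the
#'   shadow uniform with depth.
#' @return An object of class `hc_pas_spec`.
#' @export
pas_spec <- function(attenuation_factor = 0.4, lateral_coverage = 0.8,
                     depth_decay = 1) {
  if (attenuation_factor < 0 || attenuation_factor > 1) {
    stop("attenuation_factor must be in [0, 1]", call. = FALSE)
  }
  if (lateral_coverage <= 0 || lateral_coverage > 1) {
    stop("lateral_coverage must be in (0, 1]", call. = FALSE)
  }
  if (depth_decay <= 0 || depth_decay > 1) {
    stop("depth_decay must be in (0, 1]", call. = FALSE)
  }
  out <- list(attenuation_factor = attenuation_factor,
              lateral_coverage = lateral_coverage, depth_decay = depth_decay)
  class(out) <- "hc_pas_spec"
  out
}

#' Rasterize a lesion shape mask
#'
#' The boundary is given in polar form around the center:
#' \deqn{r(\phi) = r_e(\phi)\,(1 + a\,u(\phi)),}
#' where \eqn{r_e} is the radial function of the base ellipse and
#' \eqn{u(\phi) = 0.7\sin(L\phi + \psi_1) + 0.3\sin(2L\phi + \psi_2)} is a
#' two-harmonic undulation with seeded random phases (L =
#' `spiculation_lobes`). Since `|u| <= 1` and `a < 1`, the radius stays
#' positive and the filled region is star-shaped, hence a single connected
#' component.
#'
#' @param spec an `hc_shape_spec`.
#' @param image_size `c(rows, cols)` of the target raster.
#' @return 0/1 integer matrix (lesion = 1).
#' @export
make_shape_mask <- function(spec, image_size = c(384, 192)) {
  if (!inherits(spec, "hc_shape_spec")) stop("spec must be an hc_shape_spec", call. = FALSE)
  nr <- image_size[1]
  nc <- image_size[2]
  cen <- spec$center
  if (is.null(cen)) cen <- c(x = ceiling(nc / 2), y = round(0.4 * nr))
  q <- spec$aspect_ratio
  R <- spec$base_radius_px
  a <- spec$spiculation_amplitude
  # per-axis reach: |x| <= ax, |y| <= ay on the ellipse, times the largest
  # undulation factor
  xreach <- R * q * (1 + a)
  yreach <- R * (1 + a)
  if (cen[1] - xreach < 1 || cen[1] + xreach > nc ||
      cen[2] - yreach < 1 || cen[2] + yreach > nr) {
    stop("lesion exceeds image bounds for this center/radius", call. = FALSE)
  }
  phases <- with_seed(spec$rng_seed, stats::runif(2, 0, 2 * pi))
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr), nr, nc)
  dx <- xg - cen[1]
  dy <- yg - cen[2]
  phi <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  ax <- R * q  # lateral semi-axis
  ay <- R      # axial semi-axis
  re <- (ax * ay) / sqrt((ay * cos(phi))^2 + (ax * sin(phi))^2)
  und <- if (spec$spiculation_lobes > 0) {
    0.7 * sin(spec$spiculation_lobes * phi + phases[1]) +
      0.3 * sin(2 * spec$spiculation_lobes * phi + phases[2])
  } else {
    0
  }
  mask <- (rho <= re * (1 + a * und)) * 1L
  mask
}

#' Render a speckled two-level image from a lesion mask
#'
#' The mean field takes `lesion_mean` inside the mask and `background_mean`
#' outside, and is multiplied by two independent unit-mean factors: a
#' pixelwise speckle factor \eqn{F = 1 + s(E - 1)} with
#' \eqn{E \sim \mathrm{Exp}(1)} (the intensity of a fully developed speckle
#' envelope) and s = `speckle_scale`, and a spatially smooth texture factor
#' \eqn{T = 1 + t\,Z} where Z is window-averaged white Gaussian noise
#' rescaled to unit variance and t = `texture_scale`. The result is clipped
#' to the intensity range.
#'
#' @param mask 0/1 lesion mask.
#' @param echo an `hc_echo_spec`.
#' @param rng_seed seed for the speckle and texture fields.
#' @return Numeric matrix of the same shape as `mask`.
#' @export
render_phantom <- function(mask, echo = echo_spec(), rng_seed = 1) {
  if (!inherits(echo, "hc_echo_spec")) stop("echo must be an hc_echo_spec", call. = FALSE)
  if (!any(mask != 0)) stop("mask is empty", call. = FALSE)
  field <- matrix(echo$background_mean, nrow(mask), ncol(mask))
  field[mask != 0] <- echo$lesion_mean
  with_seed(rng_seed, {
    if (echo$speckle_scale > 0) {
      e <- matrix(stats::rexp(length(mask)), nrow(mask), ncol(mask))
      field <- field * (1 + echo$speckle_scale * (e - 1))
    }
    if (echo$texture_scale > 0) {
      w <- echo$texture_window
      z <- local_mean(matrix(stats::rnorm(length(mask)), nrow(mask), ncol(mask)), w)
      # the box mean of iid N(0,1) has sd 1/(2w+1); rescale to unit sd
      field <- field * (1 + echo$texture_scale * z * (2 * w + 1))
    }
  })
  pmin(pmax(field, echo$intensity_range[1]), echo$intensity_range[2])
}

#' Apply a posterior acoustic shadow below the lesion
#'
#' For the centrally located `lateral_coverage` fraction of the lesion's
#' column span, every pixel strictly below the lesion's lowest row in that
#' column is multiplied by
#' `attenuation_factor * depth_decay^j`, j = 0, 1, ... counting rows below
#' the lesion. Pixels outside the shadowed columns, and at or above the
#' lesion, are unchanged.
#'
#' @param image rendered phantom image.
#' @param mask the lesion truth mask that casts the shadow.
#' @param pas an `hc_pas_spec`.
#' @return The shadowed image.
#' @export
apply_pas <- function(image, mask, pas = pas_spec()) {
  if (!inherits(pas, "hc_pas_spec")) stop("pas must be an hc_pas_spec", call. = FALSE)
  if (!any(mask != 0)) stop("mask is empty", call. = FALSE)
  cols <- which(colSums(mask != 0) > 0)
  span <- min(cols):max(cols)
  w <- length(span)
  cw <- max(1L, round(pas$lateral_coverage * w))
  off <- (w - cw) %/% 2L
  shadowed <- span[(off + 1L):(off + cw)]
  nr <- nrow(image)
  out <- image
  for (cx in shadowed) {
    rows <- which(mask[, cx] != 0)
    if (length(rows) == 0) next
    y0 <- max(rows)
    if (y0 >= nr) next
    below <- (y0 + 1L):nr
    fac <- pas$attenuation_factor * pas$depth_decay^(seq_along(below) - 1L)
    out[below, cx] <- out[below, cx] * fac
  }
  out
}

#' Generate one phantom
#'
#' @param shape an `hc_shape_spec`.
#' @param echo an `hc_echo_spec`.
#' @param pas an `hc_pas_spec`, or `NULL` for no shadow.
#' @param image_size `c(rows, cols)`.
#' @param label `"benign"` or `"malignant"` ground-truth class label.
#' @param rng_seed seed for the speckle field (the shape uses its own
#'   `rng_seed`).
#' @return An object of class `hc_phantom`: list with `image`,
#'   `truth_mask`, `label`, `has_pas` and the three specs.
#' @export
make_phantom <- function(shape, echo = echo_spec(), pas = NULL,
                         image_size = c(384, 192),
                         label = c("benign", "malignant"), rng_seed = 1) {
  label <- match.arg(label)
  mask <- make_shape_mask(shape, image_size)
  img <- render_phantom(mask, echo, rng_seed = rng_seed)
  has_pas <- !is.null(pas)
  if (has_pas) img <- apply_pas(img, mask, pas)
  out <- list(image = img, truth_mask = mask, label = label,
              has_pas = has_pas,
              specs = list(shape = shape, echo = echo, pas = pas),
              rng_seed = as.integer(rng_seed))
  class(out) <- "hc_phantom"
  out
}

#' @export
print.hc_phantom <- function(x, ...) {
  cat(sprintf("Phantom: %s, %s PAS, %d x %d px, lesion %d px (a = %.2f)\n",
              x$label, if (x$has_pas) "with" else "without",
              nrow(x$image), ncol(x$image), sum(x$truth_mask),
              x$specs$shape$spiculation_amplitude))
  invisible(x)
}

#' @export
plot.hc_phantom <- function(x, ...) {
  img <- x$image
  # display with row 1 on top (depth increasing downward)
  graphics::image(t(img[nrow(img):1, ]) / 255, col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(img) / ncol(img), ...)
  invisible(x)
}

#' Generate a labeled phantom cohort
#'
#' Deterministic given `master_seed`: per-case sub-seeds, lesion radii,
#' aspect ratios and spiculation amplitudes are drawn once under the master
#' seed. Benign cases draw low spiculation amplitudes and malignant cases
#' high ones; exactly `round(pas_fraction * n)` of the cases (chosen at
#' random) carry a posterior shadow.
#'
#' @param n_benign,n_malignant case counts (>= 0).
#' @param pas_fraction fraction of all cases carrying PAS, in \[0, 1\].
#' @param master_seed master RNG seed.
#' @param image_size `c(rows, cols)` for all phantoms. The default is a
#'   portrait raster (depth exceeding width), as in clinical B-mode scans,
#'   so a posterior shadow has room to run well below the lesion.
#' @param echo an `hc_echo_spec` shared by all cases.
#' @param pas an `hc_pas_spec` supplying the attenuation factor and depth
#'   decay for the shadowed cases; the lateral coverage is drawn per case
#'   (see below).
#' @param benign_amplitude,malignant_amplitude ranges `c(lo, hi)` from
#'   which per-case spiculation amplitudes are drawn uniformly. The ranges
#'   overlap: clinical series report substantial morphologic overlap
#'   between fibroadenomas and carcinomas, and a cohort whose classes are
#'   separable by eye would overstate every downstream result.
#' @param benign_coverage,malignant_coverage ranges `c(lo, hi)` for the
#'   per-case lateral shadow coverage. Malignant masses, with their
#'   desmoplastic stroma, typically cast wider and more complete shadows
#'   than calcified benign lesions, so the malignant range sits higher.
#' @param radius_range,aspect_range per-case uniform ranges for the base
#'   radius (px) and aspect ratio.
#' @param depth_frac_range per-case uniform range for the lesion center
#'   depth, as a fraction of the image height. Lesions sit at varying
#'   depths in clinical scans, so the length of the posterior shadow --
#'   and hence how strongly it corrupts the lower boundary -- varies from
#'   case to case.
#' @param spiculation_lobes undulation count shared by all cases.
#' @return An object of class `hc_cohort`: list of `hc_phantom`s with
#'   attributes recording the generation arguments.
#' @export
generate_cohort <- function(n_benign, n_malignant, pas_fraction = 1,
                            master_seed = 1, image_size = c(384, 192),
                            echo = echo_spec(), pas = pas_spec(),
                            benign_amplitude = c(0.03, 0.15),
                            malignant_amplitude = c(0.12, 0.30),
                            benign_coverage = c(0.50, 0.80),
                            malignant_coverage = c(0.65, 0.95),
                            radius_range = c(26, 36),
                            aspect_range = c(1.0, 1.5),
                            depth_frac_range = c(0.25, 0.45),
                            spiculation_lobes = 12) {
  if (n_benign < 0 || n_malignant < 0) stop("counts must be >= 0", call. = FALSE)
  n <- n_benign + n_malignant
  if (n == 0) stop("empty cohort", call. = FALSE)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  draws <- with_seed(master_seed, {
    list(
      shape_seeds = sample.int(2^31 - 2, n),
      noise_seeds = sample.int(2^31 - 2, n),
      radius = stats::runif(n, radius_range[1], radius_range[2]),
      aspect = stats::runif(n, aspect_range[1], aspect_range[2]),
      amp = ifelse(labels == "benign",
                   stats::runif(n, benign_amplitude[1], benign_amplitude[2]),
                   stats::runif(n, malignant_amplitude[1], malignant_amplitude[2])),
      depth = stats::runif(n, depth_frac_range[1], depth_frac_range[2]),
      coverage = ifelse(labels == "benign",
                        stats::runif(n, benign_coverage[1], benign_coverage[2]),
                        stats::runif(n, malignant_coverage[1], malignant_coverage[2])),
      pas_cases = sample.int(n, round(pas_fraction * n))
    )
  })
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    sh <- shape_spec(base_radius_px = draws$radius[i],
                     aspect_ratio = draws$aspect[i],
                     spiculation_amplitude = draws$amp[i],
                     spiculation_lobes = spiculation_lobes,
                     center = c(x = ceiling(image_size[2] / 2),
                                y = round(draws$depth[i] * image_size[1])),
                     rng_seed = draws$shape_seeds[i])
    case_pas <- if (i %in% draws$pas_cases) {
      pas_spec(attenuation_factor = pas$attenuation_factor,
               lateral_coverage = draws$coverage[i],
               depth_decay = pas$depth_decay)
    }
    phantoms[[i]] <- make_phantom(
      sh, echo = echo, pas = case_pas,
      image_size = image_size, label = labels[i],
      rng_seed = draws$noise_seeds[i])
  }
  attr(phantoms, "master_seed") <- as.integer(master_seed)
  attr(phantoms, "labels") <- labels
  class(phantoms) <- "hc_cohort"
  phantoms
}

#' @export
print.hc_cohort <- function(x, ...) {
  labs <- attr(x, "labels")
  cat(sprintf("Phantom cohort: %d cases (%d benign, %d malignant), %d with PAS, master seed %d\n",
              length(x), sum(labs == "benign"), sum(labs == "malignant"),
              sum(vapply(x, function(p) p$has_pas, logical(1))),
              attr(x, "master_seed")))
  invisible(x)
}
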