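# Reading and writing images, masks, contours and phantom sidecars.
#
# Images are handled on a float [0, 255] scale internally; 8-bit PNG/TIFF
# files are promoted on read and rescaled on write.

#' Read a grayscale image
#'
#' Reads a PNG (or TIFF, if the tiff package is installed) image and
#' returns it as a float matrix on the 0-255 scale; color images are
#' averaged over channels.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix (rows = depth, columns = lateral).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required to read TIFF files", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  arr * 255
}

#' Write a grayscale image or mask as PNG
#'
#' @param img numeric matrix on the 0-255 scale (masks may be 0/1 and are
#'   scaled to 0/255).
#' @param path output path.
#' @export
write_gray_png <- function(img, path) {
  if (all(img %in% c(0, 1))) img <- img * 255
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Write a phantom to disk
#'
#' Writes `<id>.png` (image), `<id>_mask.png` (truth mask, 0/255) and a
#' JSON sidecar `<id>.json` recording the label, PAS flag, specs and seed.
#'
#' @param phantom an `hc_phantom`.
#' @param dir output directory (created if missing).
#' @param id case identifier used as the file stem.
#' @export
write_phantom <- function(phantom, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray_png(phantom$image, file.path(dir, paste0(id, ".png")))
  write_gray_png(phantom$truth_mask, file.path(dir, paste0(id, "_mask.png")))
  side <- list(
    id = id, label = phantom$label, has_pas = phantom$has_pas,
    rng_seed = phantom$rng_seed,
    shape = unclass(phantom$specs$shape),
    echo = unclass(phantom$specs$echo),
    pas = if (!is.null(phantom$specs$pas)) unclass(phantom$specs$pas)
  )
  jsonlite::write_json(side, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(file.path(dir, paste0(id, ".png")))
}

#' Write a contour as CSV
#'
#' Columns: `index`, `x`, `y` (1-based pixel coordinates; x = column,
#' y = row with depth increasing downward).
#'
#' @param contour an `hc_contour` or `hc_half_contour` (the arc is written).
#' @param path output CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  pts <- if (inherits(contour, "hc_half_contour")) contour$arc else contour$points
  df <- data.frame(index = seq_len(nrow(pts)), x = pts[, "x"], y = pts[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a contour from CSV
#'
#' Inverse of [write_contour_csv()]; the points are assumed to be an
#' ordered closed boundary.
#'
#' @param path CSV with columns `x` and `y`.
#' @return An `hc_contour`.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- list(points = cbind(x = as.integer(df$x), y = as.integer(df$y)),
              closed = TRUE)
  class(out) <- "hc_contour"
  out
}
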