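# CIELAB colour representation and the Euclidean colour metrics every later
# stage (clustering, identifier selection, range rules) is defined on.

# sRGB (IEC 61966-2-1) linear-RGB -> XYZ matrix, D65 white, 2 degree observer.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.XYZ_TO_SRGB <- solve(.SRGB_TO_XYZ)

# D65 reference white in XYZ (Y normalised to 1).
.D65_WHITE <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Construct a CIELAB image
#'
#' A `lab_image` is the working representation of a segmented tongue photo:
#' an `H x W x 3` array of CIELAB values (`L*` in `[0, 100]`, `a*`/`b*`
#' unbounded) plus a logical foreground mask. Pixels that were exact black
#' `(0, 0, 0)` in RGB are non-tongue background by convention: they carry Lab
#' `(0, 0, 0)` and `mask = FALSE`.
#'
#' @param lab numeric `H x W x 3` array of Lab values.
#' @param mask logical `H x W` matrix; `TRUE` marks tongue (foreground)
#'   pixels.
#' @return An object of class `lab_image` with elements `lab` and `mask`.
#' @export
lab_image <- function(lab, mask) {
  stopifnot(is.array(lab), length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  if (!is.matrix(mask) || !identical(dim(mask), dim(lab)[1:2])) {
    stop("`mask` must be a logical matrix with the image's height and width")
  }
  structure(list(lab = lab, mask = mask), class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x$lab)
  cat(sprintf("<lab_image> %d x %d pixels, %d foreground (%.1f%%)\n",
              d[1], d[2], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# Shared sRGB -> Lab core on an n x 3 matrix of 8-bit channel values.
.srgb_matrix_to_lab <- function(m) {
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.SRGB_TO_XYZ)
  t_ <- sweep(xyz, 2, .D65_WHITE, "/")
  delta <- 6 / 29
  f <- ifelse(t_ > delta^3, t_^(1 / 3), t_ / (3 * delta^2) + 4 / 29)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

# Lab -> sRGB inverse used by the synthetic generator; returns 8-bit values
# clipped to the gamut.
.lab_matrix_to_srgb <- function(lab) {
  delta <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f > delta, f^3, 3 * delta^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx) * .D65_WHITE[1],
               finv(fy) * .D65_WHITE[2],
               finv(fz) * .D65_WHITE[3])
  lin <- xyz %*% t(.XYZ_TO_SRGB)
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  round(v * 255)
}

#' Convert a 24-bit RGB image to CIELAB
#'
#' Standard sRGB companding and D65/2-degree CIELAB. Exact black `(0, 0, 0)`
#' is the reserved background colour of a segmented tongue image: such pixels
#' are forced to Lab `(0, 0, 0)` (rather than run through the converter) and
#' excluded from the foreground mask, so that distances "from black" are
#' measured from the same origin in both spaces.
#'
#' @param rgb numeric `H x W x 3` array with channel values in `[0, 255]`.
#' @return A [lab_image].
#' @examples
#' px <- array(c(200, 80, 80), dim = c(1, 1, 3))
#' rgb_to_lab(px)$lab
#' @export
rgb_to_lab <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("`rgb` must be an H x W x 3 array (24-bit RGB)")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) {
    stop("RGB channel values must be finite and in [0, 255]")
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  m <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  fg <- rowSums(m != 0) > 0
  lab <- matrix(0, nrow = h * w, ncol = 3)
  if (any(fg)) lab[fg, ] <- .srgb_matrix_to_lab(m[fg, , drop = FALSE])
  lab_image(array(lab, dim = c(h, w, 3)), matrix(fg, nrow = h, ncol = w))
}

#' Convert CIELAB colours back to 24-bit sRGB
#'
#' Inverse of the conversion in [rgb_to_lab()]; out-of-gamut colours are
#' clipped. Used mainly by the synthetic generator, which draws colours in
#' Lab and emits 8-bit RGB images.
#'
#' @param lab numeric matrix with columns `L`, `a`, `b` (one row per colour).
#' @return Integer matrix of sRGB channel values in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  lab <- rbind(lab)
  .lab_matrix_to_srgb(lab)
}

#' Euclidean colour distance in CIELAB
#'
#' The plain Euclidean metric `sqrt((L2-L1)^2 + (a2-a1)^2 + (b2-b1)^2)` that
#' the whole method is built on; in particular the "colour distance from the
#' black pixel (0, 0, 0)" identifier measures every cluster against the Lab
#' origin with this function.
#'
#' @param p,q numeric length-3 Lab vectors, or matrices with 3 columns
#'   (rowwise distances; one of the two may be a single colour).
#' @return Non-negative distance(s).
#' @examples
#' color_distance(c(0, 0, 0), c(0, 3, 4)) # 5
#' @export
color_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  stopifnot(ncol(p) == 3L, ncol(q) == 3L, nrow(p) == nrow(q))
  d <- sqrt((q[, 1] - p[, 1])^2 + (q[, 2] - p[, 2])^2 + (q[, 3] - p[, 3])^2)
  unname(d)
}

#' Distance of a pixel from a cluster centroid
#'
#' The metric used inside k-means to assign pixels to the nearest centroid
#' `(C1*, C2*, C3*)`. It is the same Euclidean metric as [color_distance()],
#' applied to a centroid point; the two functions are kept distinct because
#' they play distinct roles (cluster assignment versus identifier scoring).
#'
#' @param p numeric Lab vector or 3-column matrix of pixels.
#' @param centroid numeric length-3 Lab centroid.
#' @return Non-negative distance(s).
#' @export
centroid_distance <- function(p, centroid) {
  color_distance(p, centroid)
}

#' Read a segmented tongue image from disk
#'
#' Reads an 8-bit-per-channel PNG or TIFF image. The file must follow the
#' segmentation convention: non-tongue pixels are exact black `(0, 0, 0)`.
#' An alpha channel is accepted only if fully opaque (it is dropped).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return Numeric `H x W x 3` array of channel values in `[0, 255]`.
#' @export
read_tongue_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 2L) stop("greyscale image: 3-channel RGB required")
  if (dim(img)[3] == 4L) {
    if (any(img[, , 4] < 1)) stop("image has a non-opaque alpha channel")
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] != 3L) stop("3-channel RGB image required")
  round(img * 255)
}

#' Write an RGB image to disk
#'
#' @param rgb numeric `H x W x 3` array of channel values in `[0, 255]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_tongue_image <- function(rgb, path) {
  ext <- tolower(tools::file_ext(path))
  img <- rgb / 255
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
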