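# Synthetic tongue-image generator. Emulates segmented, coating-removed
# tongue photographs: an elliptical tongue on an exact-black background,
# with class-conditional CIELAB colour structure in three sub-regions —
# body, a more chromatic accent band over the tip and bilateral edges, and
# a darker transitional rim — so that a k = 4 clustering has genuine
# structure to find. Ground-truth masks are kept for every region.

#' Class labels of the tongue colour taxonomy
#' @export
TONGUE_CLASSES <- c("light_red", "red", "deep_red")

#' Generator parameters for synthetic tongue images
#'
#' Defaults define the reference synthetic corpus used throughout the test
#' suite: 256 x 256 images; class-conditional body colours anchored at the
#' centres of the red and light-red colour-range boxes — red `(50, 35, 8)`,
#' light red `(62, 25, 17)` — and a deep red body `(35, 20, 2)` that is
#' darker and less chromatic, i.e. nearer Lab black; an accent band shifted
#' `+4` in `a*` (and `+1` in `b*`) over tip and edges; a transitional rim
#' shifted towards black; independent Gaussian noise of sd 2 Lab units per
#' channel.
#'
#' @param width,height image size in pixels.
#' @param centre_jitter maximal uniform offset of the ellipse centre from
#'   the image centre, in pixels.
#' @param semi_x,semi_y ranges (length-2) of the ellipse semi-axes in
#'   pixels (x = width direction, y = height).
#' @param class_means named list of length-3 Lab body means, one per class.
#' @param accent_shift Lab offset of the tip/edge accent band from the body.
#' @param transition_shift Lab offset of the transitional rim from the body.
#' @param noise_sd per-channel Gaussian noise sd, in Lab units.
#' @param mixture class mixture weights (normalised internally).
#' @param rim_r normalised elliptical radius where the transitional rim
#'   starts.
#' @param edge_x,tip_y normalised coordinates delimiting the accent band:
#'   pixels with |x| beyond `edge_x` (bilateral edges) or y below the centre
#'   beyond `tip_y` (tip) belong to it.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(width = 256L, height = 256L,
                             centre_jitter = 5,
                             semi_x = c(70, 86), semi_y = c(95, 115),
                             class_means = list(
                               light_red = c(62, 25, 17),
                               red = c(50, 35, 8),
                               deep_red = c(35, 20, 2)
                             ),
                             accent_shift = c(0, 4, 1),
                             transition_shift = c(-10, -5, -2),
                             noise_sd = 2,
                             mixture = c(light_red = 1, red = 1, deep_red = 1) / 3,
                             rim_r = 0.88, edge_x = 0.60, tip_y = 0.50) {
  stopifnot(noise_sd >= 0, all(semi_x > 0), all(semi_y > 0),
            setequal(names(class_means), TONGUE_CLASSES),
            all(mixture >= 0), sum(mixture) > 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    centre_jitter = centre_jitter, semi_x = semi_x, semi_y = semi_y,
    class_means = class_means, accent_shift = accent_shift,
    transition_shift = transition_shift, noise_sd = noise_sd,
    mixture = mixture / sum(mixture), rim_r = rim_r,
    edge_x = edge_x, tip_y = tip_y
  ), class = "generator_params")
}

#' Generate one synthetic tongue image
#'
#' Draws the ellipse geometry and per-pixel colours from the class
#' distribution in Lab, converts to 24-bit sRGB and quantises (so up to one
#' RGB unit of rounding enters after the noise). The background is exact
#' RGB `(0, 0, 0)`; any foreground pixel that would quantise to exact black
#' is nudged to `(1, 1, 1)` to preserve the mask convention.
#'
#' @param class one of `TONGUE_CLASSES`.
#' @param params a [generator_params()] object.
#' @param seed integer; the image is a deterministic function of
#'   `(class, params, seed)`.
#' @return Object of class `synthetic_image`: `rgb` (`H x W x 3` array,
#'   values 0–255), `label`, `seed` and `masks` (logical matrices
#'   `background`, `body`, `accent`, `transitional` partitioning the image).
#' @export
make_tongue_image <- function(class, params = generator_params(), seed = 0L) {
  if (!class %in% TONGUE_CLASSES) {
    stop("invalid class: ", class, " (use one of ",
         paste(TONGUE_CLASSES, collapse = ", "), ")")
  }
  p <- params
  withr::with_seed(seed, {
    cx <- p$width / 2 + stats::runif(1, -p$centre_jitter, p$centre_jitter)
    cy <- p$height / 2 + stats::runif(1, -p$centre_jitter, p$centre_jitter)
    sx <- stats::runif(1, p$semi_x[1], p$semi_x[2])
    sy <- stats::runif(1, p$semi_y[1], p$semi_y[2])

    u <- outer(rep(1, p$height), (seq_len(p$width) - cx) / sx)   # x, width
    v <- outer((seq_len(p$height) - cy) / sy, rep(1, p$width))   # y, height
    r2 <- u^2 + v^2
    fg <- r2 <= 1
    transitional <- fg & r2 > p$rim_r^2
    accent <- fg & !transitional & (abs(u) > p$edge_x | v > p$tip_y)
    body <- fg & !transitional & !accent

    base <- p$class_means[[class]]
    n_fg <- sum(fg)
    lab <- matrix(0, p$height * p$width, 3)
    mean_mat <- matrix(base, n_fg, 3, byrow = TRUE)
    acc_idx <- accent[fg]; tr_idx <- transitional[fg]
    mean_mat[acc_idx, ] <- sweep(mean_mat[acc_idx, , drop = FALSE], 2,
                                 p$accent_shift, "+")
    mean_mat[tr_idx, ] <- sweep(mean_mat[tr_idx, , drop = FALSE], 2,
                                p$transition_shift, "+")
    noise <- matrix(stats::rnorm(3 * n_fg, sd = p$noise_sd), n_fg, 3)
    lab[fg, ] <- mean_mat + noise
  })

  rgb_fg <- .lab_matrix_to_srgb(lab[fg, , drop = FALSE])
  # foreground must never collide with the reserved background colour
  zero <- rowSums(rgb_fg != 0) == 0
  rgb_fg[zero, ] <- 1
  rgb <- matrix(0, p$height * p$width, 3)
  rgb[fg, ] <- rgb_fg
  structure(list(
    rgb = array(rgb, dim = c(p$height, p$width, 3)),
    label = class, seed = seed,
    masks = list(background = !fg, body = body, accent = accent,
                 transitional = transitional)
  ), class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<synthetic_image> %s, %d x %d, %.1f%% tongue\n",
              x$label, d[1], d[2], 100 * mean(!x$masks$background)))
  invisible(x)
}

# Largest-remainder apportionment of n among mixture weights.
.largest_remainder <- function(n, weights) {
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a labelled synthetic corpus
#'
#' Class counts follow the mixture by largest-remainder rounding; per-image
#' seeds are derived deterministically from the corpus seed, so the same
#' `(n, params, seed)` always regenerates the identical corpus.
#'
#' @param n number of images (at least the number of classes with nonzero
#'   mixture weight).
#' @param params a [generator_params()] object.
#' @param seed corpus seed.
#' @param dir optional directory: when given, images (and ground-truth
#'   masks) are written as PNG plus a `manifest.csv` of
#'   `(path, label, seed)`.
#' @return List of class `tongue_corpus`: `images` (list of
#'   `synthetic_image`), `manifest` (data frame `image_id, label, seed`,
#'   plus `path` when written), `params`, `seed`.
#' @export
make_corpus <- function(n, params = generator_params(), seed = 0L,
                        dir = NULL) {
  active <- sum(params$mixture > 0)
  if (n < active) stop("n must be at least the number of active classes")
  counts <- .largest_remainder(n, params$mixture)
  labels <- rep(names(params$mixture), counts)
  image_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max, n))
  images <- lapply(seq_len(n), function(i) {
    make_tongue_image(labels[i], params, image_seeds[i])
  })
  manifest <- data.frame(
    image_id = sprintf("img%04d", seq_len(n)),
    label = labels, seed = image_seeds,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$image_id, ".png"))
    for (i in seq_len(n)) {
      write_tongue_image(images[[i]]$rgb, manifest$path[i])
      mask_rgb <- array(0, dim = dim(images[[i]]$rgb))
      # region masks encoded in the red channel: body 85, accent 170, rim 255
      m <- images[[i]]$masks
      mask_rgb[, , 1] <- 85 * m$body + 170 * m$accent + 255 * m$transitional
      write_tongue_image(mask_rgb,
                         file.path(dir, paste0(manifest$image_id[i], "_mask.png")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(images = images, manifest = manifest, params = params,
                 seed = seed), class = "tongue_corpus")
}

#' @export
print.tongue_corpus <- function(x, ...) {
  cat(sprintf("<tongue_corpus> %d images (seed %d): %s\n",
              nrow(x$manifest), x$seed,
              paste(sprintf("%s=%d", names(table(x$manifest$label)),
                            table(x$manifest$label)), collapse = ", ")))
  invisible(x)
}
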