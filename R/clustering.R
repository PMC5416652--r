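# k-means partition of a tongue image in CIELAB space. With k = 4 the
# clusters correspond to the image background (black), the deep red region,
# the red/light-red region and a transitional region; the background cluster
# is recognised afterwards as the one whose centroid lies nearest the Lab
# origin.

# Pixel matrix (n x 3) from a lab_image or a plain matrix input.
.pixel_matrix <- function(x) {
  if (inherits(x, "lab_image")) {
    cbind(as.vector(x$lab[, , 1]), as.vector(x$lab[, , 2]), as.vector(x$lab[, , 3]))
  } else {
    m <- rbind(x)
    stopifnot(ncol(m) == 3L)
    m
  }
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the nearest chosen centre.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, 3)
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# One Lloyd run from given centres. Ties between equidistant centroids go to
# the lowest cluster id; a cluster emptied during iteration is re-seeded at
# the pixel currently farthest from its assigned centroid.
.lloyd <- function(X, centers, max_iter, tol) {
  n <- nrow(X); k <- nrow(centers)
  x2 <- rowSums(X^2)
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- x2 + matrix(rowSums(centers^2), n, k, byrow = TRUE) - 2 * X %*% t(centers)
    assign <- max.col(-D, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      member <- assign == j
      if (any(member)) {
        new_centers[j, ] <- colMeans(X[member, , drop = FALSE])
      } else {
        d_own <- D[cbind(seq_len(n), assign)]
        far <- which.max(d_own)
        new_centers[j, ] <- X[far, ]
        assign[far] <- j
      }
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  D <- x2 + matrix(rowSums(centers^2), n, k, byrow = TRUE) - 2 * X %*% t(centers)
  assign <- max.col(-D, ties.method = "first")
  inertia <- sum(pmax(D[cbind(seq_len(n), assign)], 0))
  list(centers = centers, assign = assign, inertia = inertia, iter = it)
}

#' k-means clustering of an image in CIELAB space
#'
#' Lloyd-style k-means under the Euclidean Lab metric, with k-means++
#' seeding and `n_init` restarts (the restart with minimal inertia wins).
#' Deterministic for a fixed `seed`: restarts consume one common seeded
#' random stream, so increasing `n_init` can only improve (never worsen)
#' the returned inertia.
#'
#' By default every pixel, including the black background, is clustered and
#' the background cluster is identified afterwards ([identify_background()]).
#' With `cluster_background = FALSE` only foreground pixels are clustered
#' (into `k - 1` clusters) and the masked-out pixels are returned as a
#' background cluster with centroid `(0, 0, 0)`.
#'
#' @param x a [lab_image] or an `n x 3` Lab matrix.
#' @param k number of clusters (default 4: background, deep red,
#'   red/light-red, transitional).
#' @param seed integer seed controlling initialisation.
#' @param n_init number of k-means++ restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol convergence threshold on the maximum centroid coordinate
#'   movement.
#' @param cluster_background cluster all pixels (`TRUE`, default) or
#'   foreground only.
#' @return An object of class `cluster_set`: `assignment` (per-pixel cluster
#'   id, shaped like the image when `x` is a [lab_image]), `centroids` and
#'   `means` (`k x 3`), `sizes`, `inertia`, `background_id`, `k`.
#' @export
kmeans_lab <- function(x, k = 4L, seed = 0L, n_init = 5L, max_iter = 300L,
                       tol = 1e-4, cluster_background = TRUE) {
  if (k < 2L) stop("k must be at least 2")
  X <- .pixel_matrix(x)
  img_dim <- if (inherits(x, "lab_image")) dim(x$lab)[1:2] else NULL

  bg_fixed <- NULL
  if (!cluster_background) {
    if (!inherits(x, "lab_image")) {
      stop("cluster_background = FALSE requires a lab_image input")
    }
    bg_fixed <- !as.vector(x$mask)
    X_fit <- X[!bg_fixed, , drop = FALSE]
    k_fit <- k - 1L
  } else {
    X_fit <- X
    k_fit <- k
  }
  if (nrow(unique(X_fit)) < k_fit) {
    stop("degenerate input: fewer distinct pixel values than clusters")
  }

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_init)) {
      run <- .lloyd(X_fit, .kmeanspp_init(X_fit, k_fit), max_iter, tol)
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })

  if (is.null(bg_fixed)) {
    assign <- best$assign
    centroids <- best$centers
  } else {
    # foreground clusters keep ids 1..k-1; the fixed background becomes id k
    assign <- integer(nrow(X))
    assign[!bg_fixed] <- best$assign
    assign[bg_fixed] <- k
    centroids <- rbind(best$centers, c(0, 0, 0))
  }

  k_out <- nrow(centroids)
  means <- matrix(NA_real_, k_out, 3)
  sizes <- integer(k_out)
  for (j in seq_len(k_out)) {
    member <- assign == j
    sizes[j] <- sum(member)
    if (sizes[j] > 0) means[j, ] <- colMeans(X[member, , drop = FALSE])
  }
  colnames(centroids) <- colnames(means) <- c("L", "a", "b")

  if (!is.null(img_dim)) assign <- matrix(assign, img_dim[1], img_dim[2])

  cs <- structure(list(
    assignment = assign, centroids = centroids, means = means,
    sizes = sizes, inertia = best$inertia, k = k_out,
    background_id = NA_integer_
  ), class = "cluster_set")
  cs$background_id <- identify_background(cs)
  cs
}

#' Identify the background cluster
#'
#' The background of a segmented tongue image is exact black, so its cluster
#' is the one whose centroid lies nearest the Lab origin `(0, 0, 0)`; ties
#' are broken by the lowest cluster id.
#'
#' @param cs a `cluster_set`.
#' @return Integer cluster id.
#' @export
identify_background <- function(cs) {
  d <- centroid_distance(cs$centroids, c(0, 0, 0))
  which.min(d) # which.min returns the first (lowest-id) minimum
}

#' Logical membership mask of one cluster
#'
#' @param cs a `cluster_set`.
#' @param id cluster id.
#' @return Logical vector or matrix, shaped like the assignment.
#' @export
cluster_mask <- function(cs, id) {
  cs$assignment == id
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> k = %d, inertia = %.2f, background id = %d\n",
              x$k, x$inertia, x$background_id))
  df <- data.frame(id = seq_len(x$k), round(x$centroids, 2),
                   n_pixels = x$sizes)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-cluster summary table
#'
#' One row per cluster: id, centroid, mean member colour and pixel count.
#' Written as CSV when `path` is given, so clustering outcomes can be
#' inspected or archived outside R.
#'
#' @param cs a `cluster_set`.
#' @param path optional CSV output path.
#' @return A data frame, invisibly when `path` is given.
#' @export
cluster_summary <- function(cs, path = NULL) {
  df <- data.frame(
    id = seq_len(cs$k),
    centroid_L = cs$centroids[, 1], centroid_a = cs$centroids[, 2],
    centroid_b = cs$centroids[, 3],
    mean_L = cs$means[, 1], mean_a = cs$means[, 2], mean_b = cs$means[, 3],
    n_pixels = cs$sizes,
    is_background = seq_len(cs$k) == cs$background_id
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a cluster map as a colour-coded PNG
#'
#' Each cluster is painted with its mean colour (background cluster in
#' black), giving the familiar posterised view of the k-means result.
#'
#' @param cs a `cluster_set` with an image-shaped assignment.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_cluster_image <- function(cs, path) {
  if (!is.matrix(cs$assignment)) {
    stop("write_cluster_image needs an image-shaped cluster set")
  }
  palette <- .lab_matrix_to_srgb(cs$means)
  palette[cs$background_id, ] <- 0
  rgb <- array(0, dim = c(nrow(cs$assignment), ncol(cs$assignment), 3))
  for (ch in 1:3) {
    rgb[, , ch] <- matrix(palette[cs$assignment, ch], nrow(cs$assignment))
  }
  write_tongue_image(rgb, path)
}
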