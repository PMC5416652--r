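# Clustering identifiers: the two informative clusters of a tongue image.
# The maximum-colour-distance identifier (largest centroid distance from Lab
# black) names the red/light-red cluster; the maximum-pixels'-coverage-area
# identifier (largest bounding box over member pixels) names the deep red
# cluster, which spreads sparsely across tip, bilateral edges and centre.

.nonbackground_ids <- function(cs) {
  ids <- setdiff(seq_len(cs$k), cs$background_id)
  if (length(ids) < 2L) {
    stop("degenerate cluster set: need at least 2 non-background clusters")
  }
  ids
}

#' Maximum colour distance identifier
#'
#' Among non-background clusters, selects the one whose centroid has the
#' largest Euclidean distance from Lab black `(0, 0, 0)`. Chromatically
#' intense (high `a*`, `b*`) red/light-red pixels lie farthest from black,
#' so this identifier picks out the red/light-red cluster; ties are broken
#' by the lowest cluster id.
#'
#' @param cs a `cluster_set`.
#' @return List with `id` and `distance` (the winning centroid's distance
#'   from black).
#' @export
select_max_distance_cluster <- function(cs) {
  ids <- .nonbackground_ids(cs)
  d <- centroid_distance(cs$centroids[ids, , drop = FALSE], c(0, 0, 0))
  win <- ids[which.max(d)]
  list(id = win, distance = max(d))
}

#' Coverage area of a cluster
#'
#' The coverage area `A_np = w' x h'` of a cluster is the area of the tight
#' axis-aligned bounding box containing all of its member (nonzero) pixels,
#' with `w' <= w` and `h' <= h` the image width and height.
#'
#' @param cs a `cluster_set` whose assignment is image-shaped.
#' @param id cluster id.
#' @return List of class `coverage_box`: `w_prime`, `h_prime`, `area`,
#'   `n_nonzero`.
#' @export
coverage_area <- function(cs, id) {
  mask <- cluster_mask(cs, id)
  if (!is.matrix(mask)) stop("coverage_area needs an image-shaped cluster set")
  .coverage_box(mask)
}

.coverage_box <- function(mask) {
  n <- sum(mask)
  if (n == 0L) stop("degenerate: cluster has no member pixels")
  rows <- range(row(mask)[mask])
  cols <- range(col(mask)[mask])
  w_prime <- cols[2] - cols[1] + 1L
  h_prime <- rows[2] - rows[1] + 1L
  structure(list(w_prime = w_prime, h_prime = h_prime,
                 area = w_prime * h_prime, n_nonzero = n),
            class = "coverage_box")
}

#' Maximum pixels' coverage area identifier
#'
#' Among non-background clusters, selects the one with the largest coverage
#' area (bounding-box area by default; member pixel count with
#' `metric = "npixels"`). Ties are broken by the lowest cluster id. If the
#' winner coincides with the maximum-colour-distance cluster (pass its id as
#' `exclude`), the runner-up is returned instead and flagged, so the two
#' identifiers always name distinct clusters.
#'
#' @param cs a `cluster_set` with an image-shaped assignment.
#' @param metric `"bbox"` (default) for bounding-box area, `"npixels"` for
#'   member count.
#' @param exclude optional cluster id to demote (the max-distance winner).
#' @return List with `id`, `coverage` (a `coverage_box`) and `collision`
#'   (`TRUE` when the runner-up rule fired).
#' @export
select_max_coverage_cluster <- function(cs, metric = c("bbox", "npixels"),
                                        exclude = NULL) {
  metric <- match.arg(metric)
  ids <- .nonbackground_ids(cs)
  boxes <- lapply(ids, function(i) coverage_area(cs, i))
  score <- vapply(boxes, function(b) {
    as.numeric(if (metric == "bbox") b$area else b$n_nonzero)
  }, numeric(1))
  ord <- order(-score, ids) # max score first, lowest id on ties
  pick <- 1L
  collision <- FALSE
  if (!is.null(exclude) && ids[ord[1L]] == exclude) {
    if (length(ids) < 2L) stop("no runner-up cluster available")
    pick <- 2L
    collision <- TRUE
  }
  list(id = ids[ord[pick]], coverage = boxes[[ord[pick]]],
       collision = collision)
}

#' Select both clustering identifiers of an image
#'
#' Runs [select_max_distance_cluster()] and [select_max_coverage_cluster()]
#' (with the collision rule) on one cluster set.
#'
#' @param cs a `cluster_set` with an image-shaped assignment.
#' @param coverage_metric passed to [select_max_coverage_cluster()].
#' @return List of class `identifier_selection`: `max_distance_id`,
#'   `max_coverage_id`, `distance_value`, `coverage`, `collision`.
#' @export
select_identifiers <- function(cs, coverage_metric = "bbox") {
  dist_sel <- select_max_distance_cluster(cs)
  cov_sel <- select_max_coverage_cluster(cs, metric = coverage_metric,
                                         exclude = dist_sel$id)
  structure(list(
    max_distance_id = dist_sel$id,
    max_coverage_id = cov_sel$id,
    distance_value = dist_sel$distance,
    coverage = cov_sel$coverage,
    collision = cov_sel$collision
  ), class = "identifier_selection")
}

#' Feature vector(s) from the selected identifier clusters
#'
#' In `"image"` mode (the default, one prediction per image) the feature
#' vector is the 6-dimensional concatenation of the mean Lab colours of the
#' max-distance cluster and the max-coverage cluster, in that order. In
#' `"instance"` mode each identifier cluster contributes its own 3-vector
#' row, so a corpus of N images yields 2N training instances.
#'
#' @param sel an `identifier_selection`.
#' @param cs the `cluster_set` it was derived from.
#' @param mode `"image"` or `"instance"`.
#' @return `"image"`: named numeric length-6 vector (`dist_L`, `dist_a`,
#'   `dist_b`, `cov_L`, `cov_a`, `cov_b`). `"instance"`: a `2 x 3` matrix
#'   with rows `distance` and `coverage`.
#' @export
build_feature_vector <- function(sel, cs, mode = c("image", "instance")) {
  mode <- match.arg(mode)
  mdist <- cs$means[sel$max_distance_id, ]
  mcov <- cs$means[sel$max_coverage_id, ]
  if (mode == "image") {
    stats::setNames(c(mdist, mcov),
                    c("dist_L", "dist_a", "dist_b", "cov_L", "cov_a", "cov_b"))
  } else {
    m <- rbind(distance = mdist, coverage = mcov)
    colnames(m) <- c("L", "a", "b")
    m
  }
}

#' Write a feature matrix as CSV
#'
#' Image mode: columns `image_id, label, dist_L..cov_b`. Instance mode:
#' columns `image_id, identifier, label, L, a, b` with two rows per image.
#'
#' @param features matrix of feature rows (image mode) or a list of
#'   instance-mode matrices.
#' @param labels class label per image.
#' @param image_ids id per image.
#' @param path CSV output path.
#' @return The data frame written, invisibly.
#' @export
write_feature_csv <- function(features, labels, image_ids, path) {
  if (is.list(features)) {
    rows <- do.call(rbind, lapply(seq_along(features), function(i) {
      data.frame(image_id = image_ids[i],
                 identifier = rownames(features[[i]]),
                 label = labels[i],
                 L = features[[i]][, 1], a = features[[i]][, 2],
                 b = features[[i]][, 3])
    }))
  } else {
    rows <- data.frame(image_id = image_ids, label = labels, features)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
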