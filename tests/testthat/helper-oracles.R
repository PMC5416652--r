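# Independent oracle implementations used to cross-check the package.
# Each is written as a direct, unoptimised transcription of the underlying
# formula, deliberately sharing no code with the implementation under test.

# Textbook sRGB -> XYZ -> CIELAB for a single 8-bit RGB triple (D65, 2 deg).
oracle_srgb_to_lab <- function(rgb) {
  gamma_expand <- function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  r <- gamma_expand(rgb[1] / 255)
  g <- gamma_expand(rgb[2] / 255)
  b <- gamma_expand(rgb[3] / 255)
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  fwd <- function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }
  fx <- fwd(X / 0.95047); fy <- fwd(Y / 1); fz <- fwd(Z / 1.08883)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

# Direct scalar evaluation of the Euclidean Lab distance.
oracle_distance <- function(p, q) {
  sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2)
}

# Exhaustive global 2-means on a tiny point set: enumerate every bipartition,
# score by within-cluster sum of squared distances to the cluster mean.
oracle_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- list(inertia = Inf)
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; skip empty
    grp <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(grp)) < 2L) next
    inertia <- 0
    for (g in 1:2) {
      pts <- X[grp == g, , drop = FALSE]
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    if (inertia < best$inertia) best <- list(inertia = inertia, grp = grp)
  }
  best
}

# Bounding box of a logical mask by explicit row/column scanning.
oracle_bbox <- function(mask) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        rmin <- min(rmin, i); rmax <- max(rmax, i)
        cmin <- min(cmin, j); cmax <- max(cmax, j)
      }
    }
  }
  list(w_prime = cmax - cmin + 1, h_prime = rmax - rmin + 1,
       area = (cmax - cmin + 1) * (rmax - rmin + 1))
}

# Accuracy rate by an explicit counting loop.
oracle_accuracy_pct <- function(predicted, truth) {
  n_ok <- 0L
  for (i in seq_along(truth)) if (predicted[i] == truth[i]) n_ok <- n_ok + 1L
  100 * n_ok / length(truth)
}

# Hard-margin maximum-margin separator of a small linearly separable 2-D set,
# by enumerating candidate support sets: class-straddling pairs (hyperplane
# perpendicular to the segment, through its midpoint) and triples of two
# same-class points plus one opposite point (hyperplane parallel to the
# same-class segment, halfway to the opposite point). Returns (w, b) scaled
# so the support points satisfy y (w.x - b) = 1.
oracle_max_margin <- function(X, y) {
  n <- nrow(X)
  feasible <- function(w, b) all(y * (X %*% w - b) >= 1 - 1e-9)
  best <- NULL
  consider <- function(w_dir, p_pos, p_neg) {
    # w_dir points towards the +1 class; margin width = gap along w_dir
    gap <- sum(w_dir * (p_pos - p_neg)) / sqrt(sum(w_dir^2))
    if (gap <= 0) return()
    w <- 2 * w_dir / (sqrt(sum(w_dir^2)) * gap)
    b <- (sum(w * p_pos) + sum(w * p_neg)) / 2
    if (feasible(w, b) && (is.null(best) || gap > best$gap + 1e-12)) {
      best <<- list(w = w, b = b, gap = gap)
    }
  }
  pos <- which(y == 1); neg <- which(y == -1)
  for (i in pos) for (j in neg) {
    consider(X[i, ] - X[j, ], X[i, ], X[j, ])
  }
  same_class_triples <- function(idx_same, idx_other, sign_same) {
    if (length(idx_same) < 2) return()
    for (a in idx_same) for (b_ in idx_same) for (q in idx_other) {
      if (a >= b_) next
      u <- X[b_, ] - X[a, ]
      u <- u / sqrt(sum(u^2))
      d <- X[q, ] - X[a, ]
      w_dir <- d - sum(d * u) * u # perpendicular from the segment to q
      if (sqrt(sum(w_dir^2)) < 1e-12) next
      if (sign_same == 1) {
        consider(-w_dir, X[a, ], X[q, ])
      } else {
        consider(w_dir, X[q, ], X[a, ])
      }
    }
  }
  same_class_triples(pos, neg, 1)
  same_class_triples(neg, pos, -1)
  best
}

# ---- shared fixtures --------------------------------------------------------

# Small-image generator parameters used across tests: same colour model as
# the defaults, smaller canvas so k-means stays fast.
small_params <- function(...) {
  generator_params(width = 96L, height = 96L, centre_jitter = 3,
                   semi_x = c(26, 32), semi_y = c(36, 43), ...)
}

# A hand-built cluster set with an image-shaped assignment, for identifier
# tests that need full control over centroids and masks.
toy_cluster_set <- function(centroids, assignment) {
  k <- nrow(centroids)
  colnames(centroids) <- c("L", "a", "b")
  means <- centroids
  sizes <- vapply(seq_len(k), function(j) sum(assignment == j), integer(1))
  cs <- structure(list(assignment = assignment, centroids = centroids,
                       means = means, sizes = sizes, inertia = 0, k = k,
                       background_id = NA_integer_), class = "cluster_set")
  cs$background_id <- identify_background(cs)
  cs
}
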