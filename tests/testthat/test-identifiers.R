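# assignment grid used when the toy cluster sets need an image shape
.toy_assign <- function(ids, h = 6, w = 6) {
  matrix(rep_len(ids, h * w), h, w)
}

test_that("max-distance identifier is the argmax of centroid distance from black", {
  cents <- rbind(c(0, 0, 0), c(55, 33, 8), c(35, 20, 2), c(60, 25, 17))
  cs <- toy_cluster_set(cents, .toy_assign(1:4))
  sel <- select_max_distance_cluster(cs)
  expect_identical(sel$id, 4L)
  expect_equal(sel$distance, sqrt(60^2 + 25^2 + 17^2))
})

test_that("equal non-background centroids tie to the lowest id", {
  cents <- rbind(c(0, 0, 0), c(50, 30, 10), c(50, 30, 10), c(50, 30, 10))
  cs <- toy_cluster_set(cents, .toy_assign(1:4))
  expect_identical(select_max_distance_cluster(cs)$id, 2L)
})

test_that("max-distance selection matches a brute-force scan on random cluster sets", {
  set.seed(37)
  for (rep in 1:100) {
    k <- sample(3:6, 1)
    cents <- rbind(c(0, 0, 0),
                   matrix(stats::runif(3 * (k - 1), 5, 90), ncol = 3))
    cs <- toy_cluster_set(cents, .toy_assign(1:k))
    sel <- select_max_distance_cluster(cs)
    ids <- setdiff(seq_len(k), cs$background_id)
    d <- vapply(ids, function(i) oracle_distance(cents[i, ], c(0, 0, 0)),
                numeric(1))
    expect_identical(sel$id, ids[which.max(d)])
    expect_equal(sel$distance, max(d))
  }
})

test_that("coverage box is the tight bounding box of member pixels", {
  # members at rows/cols (1,1) and (4,3) of a 5x5 grid -> w' = 3, h' = 4
  assign <- matrix(1L, 5, 5)
  assign[1, 1] <- 2L; assign[4, 3] <- 2L
  cs <- toy_cluster_set(rbind(c(0, 0, 0), c(50, 30, 10)), assign)
  box <- coverage_area(cs, 2L)
  expect_identical(box$w_prime, 3L)
  expect_identical(box$h_prime, 4L)
  expect_identical(box$area, 12L)
  expect_identical(box$n_nonzero, 2L)

  # full-image cluster saturates at w x h
  full <- toy_cluster_set(rbind(c(0, 0, 0), c(50, 30, 10)),
                          matrix(2L, 4, 7))
  expect_identical(coverage_area(full, 2L)$area, 28L)
})

test_that("coverage boxes match an independent min/max scan on random masks", {
  set.seed(43)
  for (rep in 1:100) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    assign <- matrix(1L, h, w)
    members <- sample(h * w, sample(1:(h * w - 1), 1))
    assign[members] <- 2L
    cs <- toy_cluster_set(rbind(c(0, 0, 0), c(50, 30, 10)), assign)
    box <- coverage_area(cs, 2L)
    ref <- oracle_bbox(assign == 2L)
    expect_equal(box$w_prime, ref$w_prime)
    expect_equal(box$h_prime, ref$h_prime)
    expect_equal(box$area, ref$area)
    expect_lte(box$w_prime, w)
    expect_lte(box$h_prime, h)
    expect_gte(box$area, box$n_nonzero)
  }
})

test_that("max-coverage selection prefers the spanning cluster and honours ties", {
  assign <- matrix(1L, 8, 8)
  assign[2:7, 2:7] <- 3L     # spans a 6x6 box
  assign[4:5, 4:5] <- 2L     # confined 2x2 box
  cents <- rbind(c(0, 0, 0), c(60, 30, 10), c(40, 20, 5))
  cs <- toy_cluster_set(cents, assign)
  sel <- select_max_coverage_cluster(cs)
  expect_identical(sel$id, 3L)
  expect_false(sel$collision)
})

test_that("collision with the max-distance winner demotes coverage to the runner-up", {
  assign <- matrix(1L, 8, 8)
  assign[2:7, 2:7] <- 2L
  assign[4:5, 4:5] <- 3L
  cents <- rbind(c(0, 0, 0), c(60, 30, 10), c(40, 20, 5))
  cs <- toy_cluster_set(cents, assign)
  dist_sel <- select_max_distance_cluster(cs)
  expect_identical(dist_sel$id, 2L) # also the biggest box
  sel <- select_max_coverage_cluster(cs, exclude = dist_sel$id)
  expect_identical(sel$id, 3L)
  expect_true(sel$collision)

  both <- select_identifiers(cs)
  expect_identical(both$max_distance_id, 2L)
  expect_identical(both$max_coverage_id, 3L)
  expect_true(both$collision)
})

test_that("selected identifier clusters are distinct and never the background", {
  p <- small_params()
  for (i in 1:12) {
    cls <- TONGUE_CLASSES[(i %% 3) + 1]
    img <- make_tongue_image(cls, p, seed = 200 + i)
    cs <- kmeans_lab(rgb_to_lab(img$rgb), k = 4, seed = i)
    sel <- select_identifiers(cs)
    expect_false(sel$max_distance_id == cs$background_id)
    expect_false(sel$max_coverage_id == cs$background_id)
    expect_false(sel$max_distance_id == sel$max_coverage_id)
  }
})

test_that("feature vectors concatenate the identifier cluster mean colours", {
  assign <- matrix(1L, 8, 8)
  assign[2:7, 2:7] <- 3L
  assign[4:5, 4:5] <- 2L
  cents <- rbind(c(0, 0, 0), c(60, 25, 17), c(40, 35, 5))
  cs <- toy_cluster_set(cents, assign)
  sel <- select_identifiers(cs)
  expect_identical(sel$max_distance_id, 2L)
  expect_identical(sel$max_coverage_id, 3L)

  v <- build_feature_vector(sel, cs, mode = "image")
  expect_identical(unname(v), c(60, 25, 17, 40, 35, 5))

  inst <- build_feature_vector(sel, cs, mode = "instance")
  expect_identical(dim(inst), c(2L, 3L))
  expect_identical(unname(inst["distance", ]), c(60, 25, 17))
  expect_identical(unname(inst["coverage", ]), c(40, 35, 5))
})

test_that("image-mode features equal cluster-mask means recomputed independently", {
  img <- make_tongue_image("red", small_params(), seed = 21)
  li <- rgb_to_lab(img$rgb)
  cs <- kmeans_lab(li, k = 4, seed = 3)
  sel <- select_identifiers(cs)
  v <- build_feature_vector(sel, cs)
  px <- cbind(as.vector(li$lab[, , 1]), as.vector(li$lab[, , 2]),
              as.vector(li$lab[, , 3]))
  md <- colMeans(px[as.vector(cluster_mask(cs, sel$max_distance_id)), ])
  mc <- colMeans(px[as.vector(cluster_mask(cs, sel$max_coverage_id)), ])
  expect_equal(unname(v), unname(c(md, mc)), tolerance = 1e-9)
})

test_that("instance mode yields two rows per image across a corpus", {
  p <- small_params()
  cfg <- pipeline_config(feature_mode = "instance")
  n_rows <- 0L
  for (i in 1:4) {
    img <- make_tongue_image("red", p, seed = 300 + i)
    ft <- tongue_features(img, cfg)
    n_rows <- n_rows + nrow(ft$features)
  }
  expect_identical(n_rows, 8L)
})

test_that("on deep red images the coverage cluster is less chromatic than the distance cluster", {
  p <- small_params()
  n <- 30
  ok <- vapply(seq_len(n), function(i) {
    img <- make_tongue_image("deep_red", p, seed = 400 + i)
    cs <- kmeans_lab(rgb_to_lab(img$rgb), k = 4, seed = i)
    sel <- select_identifiers(cs)
    mdist <- cs$means[sel$max_distance_id, ]
    mcov <- cs$means[sel$max_coverage_id, ]
    mcov["a"] < mdist["a"] && mcov["b"] < mdist["b"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("feature CSV export round-trips both modes", {
  path <- withr::local_tempfile(fileext = ".csv")
  X <- matrix(1:12, 2, 6,
              dimnames = list(NULL, c("dist_L", "dist_a", "dist_b",
                                      "cov_L", "cov_a", "cov_b")))
  write_feature_csv(X, c("red", "light_red"), c("a", "b"), path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$label, c("red", "light_red"))

  inst <- list(rbind(distance = c(60, 25, 17), coverage = c(40, 35, 5)))
  write_feature_csv(inst, "red", "a", path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$identifier, c("distance", "coverage"))
})
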