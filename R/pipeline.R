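# End-to-end cascade and evaluation harness. Per image: RGB -> Lab ->
# k-means (k = 4) -> identifier selection -> stage-1 SVM; a stage-1 deep red
# verdict is final, everything else is resolved by the stage-2 colour-range
# rules applied to the mean colour of the red/light-red identifier cluster.

#' Pipeline configuration
#'
#' Bundles every tunable of the cascade. `k` must be at least 3 (background
#' plus two identifier candidates).
#'
#' @param k number of k-means clusters.
#' @param seed base seed for clustering and fold assignment.
#' @param n_init,max_iter,tol k-means controls (see [kmeans_lab()]).
#' @param feature_mode `"image"` (6-dim concatenated features, one
#'   prediction per image) or `"instance"` (two 3-dim instances per image).
#' @param kernel,C stage-1 SVM kernel and soft-margin penalty.
#' @param rules stage-2 [range_rules()].
#' @param coverage_metric `"bbox"` or `"npixels"` (see
#'   [select_max_coverage_cluster()]).
#' @param cluster_background cluster all pixels including background
#'   (default) or foreground only.
#' @param stage2_color classify the mean colour of the max-distance
#'   identifier cluster (`"identifier"`, default) or of the whole tongue
#'   foreground (`"foreground"`).
#' @param raw_pixel_budget foreground pixels sampled per image for the
#'   raw-pixel baseline features.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 4L, seed = 0L, n_init = 5L, max_iter = 300L,
                            tol = 1e-4, feature_mode = "image",
                            kernel = "linear", C = 1,
                            rules = range_rules(),
                            coverage_metric = "bbox",
                            cluster_background = TRUE,
                            stage2_color = "identifier",
                            raw_pixel_budget = 500L) {
  if (k < 3L) stop("k must be at least 3 (background + 2 identifier candidates)")
  stopifnot(feature_mode %in% c("image", "instance"),
            stage2_color %in% c("identifier", "foreground"))
  .map_kernel(kernel) # validates
  structure(list(
    k = as.integer(k), seed = as.integer(seed), n_init = as.integer(n_init),
    max_iter = as.integer(max_iter), tol = tol, feature_mode = feature_mode,
    kernel = kernel, C = C, rules = rules,
    coverage_metric = coverage_metric,
    cluster_background = cluster_background, stage2_color = stage2_color,
    raw_pixel_budget = as.integer(raw_pixel_budget)
  ), class = "pipeline_config")
}

.as_lab_image <- function(image) {
  if (inherits(image, "lab_image")) return(image)
  if (inherits(image, "synthetic_image")) return(rgb_to_lab(image$rgb))
  rgb_to_lab(image)
}

#' Clustering-identifier features of one image
#'
#' Runs the per-image front end of the cascade: Lab conversion, k-means,
#' identifier selection, feature construction. Also returns the colour the
#' stage-2 rules will judge (the mean Lab colour of the max-distance
#' cluster, or the foreground mean when so configured).
#'
#' @param image RGB array, [lab_image] or `synthetic_image`.
#' @param cfg a [pipeline_config()].
#' @return List: `features` (named length-6 vector in image mode, or a
#'   `2 x 3` matrix in instance mode), `stage2_color`, `selection`,
#'   `cluster_summary`, `timing_s`.
#' @export
tongue_features <- function(image, cfg = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  lab <- .as_lab_image(image)
  t1 <- proc.time()[["elapsed"]]
  cs <- kmeans_lab(lab, k = cfg$k, seed = cfg$seed, n_init = cfg$n_init,
                   max_iter = cfg$max_iter, tol = cfg$tol,
                   cluster_background = cfg$cluster_background)
  t2 <- proc.time()[["elapsed"]]
  sel <- select_identifiers(cs, coverage_metric = cfg$coverage_metric)
  features <- build_feature_vector(sel, cs, mode = cfg$feature_mode)
  s2col <- if (cfg$stage2_color == "identifier") {
    cs$means[sel$max_distance_id, ]
  } else {
    px <- .pixel_matrix(lab)[as.vector(lab$mask), , drop = FALSE]
    colMeans(px)
  }
  t3 <- proc.time()[["elapsed"]]
  list(features = features, stage2_color = s2col, selection = sel,
       cluster_summary = cluster_summary(cs),
       timing_s = c(convert = t1 - t0, cluster = t2 - t1, identify = t3 - t2))
}

#' Final label of the cascade
#'
#' @param value `light_red`, `red` or `deep_red`.
#' @param stage which stage decided: 1 (SVM, deep red only) or 2 (range
#'   rules).
#' @param rule_path branch that fired in stage 2 (`NA` for stage-1
#'   decisions).
#' @return Object of class `final_label`.
#' @export
final_label <- function(value, stage, rule_path = NA_character_) {
  stopifnot(value %in% TONGUE_CLASSES,
            (stage == 1L) == (value == "deep_red"))
  structure(list(value = value, stage = as.integer(stage),
                 rule_path = rule_path), class = "final_label")
}

#' @export
print.final_label <- function(x, ...) {
  cat(sprintf("<final_label> %s (stage %d%s)\n", x$value, x$stage,
              if (is.na(x$rule_path)) "" else paste0(", ", x$rule_path)))
  invisible(x)
}

#' Classify one tongue image with the full cascade
#'
#' Stage 1 (SVM on identifier features) separates deep red from the
#' red/light-red group; a deep red verdict short-circuits the cascade.
#' Otherwise stage 2 applies the colour-range rules to the identifier
#' cluster colour.
#'
#' @param image RGB array, [lab_image] or `synthetic_image`.
#' @param model a trained [train_stage1()] model (image feature mode).
#' @param cfg a [pipeline_config()].
#' @param image_id identifier carried into the record.
#' @return Object of class `diagnosis_record`: `image_id`, `stage1`
#'   (stage-1 label), `final` (a [final_label()]), `features`,
#'   `stage2_color`, `timing_s`.
#' @export
classify_image <- function(image, model, cfg = pipeline_config(),
                           image_id = NA_character_) {
  if (cfg$feature_mode != "image") {
    stop("classify_image requires feature_mode = \"image\"")
  }
  ft <- tryCatch(tongue_features(image, cfg), error = function(e) {
    stop("image ", image_id, ": ", conditionMessage(e), call. = FALSE)
  })
  t0 <- proc.time()[["elapsed"]]
  s1 <- predict_stage1(model, ft$features)
  if (s1 == STAGE1_DEEP_RED) {
    fin <- final_label("deep_red", stage = 1L)
  } else {
    lab2 <- classify_range(ft$stage2_color, cfg$rules)
    fin <- final_label(as.character(lab2), stage = 2L,
                       rule_path = attr(lab2, "rule_path"))
  }
  timing <- c(ft$timing_s, classify = proc.time()[["elapsed"]] - t0)
  structure(list(image_id = image_id, stage1 = s1, final = fin,
                 features = ft$features, stage2_color = ft$stage2_color,
                 timing_s = timing), class = "diagnosis_record")
}

#' @export
print.diagnosis_record <- function(x, ...) {
  cat(sprintf("<diagnosis_record> %s: stage1 = %s, final = %s (stage %d)\n",
              x$image_id, x$stage1, x$final$value, x$final$stage))
  invisible(x)
}

# ---- corpus-level harness ---------------------------------------------------

.corpus_images <- function(corpus) {
  if (inherits(corpus, "tongue_corpus")) {
    list(images = corpus$images, labels = corpus$manifest$label,
         ids = corpus$manifest$image_id)
  } else if (is.data.frame(corpus)) {
    # manifest data frame with columns path, label
    list(images = lapply(corpus$path, read_tongue_image),
         labels = corpus$label,
         ids = if ("image_id" %in% names(corpus)) corpus$image_id
               else basename(corpus$path))
  } else {
    stop("corpus must be a tongue_corpus or a manifest data frame")
  }
}

#' Identifier features for every image of a corpus
#'
#' The expensive per-image front end (Lab conversion, k-means, identifier
#' selection), computed once; the cross-validated evaluation then operates
#' on the returned feature table.
#'
#' @param corpus a `tongue_corpus` (from [make_corpus()]) or a manifest
#'   data frame with columns `path`, `label`.
#' @param cfg a [pipeline_config()].
#' @return Object of class `corpus_features`: `X` (n x 6 feature matrix),
#'   `stage2_colors` (n x 3), `labels`, `ids`, `timing_s`.
#' @export
corpus_features <- function(corpus, cfg = pipeline_config()) {
  cc <- .corpus_images(corpus)
  n <- length(cc$images)
  X <- matrix(NA_real_, n, 6)
  s2 <- matrix(NA_real_, n, 3)
  timing <- 0
  for (i in seq_len(n)) {
    ft <- tongue_features(cc$images[[i]], cfg)
    X[i, ] <- ft$features
    s2[i, ] <- ft$stage2_color
    timing <- timing + sum(ft$timing_s)
  }
  colnames(X) <- c("dist_L", "dist_a", "dist_b", "cov_L", "cov_a", "cov_b")
  colnames(s2) <- c("L", "a", "b")
  structure(list(X = X, stage2_colors = s2, labels = cc$labels,
                 ids = cc$ids, timing_s = timing),
            class = "corpus_features")
}

# Stratified fold assignment: within each class, images are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validated evaluation of the two-stage cascade
#'
#' Stratified K-fold protocol: the stage-1 SVM is fitted on the training
#' folds only (feature standardisation included) and the full cascade is
#' applied to each held-out image. Reports the 3-class accuracy rate, the
#' stage-1 binary accuracy, the stage-2 conditional accuracy (over truly
#' red/light-red images that stage 1 passed on), support-vector counts per
#' fold and per-image wall time.
#'
#' @param feat a `corpus_features` object (or pass a corpus to
#'   [evaluate_corpus()]).
#' @param cfg a [pipeline_config()].
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @return Object of class `cascade_eval`: `overall`, `stage1`, `stage2`
#'   ([classification_accuracy()] results), `support_vectors` per fold,
#'   `records` (per-image data frame with truth, stage-1 and final labels,
#'   deciding stage and rule path), `protocol`.
#' @export
evaluate_features <- function(feat, cfg = pipeline_config(), folds = 5L,
                              seed = 0L) {
  labels <- feat$labels
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < 2L)) stop("need at least 2 images per class")
  fold_of <- stratified_folds(labels, folds, seed)
  truth1 <- stage1_label(labels)

  pred1 <- character(n)
  final <- character(n)
  stage <- integer(n)
  rule_path <- rep(NA_character_, n)
  sv <- integer(folds)

  for (f in seq_len(folds)) {
    test <- fold_of == f
    if (length(unique(truth1[!test])) < 2L) {
      stop("protocol error: a stage-1 class is absent from training fold ", f)
    }
    model <- train_stage1(feat$X[!test, , drop = FALSE], labels[!test],
                          kernel = cfg$kernel, C = cfg$C, seed = cfg$seed)
    sv[f] <- count_support_vectors(model)
    p1 <- predict_stage1(model, feat$X[test, , drop = FALSE])
    pred1[test] <- p1
    ti <- which(test)
    deep <- p1 == STAGE1_DEEP_RED
    final[ti[deep]] <- "deep_red"
    stage[ti[deep]] <- 1L
    if (any(!deep)) {
      lab2 <- classify_range(feat$stage2_colors[ti[!deep], , drop = FALSE],
                             cfg$rules)
      final[ti[!deep]] <- as.character(lab2)
      stage[ti[!deep]] <- 2L
      rule_path[ti[!deep]] <- attr(lab2, "rule_path")
    }
  }

  overall <- classification_accuracy(final, labels,
                                     support_vector_count = stats::median(sv))
  stage1 <- classification_accuracy(pred1, truth1)
  s2_scope <- pred1 == STAGE1_RED_OR_LIGHT & labels %in% c("red", "light_red")
  stage2 <- if (any(s2_scope)) {
    classification_accuracy(final[s2_scope], labels[s2_scope])
  } else {
    NULL
  }
  records <- data.frame(image_id = feat$ids, truth = labels,
                        stage1 = pred1, final = final, stage = stage,
                        rule_path = rule_path, fold = fold_of,
                        stringsAsFactors = FALSE)
  structure(list(
    overall = overall, stage1 = stage1, stage2 = stage2,
    support_vectors = sv, records = records,
    protocol = sprintf("stratified %d-fold CV, seed %d", folds, seed),
    time_per_image_s = feat$timing_s / n
  ), class = "cascade_eval")
}

#' @rdname evaluate_features
#' @param corpus a `tongue_corpus` or manifest data frame.
#' @export
evaluate_corpus <- function(corpus, cfg = pipeline_config(), folds = 5L,
                            seed = 0L) {
  evaluate_features(corpus_features(corpus, cfg), cfg, folds, seed)
}

#' @export
print.cascade_eval <- function(x, ...) {
  cat(sprintf("<cascade_eval> %s\n", x$protocol))
  cat(sprintf("  3-class accuracy: %.1f%% (N = %d)\n",
              x$overall$accuracy_pct, x$overall$N))
  cat(sprintf("  stage 1 (deep red vs red/light red): %.1f%%\n",
              x$stage1$accuracy_pct))
  if (!is.null(x$stage2)) {
    cat(sprintf("  stage 2 (red vs light red, conditional): %.1f%% (N = %d)\n",
                x$stage2$accuracy_pct, x$stage2$N))
  }
  cat(sprintf("  support vectors per fold: %s\n",
              paste(x$support_vectors, collapse = ", ")))
  invisible(x)
}

# ---- raw-pixel baseline and kernel comparison -------------------------------

#' Raw-pixel baseline features
#'
#' The conventional-SVM baseline: each image is represented by the Lab
#' values of `budget` foreground pixels, sampled uniformly (deterministic
#' per image seed) and flattened to a `3 * budget` vector. Images with
#' fewer foreground pixels than the budget recycle pixels.
#'
#' @param corpus a `tongue_corpus` or manifest data frame.
#' @param budget pixels per image.
#' @param seed sampling seed.
#' @return List `X` (n x 3*budget matrix), `labels`, `ids`.
#' @export
raw_pixel_features <- function(corpus, budget = 500L, seed = 0L) {
  cc <- .corpus_images(corpus)
  n <- length(cc$images)
  X <- matrix(NA_real_, n, 3L * budget)
  for (i in seq_len(n)) {
    lab <- .as_lab_image(cc$images[[i]])
    px <- .pixel_matrix(lab)[as.vector(lab$mask), , drop = FALSE]
    idx <- withr::with_seed(seed + i, {
      sort(sample.int(nrow(px), budget, replace = nrow(px) < budget))
    })
    X[i, ] <- as.vector(px[idx, ])
  }
  list(X = X, labels = cc$labels, ids = cc$ids)
}

#' Kernel and feature-set comparison table
#'
#' Reproduces the comparison design of the evaluation study: for each
#' combination of feature set (`identifier` = clustering-identifier
#' features; `raw_pixel` = downsampled foreground pixels, the conventional
#' SVM) and kernel, reports the cross-validated stage-1 accuracy, the
#' support-vector count of a full-data fit, and the wall time.
#'
#' @param corpus a `tongue_corpus` or manifest data frame.
#' @param cfg a [pipeline_config()].
#' @param kernels character vector of kernels to compare.
#' @param methods subset of `c("identifier", "raw_pixel")`.
#' @param folds CV folds.
#' @param seed fold seed.
#' @param feat optional precomputed `corpus_features` (identifier method).
#' @return Data frame: `method`, `kernel`, `accuracy_pct`,
#'   `support_vectors`, `runtime_s`.
#' @export
compare_kernels <- function(corpus, cfg = pipeline_config(),
                            kernels = c("linear", "rbf", "polynomial",
                                        "quadratic"),
                            methods = c("identifier", "raw_pixel"),
                            folds = 5L, seed = 0L, feat = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  sets <- list()
  if ("identifier" %in% methods) {
    if (is.null(feat)) feat <- corpus_features(corpus, cfg)
    sets$identifier <- list(X = feat$X, labels = feat$labels)
  }
  if ("raw_pixel" %in% methods) {
    rp <- raw_pixel_features(corpus, budget = cfg$raw_pixel_budget,
                             seed = cfg$seed)
    sets$raw_pixel <- list(X = rp$X, labels = rp$labels)
  }
  rows <- list()
  for (method in names(sets)) {
    s <- sets[[method]]
    truth1 <- stage1_label(s$labels)
    fold_of <- stratified_folds(s$labels, folds, seed)
    for (kern in kernels) {
      t0 <- proc.time()[["elapsed"]]
      pred <- character(length(truth1))
      for (f in seq_len(folds)) {
        test <- fold_of == f
        m <- train_stage1(s$X[!test, , drop = FALSE], s$labels[!test],
                          kernel = kern, C = cfg$C, seed = cfg$seed)
        pred[test] <- predict_stage1(m, s$X[test, , drop = FALSE])
      }
      full <- train_stage1(s$X, s$labels, kernel = kern, C = cfg$C,
                           seed = cfg$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, kernel = kern,
        accuracy_pct = classification_accuracy(pred, truth1)$accuracy_pct,
        support_vectors = count_support_vectors(full),
        runtime_s = proc.time()[["elapsed"]] - t0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
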