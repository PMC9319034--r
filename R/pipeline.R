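# High-level pipeline helpers: learn the master palette from per-pattern
# training tiles, extract feature tables, and run the end-to-end
# train/evaluate loop used by the acceptance harness.

#' Learn the master palette from per-pattern training tiles
#'
#' Stage 1: the pixels of all training tiles of each pattern are pooled (with
#' a seeded subsampling cap for tractability) and clustered by Euclidean
#' K-means in the working space into `k` centroids per pattern. Stage 2: the
#' pooled `7 * k` centroids are merged into exactly `target_n` master colours
#' by [build_master_palette()].
#'
#' @param images_by_pattern Named list (by pattern) of lists of H x W x 3
#'   sRGB arrays.
#' @param space Working space, `"cam16ucs"` (default) or `"lab"`.
#' @param k Stage-1 centroids per pattern (default 18).
#' @param target_n Master palette size (default 20).
#' @param vc Viewing conditions.
#' @param seed Integer seed (clustering initialisation and subsampling).
#' @param max_pixels_per_image Per-image subsampling cap (default 5e4).
#' @param max_pixels_per_pattern Pooled subsampling cap per pattern (default
#'   2e4) keeping stage-1 clustering desk-scale.
#' @return A `bcc_palette`; the stage-1 `centroid_set`s are attached as
#'   attribute `"stage1"`.
#' @export
build_palette_from_images <- function(images_by_pattern,
                                      space = c("cam16ucs", "lab"),
                                      k = 18, target_n = 20,
                                      vc = viewing_conditions(), seed = 1,
                                      max_pixels_per_image = 5e4,
                                      max_pixels_per_pattern = 2e4) {
  space <- match.arg(space)
  patterns <- names(images_by_pattern)
  if (is.null(patterns) || !all(nzchar(patterns))) {
    stop("images_by_pattern must be a named list (one entry per pattern)")
  }
  stage1 <- vector("list", length(patterns))
  names(stage1) <- patterns
  for (pi in seq_along(patterns)) {
    p <- patterns[pi]
    px <- do.call(rbind, lapply(images_by_pattern[[p]], function(img) {
      m <- .flatten_image(img)
      if (nrow(m) > max_pixels_per_image) {
        set.seed(seed + 7919L * pi)
        m <- m[sample.int(nrow(m), max_pixels_per_image), , drop = FALSE]
      }
      m
    }))
    if (nrow(px) > max_pixels_per_pattern) {
      set.seed(seed + 104729L * pi)
      px <- px[sample.int(nrow(px), max_pixels_per_pattern), , drop = FALSE]
    }
    wp <- srgb_to_working(px, space = space, vc = vc)
    stage1[[p]] <- cluster_pattern_colors(wp, k = k, seed = seed + pi,
                                          srgb = px, source = p)
  }
  pal <- build_master_palette(stage1, target_n = target_n, space = space,
                              vc = vc)
  attr(pal, "stage1") <- stage1
  pal
}

#' Extract the CCM feature table of a synthetic dataset
#'
#' @param dataset A `synthetic_dataset` (or plain list of images).
#' @param palette A `bcc_palette`.
#' @param ... Passed to [image_features()].
#' @return Numeric feature matrix, one row per tile.
#' @export
dataset_features <- function(dataset, palette, ...) {
  images <- if (inherits(dataset, "synthetic_dataset")) dataset$images else dataset
  t(vapply(images, image_features, numeric(7L), palette = palette, ...))
}

#' End-to-end synthetic study: palette, features, detector, clinical rule
#'
#' Runs the whole pipeline at desk scale on planted synthetic data: learns
#' the master palette from the training singles, extracts CCM features,
#' trains the multilabel detector, tunes per-pattern thresholds by Youden's J
#' on the training set, then evaluates pattern detection (per-pattern and
#' macro AUC) and the binary BCC diagnosis (clinical rule, strict mode) on a
#' freshly seeded test set.
#'
#' @param n_per_pattern Training singles per pattern (default 50).
#' @param size Tile size (default 96 x 96, the desk-scale study size).
#' @param train_seed,test_seed Seeds of the two independently generated
#'   datasets.
#' @param space Working space for palette and CCM.
#' @param thresholds `"youden"` (default) or a numeric threshold setting.
#' @return List with the palette, model, thresholds, the multilabel report
#'   and the binary BCC report of the test set.
#' @export
run_synthetic_study <- function(n_per_pattern = 50, size = c(96, 96),
                                train_seed = 1, test_seed = 2,
                                space = "cam16ucs", thresholds = "youden") {
  train <- make_dataset(n_per_pattern, size = size, seed = train_seed)
  test <- make_dataset(n_per_pattern, size = size, seed = test_seed)

  singles <- lapply(stats::setNames(bcc_patterns(), bcc_patterns()),
                    function(p) {
    train$images[train$labels[, p] == 1L & rowSums(train$labels) == 1L]
  })
  palette <- build_palette_from_images(singles, space = space,
                                       seed = train_seed)

  x_train <- dataset_features(train, palette)
  x_test <- dataset_features(test, palette)
  model <- train_pattern_classifier(x_train, train$labels, seed = train_seed)

  p_train <- predict_patterns(model, x_train)
  th <- if (identical(thresholds, "youden")) {
    youden_thresholds(p_train, train$labels)
  } else .expand_thresholds(thresholds)

  p_test <- predict_patterns(model, x_test)
  ml <- multilabel_report(p_test, test$labels, th)

  d_test <- apply_thresholds(p_test, th)
  pred <- bcc_rule(d_test, mode = "strict")
  truth <- bcc_rule(test$labels == 1L, mode = "strict")
  bin <- binary_report(truth, pred)

  list(palette = palette, model = model, thresholds = th,
       multilabel = ml, binary = bin,
       n_train = length(train$images), n_test = length(test$images))
}
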