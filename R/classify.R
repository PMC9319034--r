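# Multilabel detection of the seven dermoscopic patterns from texture feature
# records, and the clinical rule mapping pattern detections to a BCC/non-BCC
# diagnosis. The detector is a bank of seven one-vs-rest single-hidden-layer
# perceptrons (nnet) trained with binary cross-entropy; class imbalance is
# handled by per-pattern positive case weights.

# coerce a feature argument to a numeric matrix with stable column order
.as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), "image_id"), drop = FALSE]
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, names(features)))
  storage.mode(features) <- "double"
  features
}

.as_label_matrix <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  if (ncol(labels) != 7L) stop("labels must have 7 columns (one per pattern)")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  colnames(labels) <- bcc_patterns()
  labels
}

#' Train the multilabel pattern detector
#'
#' Fits one sigmoid-output multilayer perceptron per dermoscopic pattern
#' (one-vs-rest) on standardized feature records, minimizing binary
#' cross-entropy. Positive examples of each pattern receive case weight
#' `n_neg / n_pos` (capped) when `pos_weight = TRUE`, compensating the strong
#' class imbalance among patterns. Deterministic for a given seed.
#'
#' @param features Numeric matrix or data frame of feature records (an
#'   `image_id` column is dropped); all values must be finite.
#' @param labels n x 7 binary matrix in the [bcc_patterns()] column order.
#' @param hidden Hidden-layer width (default 8).
#' @param decay Weight decay (default 1e-3).
#' @param maxit Maximum optimizer iterations (default 500).
#' @param pos_weight Per-pattern positive weighting on/off (default on), or a
#'   numeric cap for the weight (default cap 20).
#' @param seed Integer seed.
#' @return A `pattern_classifier` with the seven fitted heads and the
#'   training standardization constants.
#' @importFrom nnet nnet
#' @export
train_pattern_classifier <- function(features, labels, hidden = 8,
                                     decay = 1e-3, maxit = 500,
                                     pos_weight = TRUE, seed = 1) {
  x <- .as_feature_matrix(features)
  y <- .as_label_matrix(labels)
  if (nrow(x) != nrow(y)) stop("features and labels must align row-wise")
  if (anyNA(x) || any(!is.finite(x))) stop("features must be finite")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  cap <- if (is.numeric(pos_weight)) pos_weight else 20
  use_w <- !identical(pos_weight, FALSE)
  patterns <- bcc_patterns()
  heads <- vector("list", 7L)
  names(heads) <- patterns
  loss <- numeric(7L)
  for (i in seq_len(7L)) {
    yi <- y[, i]
    n_pos <- sum(yi == 1); n_neg <- sum(yi == 0)
    if (n_pos == 0 || n_neg == 0) {
      warning(sprintf("pattern `%s` is degenerate (all %s); head trained anyway",
                      patterns[i], if (n_pos == 0) "negative" else "positive"))
    }
    w <- rep(1, length(yi))
    if (use_w && n_pos > 0 && n_neg > 0) {
      w[yi == 1] <- min(cap, n_neg / n_pos)
    }
    set.seed(seed + i)
    fit <- nnet::nnet(xs, yi, weights = w, size = hidden, decay = decay,
                      maxit = maxit, entropy = TRUE, trace = FALSE)
    heads[[i]] <- fit
    loss[i] <- fit$value / sum(w)
  }
  structure(list(heads = heads, center = center, scale = scale,
                 features = colnames(x), hidden = hidden, decay = decay,
                 maxit = maxit, seed = seed, loss = loss),
            class = "pattern_classifier")
}

#' @export
print.pattern_classifier <- function(x, ...) {
  cat(sprintf(
    "<pattern_classifier> 7 one-vs-rest MLP heads (%d inputs -> %d hidden -> 1), seed %d\n",
    length(x$center), x$hidden, x$seed))
  invisible(x)
}

#' Predict pattern probabilities
#'
#' @param model A `pattern_classifier`.
#' @param features One feature record (named vector) or a matrix/data frame
#'   of records with the arity the model was trained on.
#' @return Probabilities in `[0, 1]`: named length-7 vector for one record,
#'   n x 7 matrix otherwise. Columns follow [bcc_patterns()].
#' @export
predict_patterns <- function(model, features) {
  stopifnot(inherits(model, "pattern_classifier"))
  single <- is.null(dim(features)) ||
    (!is.null(dim(features)) && nrow(features) == 1L && is.null(rownames(features)))
  x <- .as_feature_matrix(features)
  if (ncol(x) != length(model$center)) {
    stop(sprintf("feature arity mismatch: model expects %d, got %d",
                 length(model$center), ncol(x)))
  }
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  p <- vapply(model$heads, function(h) as.numeric(stats::predict(h, xs)),
              numeric(nrow(xs)))
  if (nrow(xs) == 1L) p <- matrix(p, nrow = 1L, dimnames = list(NULL, bcc_patterns()))
  colnames(p) <- bcc_patterns()
  p <- pmin(pmax(p, 0), 1)
  if (is.null(dim(features)) && nrow(xs) == 1L) p[1L, ] else p
}

#' Threshold pattern probabilities
#'
#' `detected[k] = p[k] >= t[k]` (a tie counts as detected).
#'
#' @param p Probabilities: named length-7 vector or n x 7 matrix.
#' @param thresholds Single number recycled to all patterns, or a named
#'   length-7 vector. Default 0.5 each.
#' @return Logical detections, same shape as `p`.
#' @export
apply_thresholds <- function(p, thresholds = 0.5) {
  t <- .expand_thresholds(thresholds)
  if (is.null(dim(p))) {
    if (length(p) != 7L) stop("probabilities must cover all 7 patterns")
    if (!is.null(names(p))) p <- p[bcc_patterns()]
    stats::setNames(as.logical(p >= t), bcc_patterns())
  } else {
    if (ncol(p) != 7L) stop("probabilities must have 7 columns")
    if (!is.null(colnames(p))) p <- p[, bcc_patterns(), drop = FALSE]
    d <- sweep(p, 2L, t, ">=")
    colnames(d) <- bcc_patterns()
    d
  }
}

.expand_thresholds <- function(thresholds) {
  if (length(thresholds) == 1L) {
    t <- rep(as.numeric(thresholds), 7L)
  } else {
    if (!all(bcc_patterns() %in% names(thresholds))) {
      stop("named thresholds must cover all 7 patterns")
    }
    t <- as.numeric(thresholds[bcc_patterns()])
  }
  if (any(t < 0 | t > 1)) stop("thresholds must lie in [0, 1]")
  stats::setNames(t, bcc_patterns())
}

#' Per-pattern thresholds maximizing Youden's J
#'
#' Chooses, for every pattern, the probability threshold maximizing
#' sensitivity + specificity - 1 on the given (validation) set. Patterns with
#' a single observed class keep the 0.5 default.
#'
#' @param p n x 7 probability matrix.
#' @param labels n x 7 binary label matrix.
#' @return Named length-7 threshold vector.
#' @export
youden_thresholds <- function(p, labels) {
  y <- .as_label_matrix(labels)
  if (ncol(p) != 7L) stop("probabilities must have 7 columns")
  if (is.null(colnames(p))) colnames(p) <- bcc_patterns()
  t <- stats::setNames(rep(0.5, 7L), bcc_patterns())
  for (k in bcc_patterns()) {
    yk <- y[, k]
    if (length(unique(yk)) < 2L) next
    r <- pROC::roc(response = yk, predictor = p[, k], levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
    th <- best$threshold[1L]
    if (is.finite(th)) t[k] <- min(max(th, 0), 1)
  }
  t
}

#' Clinical BCC rule
#'
#' Maps the seven pattern detections to a BCC/non-BCC diagnosis. The
#' dermoscopic criterion for BCC combines the absence of the pigment network
#' (the negative criterion) with the presence of at least one of the six
#' positive patterns:
#' \itemize{
#'   \item `strict` (default): BCC iff at least one positive pattern is
#'     detected AND the pigment network is absent;
#'   \item `permissive`: BCC iff at least one positive pattern is detected,
#'     regardless of the pigment network.
#' }
#' With no detected pattern the diagnosis is non-BCC in both modes.
#'
#' @param d Named logical length-7 vector of detections, or an n x 7 logical
#'   matrix.
#' @param mode `"strict"` or `"permissive"`.
#' @return `"BCC"`/`"nonBCC"` (character; vector for matrix input).
#' @export
bcc_rule <- function(d, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  single <- is.null(dim(d))
  if (single) d <- matrix(d, nrow = 1L, dimnames = list(NULL, names(d)))
  if (!all(bcc_patterns() %in% colnames(d))) {
    stop("detections must cover all 7 patterns")
  }
  d <- d[, bcc_patterns(), drop = FALSE]
  positive <- rowSums(d[, setdiff(bcc_patterns(), "pigment_network"),
                        drop = FALSE]) > 0
  network <- d[, "pigment_network"]
  is_bcc <- if (mode == "strict") positive & !network else positive
  out <- ifelse(is_bcc, "BCC", "nonBCC")
  if (single) out[[1L]] else out
}

#' End-to-end diagnosis of one image tile
#'
#' Runs the full pipeline — quantization, CCM texture features, pattern
#' probabilities, thresholding and the clinical rule — and returns the
#' diagnosis together with the per-pattern evidence that explains it.
#'
#' @param img H x W x 3 sRGB array.
#' @param palette A `bcc_palette`.
#' @param model A `pattern_classifier` trained on matching features.
#' @param thresholds Detection thresholds (see [apply_thresholds()]).
#' @param mode Rule mode, `"strict"` (default) or `"permissive"`.
#' @param ... Passed to [image_features()] (e.g. `mode`, `spec`).
#' @return List with `diagnosis`, `detections`, `probabilities` and
#'   `features`.
#' @export
diagnose <- function(img, palette, model, thresholds = 0.5,
                     mode = c("strict", "permissive"), ...) {
  mode <- match.arg(mode)
  feats <- image_features(img, palette = palette, ...)
  p <- predict_patterns(model, feats)
  d <- apply_thresholds(p, thresholds)
  list(diagnosis = bcc_rule(d, mode), detections = d, probabilities = p,
       features = feats)
}

# ---- model serialization ----------------------------------------------------

# the nnet components needed by predict.nnet
.nnet_fields <- c("n", "nunits", "nconn", "conn", "nsunits", "decay",
                  "entropy", "softmax", "censored", "value", "wts")

#' Write a trained pattern classifier to JSON
#'
#' @param model A `pattern_classifier`.
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_classifier"))
  heads <- lapply(model$heads, function(h) h[.nnet_fields])
  obj <- list(center = as.list(stats::setNames(model$center, model$features)),
              scale = as.list(stats::setNames(model$scale, model$features)),
              hidden = model$hidden, decay = model$decay, maxit = model$maxit,
              seed = model$seed, loss = model$loss, heads = heads)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a pattern classifier from JSON
#'
#' @param path File written by [write_model()].
#' @return A `pattern_classifier`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  heads <- lapply(seq_len(7L), function(i) {
    h <- lapply(.nnet_fields, function(f) {
      v <- if (is.data.frame(obj$heads)) obj$heads[[f]][[i]] else obj$heads[[i]][[f]]
      if (f %in% c("entropy", "softmax", "censored")) as.logical(v)
      else if (f %in% c("nunits", "nconn", "conn", "n")) as.integer(unlist(v))
      else as.numeric(unlist(v))
    })
    names(h) <- .nnet_fields
    structure(h, class = "nnet")
  })
  names(heads) <- bcc_patterns()
  structure(list(heads = heads,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 features = names(obj$center), hidden = obj$hidden,
                 decay = obj$decay, maxit = obj$maxit, seed = obj$seed,
                 loss = as.numeric(obj$loss)),
            class = "pattern_classifier")
}

#' Read / write multilabel annotation tables
#'
#' CSV with an `image_id` column followed by the 7 binary pattern columns in
#' the [bcc_patterns()] order.
#'
#' @param path CSV file path.
#' @return For `read_labels`, a data frame with `image_id` and the 7 columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("image_id", bcc_patterns()), names(df))
  if (length(missing)) {
    stop("labels CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df[, c("image_id", bcc_patterns())]
}

#' @rdname read_labels
#' @param labels n x 7 binary matrix (or data frame including `image_id`).
#' @param ids Image identifiers (defaults to row numbers).
#' @export
write_labels <- function(labels, path, ids = NULL) {
  if (is.data.frame(labels) && "image_id" %in% names(labels)) {
    df <- labels[, c("image_id", bcc_patterns())]
  } else {
    y <- .as_label_matrix(labels)
    if (is.null(ids)) ids <- sprintf("img_%04d", seq_len(nrow(y)))
    df <- data.frame(image_id = ids, y, row.names = NULL)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
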