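# Two-step perceptual palette learning and nearest-centroid quantization.
#
# Stage 1 clusters the pooled pixels of each dermoscopic pattern (Euclidean
# K-means in the working space, 18 centroids per pattern by default). Stage 2
# merges near-duplicate centroids across patterns: two centroids belong
# together when their Delta E falls below a threshold, and the threshold is
# adjusted automatically so that exactly `target_n` (default 20) master
# colours remain. Threshold merging by connected components is exactly a cut
# of the single-linkage dendrogram, which is how the exact count is found.

#' The seven BCC dermoscopic pattern classes
#'
#' Fixed-order labels for the seven dermoscopic structures: pigment network
#' (the sole negative criterion), ulceration, blue-gray ovoid nests, multiple
#' blue-gray globules, maple-leaf areas, spoke-wheel areas and arborizing
#' telangiectasia.
#'
#' @return Character vector of length 7.
#' @export
bcc_patterns <- function() {
  c("pigment_network", "ulceration", "ovoid_nest", "multi_globules",
    "maple_leaf", "spoke_wheel", "telangiectasia")
}

# internal constructor for a set of centroids (pre-palette)
.centroid_set <- function(colors, srgb, weights, sources) {
  stopifnot(nrow(colors) == length(weights), nrow(srgb) == nrow(colors),
            length(sources) == nrow(colors))
  structure(list(colors = colors, srgb = srgb, weights = as.numeric(weights),
                 sources = sources),
            class = "centroid_set")
}

#' Cluster the colours of one dermoscopic pattern
#'
#' Euclidean K-means over pooled working-space pixels of a pattern's training
#' tiles. Cluster centres are initialised from randomly chosen pixels; ten
#' restarts keep the best within-cluster sum of squares. Deterministic for a
#' given seed.
#'
#' @param pixels N x 3 matrix of working-space pixel colours.
#' @param k Number of centroids (default 18).
#' @param seed Integer seed.
#' @param srgb Optional N x 3 matrix of the same pixels in sRGB; when given,
#'   each centroid's display rendering is the mean sRGB of its member pixels,
#'   otherwise the rendering is deferred to [working_to_srgb()].
#' @param source Pattern label attached to every centroid (may be `NA`).
#' @return A `centroid_set` with `k` centroids; weights are cluster pixel
#'   counts.
#' @export
cluster_pattern_colors <- function(pixels, k = 18, seed = 1, srgb = NULL,
                                   source = NA_character_) {
  pixels <- .as_color_matrix(pixels, "pixels")
  if (!is.null(srgb)) {
    srgb <- .as_color_matrix(srgb, "srgb")
    if (nrow(srgb) != nrow(pixels)) stop("`srgb` must match `pixels` row-wise")
  }
  n_distinct <- nrow(unique(pixels))
  if (n_distinct < k) {
    stop(sprintf("need at least %d distinct colours for k = %d, have %d (deficit %d)",
                 k, k, n_distinct, k - n_distinct))
  }
  set.seed(seed)
  km <- NULL
  for (attempt in 1:5) {
    km <- tryCatch(
      stats::kmeans(pixels, centers = k, iter.max = 300, nstart = 10,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) {  # fall back to the more forgiving default algorithm
    km <- suppressWarnings(stats::kmeans(pixels, centers = k, iter.max = 300,
                                         nstart = 10))
  }
  centers <- unname(km$centers)
  weights <- as.numeric(km$size)
  if (is.null(srgb)) {
    rend <- matrix(NA_real_, k, 3L)
  } else {
    rend <- t(vapply(seq_len(k), function(i) {
      colMeans(srgb[km$cluster == i, , drop = FALSE])
    }, numeric(3L)))
  }
  .centroid_set(centers, rend, weights,
                sources = rep(list(source), k))
}

# weighted merge of the centroid rows listed in `idx`
.merge_rows <- function(cs, idx) {
  w <- cs$weights[idx]
  list(color = colSums(cs$colors[idx, , drop = FALSE] * w) / sum(w),
       srgb = if (anyNA(cs$srgb[idx, ])) rep(NA_real_, 3L) else
         colSums(cs$srgb[idx, , drop = FALSE] * w) / sum(w),
       weight = sum(w),
       sources = sort(unique(unlist(cs$sources[idx]))))
}

# combine several centroid_sets into one
.pool_centroids <- function(sets) {
  .centroid_set(do.call(rbind, lapply(sets, `[[`, "colors")),
                do.call(rbind, lapply(sets, `[[`, "srgb")),
                unlist(lapply(sets, `[[`, "weights")),
                do.call(c, lapply(sets, `[[`, "sources")))
}

#' Merge centroids closer than a threshold
#'
#' Single-linkage agglomeration: connected components of the graph joining
#' centroid pairs with Delta E strictly below `threshold` collapse to their
#' weight-weighted mean. Total weight is conserved. Components are ordered by
#' their first member's original index.
#'
#' @param centroids A `centroid_set` (e.g. from [cluster_pattern_colors()]).
#' @param threshold Positive Delta E merge threshold.
#' @return A `centroid_set` of the merged centroids.
#' @export
merge_step <- function(centroids, threshold) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number")
  }
  n <- nrow(centroids$colors)
  d <- as.matrix(stats::dist(centroids$colors))
  # union-find over the "closer than threshold" graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (d[i, j] < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), match(comp, unique(comp)))
  merged <- lapply(groups, function(idx) .merge_rows(centroids, idx))
  .centroid_set(do.call(rbind, lapply(merged, `[[`, "color")),
                do.call(rbind, lapply(merged, `[[`, "srgb")),
                vapply(merged, `[[`, numeric(1L), "weight"),
                lapply(merged, `[[`, "sources"))
}

#' Build the master colour palette
#'
#' Merges the per-pattern centroids of stage 1 into a fixed-size master
#' palette: the merge threshold is adjusted automatically so that exactly
#' `target_n` colours remain (a cut of the single-linkage dendrogram over the
#' pairwise Delta E). Merged centroids are weight-weighted means; their
#' pattern sources are unioned.
#'
#' @param per_pattern Named list (by pattern) of `centroid_set`s, or a single
#'   `centroid_set`.
#' @param target_n Final palette size (default 20).
#' @param space Working-space tag, `"cam16ucs"` or `"lab"`.
#' @param vc Viewing conditions used for the working-space transform.
#' @return A `bcc_palette` object with exactly `target_n` centroids.
#' @export
build_master_palette <- function(per_pattern, target_n = 20,
                                 space = c("cam16ucs", "lab"),
                                 vc = viewing_conditions()) {
  space <- match.arg(space)
  pool <- if (inherits(per_pattern, "centroid_set")) per_pattern
          else .pool_centroids(per_pattern)
  n <- nrow(pool$colors)
  if (target_n > n) {
    stop(sprintf("target_n = %d exceeds the %d input centroids", target_n, n))
  }
  if (target_n == n) {
    groups <- as.list(seq_len(n))
    threshold <- 0
  } else {
    d <- stats::dist(pool$colors)
    hc <- stats::hclust(d, method = "single")
    comp <- stats::cutree(hc, k = target_n)
    groups <- split(seq_len(n), match(comp, unique(comp)))
    threshold <- hc$height[n - target_n]  # largest merge height applied
  }
  merged <- lapply(groups, function(idx) .merge_rows(pool, idx))
  colors <- do.call(rbind, lapply(merged, `[[`, "color"))
  srgb <- do.call(rbind, lapply(merged, `[[`, "srgb"))
  if (anyNA(srgb)) {
    srgb <- working_to_srgb(colors, space = space, vc = vc)
  }
  new_palette(colors = colors, srgb = srgb,
              weights = vapply(merged, `[[`, numeric(1L), "weight"),
              sources = lapply(merged, `[[`, "sources"),
              space = space, vc = vc, threshold = threshold)
}

#' Construct a colour palette
#'
#' @param colors n x 3 matrix of centroid coordinates in the working space.
#' @param srgb n x 3 matrix of display renderings in `[0, 1]`.
#' @param weights Positive pixel masses.
#' @param sources List (length n) of character vectors of contributing
#'   pattern labels.
#' @param space Working-space tag.
#' @param vc Viewing conditions.
#' @param threshold Merge threshold actually applied (0 if none).
#' @return A `bcc_palette` object.
#' @export
new_palette <- function(colors, srgb, weights = rep(1, nrow(colors)),
                        sources = rep(list(NA_character_), nrow(colors)),
                        space = c("cam16ucs", "lab"),
                        vc = viewing_conditions(), threshold = 0) {
  space <- match.arg(space)
  colors <- .as_color_matrix(colors, "colors")
  srgb <- .as_color_matrix(srgb, "srgb")
  if (nrow(srgb) != nrow(colors) || length(weights) != nrow(colors) ||
      length(sources) != nrow(colors)) {
    stop("palette fields must have one row/element per centroid")
  }
  if (any(weights <= 0)) stop("centroid weights must be positive")
  if (any(srgb < -1e-9) || any(srgb > 1 + 1e-9)) stop("srgb renderings must lie in [0, 1]")
  structure(list(colors = unname(colors), srgb = pmin(pmax(unname(srgb), 0), 1),
                 weights = as.numeric(weights), sources = sources,
                 space = space, vc = vc, threshold = threshold),
            class = "bcc_palette")
}

#' @export
print.bcc_palette <- function(x, ...) {
  cat(sprintf("<bcc_palette> %d colours in %s (merge threshold %.3f)\n",
              nrow(x$colors), x$space, x$threshold))
  invisible(x)
}

#' Number of palette colours
#' @param x A `bcc_palette`.
#' @export
palette_size <- function(x) {
  stopifnot(inherits(x, "bcc_palette"))
  nrow(x$colors)
}

# flatten an H x W x 3 array to an N x 3 matrix (row-major per pixel)
.flatten_image <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  matrix(img, ncol = 3L)
}

.unflatten_image <- function(m, h, w) array(m, dim = c(h, w, 3L))

#' Quantize an image against a palette
#'
#' Maps every pixel to the index of the nearest palette centroid (Euclidean
#' distance in the palette's working space; ties go to the lowest index).
#'
#' @param image H x W x 3 array of sRGB values in `[0, 1]`.
#' @param palette A `bcc_palette`.
#' @return A `quantized_image`: list with `indices` (H x W integer matrix of
#'   1-based palette indices), `palette` and `shape`.
#' @export
quantize <- function(image, palette) {
  stopifnot(inherits(palette, "bcc_palette"))
  if (palette_size(palette) < 1L) stop("palette is empty")
  px <- .flatten_image(image)
  wp <- srgb_to_working(px, space = palette$space, vc = palette$vc)
  idx <- nearest_centroid(wp, palette$colors)
  structure(list(indices = matrix(idx, dim(image)[1L], dim(image)[2L]),
                 palette = palette,
                 shape = dim(image)[1:2]),
            class = "quantized_image")
}

#' Nearest-centroid assignment
#'
#' @param x N x 3 matrix of working-space colours.
#' @param centers k x 3 matrix of centroids.
#' @return Integer vector of 1-based indices of the nearest centroid
#'   (Euclidean; ties broken by the lowest index).
#' @export
nearest_centroid <- function(x, centers) {
  x <- .as_color_matrix(x, "x")
  centers <- .as_color_matrix(centers, "centers")
  # squared distances via the expansion |x - c|^2 = |x|^2 - 2 x.c + |c|^2
  cross <- x %*% t(centers)
  d2 <- sweep(-2 * cross, 2L, rowSums(centers^2), "+")
  max.col(-d2, ties.method = "first")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d over %d colours\n",
              x$shape[1L], x$shape[2L], palette_size(x$palette)))
  invisible(x)
}

#' Render a quantized image back to sRGB
#'
#' Each pixel is replaced by its centroid's display rendering.
#'
#' @param q A `quantized_image`.
#' @return H x W x 3 array of sRGB values.
#' @export
render_quantized <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  m <- q$palette$srgb[as.integer(q$indices), , drop = FALSE]
  .unflatten_image(m, q$shape[1L], q$shape[2L])
}

#' Write a palette to JSON
#'
#' Lossless round trip of all palette fields (full float precision).
#'
#' @param palette A `bcc_palette`.
#' @param path Output file path.
#' @export
write_palette <- function(palette, path) {
  stopifnot(inherits(palette, "bcc_palette"))
  obj <- list(
    space = palette$space,
    viewing = list(white = palette$vc$white, L_A = palette$vc$L_A,
                   Y_b = palette$vc$Y_b, surround = palette$vc$surround,
                   discount_illuminant = palette$vc$discount_illuminant),
    threshold = palette$threshold,
    centroids = lapply(seq_len(palette_size(palette)), function(i) {
      list(color = palette$colors[i, ], srgb = palette$srgb[i, ],
           weight = palette$weights[i],
           sources = as.character(stats::na.omit(palette$sources[[i]])))
    }))
  # I(17) significant digits: doubles survive the round trip bitwise
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a palette from JSON
#'
#' @param path Palette file written by [write_palette()] (or hand-authored to
#'   the same schema). Schema violations raise an error naming the field.
#' @return A `bcc_palette`.
#' @export
read_palette <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("space", "centroids")) {
    if (is.null(obj[[field]])) stop(sprintf("palette file: missing `%s`", field))
  }
  if (!obj$space %in% c("lab", "cam16ucs")) {
    stop(sprintf("palette file: unknown space tag `%s`", obj$space))
  }
  v <- obj$viewing
  vc <- if (is.null(v)) viewing_conditions() else viewing_conditions(
    white = unlist(v$white), L_A = v$L_A, Y_b = v$Y_b, surround = v$surround,
    discount_illuminant = isTRUE(v$discount_illuminant))
  cents <- obj$centroids
  if (length(cents) < 1L) stop("palette file: `centroids` is empty")
  grab <- function(cent, f, len) {
    val <- unlist(cent[[f]])
    if (f %in% c("color", "srgb", "weight") &&
        (is.null(val) || length(val) != len || !is.numeric(val))) {
      stop(sprintf("palette file: bad `centroids[].%s`", f))
    }
    val
  }
  colors <- do.call(rbind, lapply(cents, grab, "color", 3L))
  srgb <- do.call(rbind, lapply(cents, grab, "srgb", 3L))
  weights <- vapply(cents, function(cc) grab(cc, "weight", 1L), numeric(1L))
  sources <- lapply(cents, function(cc) {
    s <- unlist(cc$sources)
    if (is.null(s)) NA_character_ else as.character(s)
  })
  new_palette(colors, srgb, weights, sources, space = obj$space, vc = vc,
              threshold = if (is.null(obj$threshold)) 0 else obj$threshold)
}
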