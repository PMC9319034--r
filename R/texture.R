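# Co-occurrence texture analysis: the classical GLCM on the L* channel and
# the perceptual colour co-occurrence matrix (CCM) over palette-quantized
# images. The CCM replaces the integer level difference |i - j| of Haralick
# statistics with the perceptual colour difference Delta E(C_i, C_j) between
# palette centroids, so all five statistics are colour-appearance weighted.

#' Spatial offset specification for co-occurrence matrices
#'
#' @param offsets Two-column integer matrix of `(dy, dx)` displacements; one
#'   row per offset. `(0, 0)` is not allowed and offsets must be distinct.
#' @param symmetric If `TRUE` (default) each pair is also counted in the
#'   reverse direction, making the matrix symmetric.
#' @return An `offset_spec` object.
#' @export
offset_spec <- function(offsets = haralick_offsets(), symmetric = TRUE) {
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("dy", "dx")))
  if (any(offsets[, 1L] == 0L & offsets[, 2L] == 0L)) {
    stop("the (0, 0) offset is not allowed")
  }
  if (anyDuplicated(offsets)) stop("offsets must be distinct")
  structure(list(offsets = offsets, symmetric = isTRUE(symmetric)),
            class = "offset_spec")
}

#' The classical four distance-1 directions
#'
#' Displacements for 0, 45, 90 and 135 degrees at distance 1 — the Haralick
#' default. With symmetric accumulation this set is closed under 90-degree
#' image rotation, so direction-averaged features are rotation-robust.
#'
#' @return 4 x 2 integer matrix of `(dy, dx)` rows.
#' @export
haralick_offsets <- function() {
  matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("dy", "dx")))
}

# Accumulate co-occurrence counts of an integer index matrix over offsets.
# Returns the n x n count matrix (integer counts, before normalization).
.cooc_counts <- function(idx, n, spec) {
  h <- nrow(idx); w <- ncol(idx)
  counts <- matrix(0, n, n)
  for (r in seq_len(nrow(spec$offsets))) {
    dy <- spec$offsets[r, 1L]; dx <- spec$offsets[r, 2L]
    if (abs(dy) >= h || abs(dx) >= w) {
      stop(sprintf("image (%d x %d) is smaller than offset (%d, %d)", h, w, dy, dx))
    }
    ys <- if (dy >= 0) seq_len(h - dy) else seq.int(1L - dy, h)
    xs <- if (dx >= 0) seq_len(w - dx) else seq.int(1L - dx, w)
    a <- idx[ys, xs, drop = FALSE]
    b <- idx[ys + dy, xs + dx, drop = FALSE]
    tab <- tabulate((a - 1L) * n + b, nbins = n * n)
    counts <- counts + matrix(tab, n, n, byrow = TRUE)
  }
  if (spec$symmetric) counts <- counts + t(counts)
  counts
}

.new_cooc <- function(P, n, spec, kind, palette = NULL, counts = NULL) {
  structure(list(P = P, n = n, offsets = spec, kind = kind,
                 palette = palette, counts = counts),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> %s, %d x %d, %d offset(s)%s\n", x$kind, x$n, x$n,
              nrow(x$offsets$offsets),
              if (x$offsets$symmetric) ", symmetric" else ""))
  invisible(x)
}

#' Grey-level co-occurrence matrix
#'
#' Bins a real-valued channel uniformly over `value_range` (values clipped)
#' and accumulates pair counts over the given offsets; counts are normalized
#' to a joint probability table summing to 1.
#'
#' @param gray H x W numeric matrix (e.g. the L* channel).
#' @param levels Number of grey bins (default 32).
#' @param value_range `c(lo, hi)` range binned uniformly (default `c(0, 100)`
#'   for L*).
#' @param spec An [offset_spec()].
#' @return A `cooc_matrix` of kind `"gray"`.
#' @export
compute_glcm <- function(gray, levels = 32, value_range = c(0, 100),
                         spec = offset_spec()) {
  if (!is.matrix(gray) || !is.numeric(gray)) stop("`gray` must be a numeric matrix")
  if (levels < 2L) stop("`levels` must be at least 2")
  lo <- value_range[1L]; hi <- value_range[2L]
  if (!(hi > lo)) stop("`value_range` must satisfy hi > lo")
  g <- pmin(pmax(gray, lo), hi)
  idx <- pmin(floor((g - lo) / (hi - lo) * levels) + 1L, levels)
  idx <- matrix(as.integer(idx), nrow(gray), ncol(gray))
  counts <- .cooc_counts(idx, as.integer(levels), spec)
  .new_cooc(counts / sum(counts), as.integer(levels), spec, "gray",
            counts = counts)
}

#' Colour co-occurrence matrix over a quantized image
#'
#' Same accumulation and normalization rules as [compute_glcm()], applied to
#' the palette index map; the palette reference is retained so that the
#' feature statistics can look up centroid Delta E values.
#'
#' @param q A `quantized_image`.
#' @param spec An [offset_spec()].
#' @return A `cooc_matrix` of kind `"color"` (n = palette size).
#' @export
compute_ccm <- function(q, spec = offset_spec()) {
  stopifnot(inherits(q, "quantized_image"))
  n <- palette_size(q$palette)
  counts <- .cooc_counts(q$indices, n, spec)
  .new_cooc(counts / sum(counts), n, spec, "color", palette = q$palette,
            counts = counts)
}

#' Pairwise centroid Delta E table
#'
#' `D[i, j] = Delta E(C_i, C_j)` between palette centroids; because both
#' working spaces are perceptually uniform, this is the Euclidean distance of
#' the stored working-space coordinates (Delta E*ab in CIELAB, Delta E' in
#' CAM16-UCS). Symmetric with a zero diagonal.
#'
#' @param palette A `bcc_palette`.
#' @return n x n matrix of non-negative distances.
#' @export
ccm_distance_table <- function(palette) {
  stopifnot(inherits(palette, "bcc_palette"))
  as.matrix(stats::dist(palette$colors))
}

# Shared implementation of the five statistics.
#
# P: joint probability; Dij: pairwise "distance" between levels/colours;
# lvl_coord: per-level coordinate (scalar bin index for GLCM, working-space
# 3-vector rows for CCM). The mean is the P-weighted mean coordinate; sigma_i
# is the row-marginal Delta E dispersion around the row mean.
.cooc_stats <- function(P, Dij, lvl_coord,
                        correlation_denominator = "sigma_product") {
  p_row <- rowSums(P)
  p_col <- colSums(P)
  lvl_coord <- as.matrix(lvl_coord)
  mu_row <- colSums(lvl_coord * p_row)
  mu_col <- colSums(lvl_coord * p_col)
  d_row <- sqrt(rowSums(sweep(lvl_coord, 2L, mu_row)^2))  # Delta E(C_i, mu_i)
  d_col <- sqrt(rowSums(sweep(lvl_coord, 2L, mu_col)^2))
  sigma_row <- sqrt(sum(p_row * d_row^2))
  sigma_col <- sqrt(sum(p_col * d_col^2))

  homogeneity <- sum(P / (1 + Dij^2))
  variance <- sum(outer(d_row^2, rep(1, ncol(P))) * P)  # = sigma_row^2
  denom <- switch(correlation_denominator,
                  sigma_product = sigma_row * sigma_col,
                  sigma_squared_product = sigma_row^2 * sigma_col^2,
                  stop("unknown `correlation_denominator`"))
  correlation <- if (denom <= 0) 0 else sum(outer(d_row, d_col) * P) / denom
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))  # 0 * log(0) := 0

  structure(list(homogeneity = homogeneity,
                 mean = if (ncol(lvl_coord) == 1L) mu_row[[1L]] else mu_row,
                 variance = variance,
                 correlation = correlation,
                 entropy = entropy,
                 marginals = list(p_row = p_row, p_col = p_col,
                                  mu_row = mu_row, mu_col = mu_col,
                                  sigma_row = sigma_row, sigma_col = sigma_col)),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf(
    "texture features: homogeneity %.4f, variance %.4f, correlation %.4f, entropy %.4f\n",
    x$homogeneity, x$variance, x$correlation, x$entropy))
  cat("mean:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  invisible(x)
}

#' GLCM texture statistics
#'
#' The five co-occurrence statistics (homogeneity, mean, variance,
#' correlation, entropy) computed with the integer bin distance `|i - j|` in
#' place of Delta E and the bin index `i` in place of the centroid colour, so
#' the mean is a scalar.
#'
#' @param m A `cooc_matrix` of kind `"gray"`.
#' @param correlation_denominator `"sigma_product"` (default, the standard
#'   normalization giving a scale-free correlation) or
#'   `"sigma_squared_product"`.
#' @return A `texture_features` object (scalar `mean`).
#' @export
glcm_features <- function(m, correlation_denominator = "sigma_product") {
  stopifnot(inherits(m, "cooc_matrix"))
  if (m$kind != "gray") stop("`m` must be a grey-level co-occurrence matrix")
  lv <- seq_len(m$n)
  .cooc_stats(m$P, abs(outer(lv, lv, "-")), matrix(lv, ncol = 1L),
              correlation_denominator)
}

#' CCM texture statistics
#'
#' The five perceptually weighted co-occurrence statistics:
#' \itemize{
#'   \item homogeneity `H = sum P_ij / (1 + Delta E(C_i, C_j)^2)` in `(0, 1]`;
#'   \item mean `mu = sum C_i P_ij`, a working-space 3-vector (the image mean
#'     colour);
#'   \item variance `sigma^2 = sum Delta E(C_i, mu_i)^2 P_ij`;
#'   \item correlation
#'     `rho = sum Delta E(C_i, mu_i) Delta E(C_j, mu_j) P_ij / (sigma_i sigma_j)`
#'     — a non-negative co-dispersion index, since Delta E >= 0; defined as 0
#'     when either sigma vanishes (constant image);
#'   \item entropy `S = -sum P_ij ln P_ij` (natural log, `0 ln 0 := 0`),
#'     which is 0 for a constant image.
#' }
#'
#' @param m A `cooc_matrix` of kind `"color"` with its palette attached.
#' @param correlation_denominator `"sigma_product"` (default) or
#'   `"sigma_squared_product"`.
#' @return A `texture_features` object (3-vector `mean`).
#' @export
ccm_features <- function(m, correlation_denominator = "sigma_product") {
  stopifnot(inherits(m, "cooc_matrix"))
  if (m$kind != "color") stop("`m` must be a colour co-occurrence matrix")
  if (is.null(m$palette)) stop("colour co-occurrence matrix has no palette attached")
  .cooc_stats(m$P, ccm_distance_table(m$palette), m$palette$colors,
              correlation_denominator)
}

# flatten a texture_features object to the flat record used downstream
.feature_record <- function(f) {
  mu <- f$mean
  if (length(mu) == 1L) {
    c(homogeneity = f$homogeneity, mean = unname(mu), variance = f$variance,
      correlation = f$correlation, entropy = f$entropy)
  } else {
    c(homogeneity = f$homogeneity, mean_1 = mu[[1L]], mean_2 = mu[[2L]],
      mean_3 = mu[[3L]], variance = f$variance, correlation = f$correlation,
      entropy = f$entropy)
  }
}

#' Per-image texture feature record
#'
#' Assembles the flat feature record fed to the pattern classifier. In
#' `"ccm"` mode the image is quantized against the palette and the five CCM
#' statistics are computed; in `"glcm"` mode the image is converted to L* and
#' the GLCM statistics are computed. Statistics are computed per offset
#' direction (each accumulated symmetrically per `spec$symmetric`) and
#' averaged across directions, which makes the record robust to 90-degree
#' rotations for the default offset set.
#'
#' @param img H x W x 3 sRGB array.
#' @param palette A `bcc_palette` (required in `"ccm"` mode; its viewing
#'   conditions also govern the L* conversion in `"glcm"` mode when given).
#' @param mode `"ccm"` or `"glcm"`.
#' @param spec An [offset_spec()]; its offsets are analysed one at a time.
#' @param levels,value_range GLCM binning (ignored in `"ccm"` mode).
#' @param correlation_denominator Passed to the feature statistics.
#' @param per_offset If `TRUE`, attach the per-direction records as an
#'   attribute `"per_offset"`.
#' @return Named numeric record: `homogeneity, mean_1..3, variance,
#'   correlation, entropy` for `"ccm"`; `homogeneity, mean, variance,
#'   correlation, entropy` for `"glcm"`.
#' @export
image_features <- function(img, palette = NULL, mode = c("ccm", "glcm"),
                           spec = offset_spec(), levels = 32,
                           value_range = c(0, 100),
                           correlation_denominator = "sigma_product",
                           per_offset = FALSE) {
  mode <- match.arg(mode)
  one_dir <- function(off) offset_spec(matrix(off, ncol = 2L),
                                       symmetric = spec$symmetric)
  if (mode == "ccm") {
    if (!inherits(palette, "bcc_palette")) stop("`ccm` mode needs a palette")
    q <- quantize(img, palette)
    per <- apply(spec$offsets, 1L, function(off) {
      .feature_record(ccm_features(compute_ccm(q, one_dir(off)),
                                   correlation_denominator))
    })
  } else {
    vc <- if (inherits(palette, "bcc_palette")) palette$vc else viewing_conditions()
    lab <- srgb_to_working(.flatten_image(img), space = "lab", vc = vc)
    L <- matrix(lab[, 1L], dim(img)[1L], dim(img)[2L])
    per <- apply(spec$offsets, 1L, function(off) {
      .feature_record(glcm_features(compute_glcm(L, levels, value_range,
                                                 one_dir(off)),
                                    correlation_denominator))
    })
  }
  rec <- rowMeans(per)
  if (per_offset) attr(rec, "per_offset") <- per
  rec
}

#' Feature table for a set of images
#'
#' @param images List of H x W x 3 sRGB arrays.
#' @param ... Passed on to [image_features()].
#' @return Data frame with `image_id` and one column per feature.
#' @export
feature_table <- function(images, ...) {
  recs <- t(vapply(images, image_features, image_features(images[[1L]], ...), ...))
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(images))
  data.frame(image_id = ids, recs, row.names = NULL)
}
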