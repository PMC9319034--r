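# Seeded generator of pattern-labelled synthetic dermoscopic-like tiles.
#
# Each of the seven dermoscopic patterns is emulated by a deliberately simple
# geometric motif drawn in that pattern's characteristic colours on a
# skin-toned background: a brown reticular mesh (pigment network), an
# irregular saturated red/white patch (ulceration), a few large blue-gray
# ellipses (ovoid nests), many small blue-gray discs (globules), lobed brown
# shapes along a border arc (maple leaf), lines radiating from a hub
# (spoke wheel) and red branching curves (telangiectasia). The goal is a
# testable planted structure for the colour/texture/classification machinery,
# not photorealism.

#' Recipe for one synthetic pattern motif
#'
#' @param pattern One of [bcc_patterns()].
#' @param motif Motif name; fixed one-to-one with the pattern by default.
#' @param fg_colors List of sRGB triples the motif draws from.
#' @param bg_color Background sRGB triple (skin tone).
#' @param density Relative element count multiplier (0 disables the motif).
#' @param scale Relative element size multiplier.
#' @param noise_sd Gaussian channel noise standard deviation (clipped to
#'   `[0, 1]` after adding).
#' @return A `pattern_recipe` object.
#' @export
pattern_recipe <- function(pattern,
                           motif = NULL,
                           fg_colors = NULL,
                           bg_color = c(0.894, 0.737, 0.686),
                           density = 1, scale = 1, noise_sd = 0.02) {
  if (!pattern %in% bcc_patterns()) stop("unknown pattern: ", pattern)
  defaults <- .recipe_defaults()[[pattern]]
  if (is.null(motif)) motif <- defaults$motif
  if (is.null(fg_colors)) fg_colors <- defaults$fg_colors
  if (!is.list(fg_colors)) fg_colors <- list(fg_colors)
  if (length(fg_colors) < 1L) stop("fg_colors must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(pattern = pattern, motif = motif, fg_colors = fg_colors,
                 bg_color = as.numeric(bg_color), density = density,
                 scale = scale, noise_sd = noise_sd),
            class = "pattern_recipe")
}

# characteristic colours per pattern (qualitative: brown reticular lines,
# red/white erosion, blue-gray nests and globules, brown-gray leaflets,
# tan spokes, bright red vessels)
.recipe_defaults <- function() list(
  pigment_network = list(motif = "reticular_mesh",
                         fg_colors = list(c(0.478, 0.294, 0.141))),
  ulceration = list(motif = "erosion_patch",
                    fg_colors = list(c(0.698, 0.133, 0.133),
                                     c(0.930, 0.830, 0.720))),
  ovoid_nest = list(motif = "ovoid_blobs",
                    fg_colors = list(c(0.314, 0.392, 0.533))),
  multi_globules = list(motif = "scattered_globules",
                        fg_colors = list(c(0.471, 0.565, 0.682))),
  maple_leaf = list(motif = "leaflets",
                    fg_colors = list(c(0.549, 0.420, 0.361))),
  spoke_wheel = list(motif = "radial_spokes",
                     fg_colors = list(c(0.710, 0.502, 0.239))),
  telangiectasia = list(motif = "branching_lines",
                        fg_colors = list(c(0.753, 0.224, 0.169))))

#' Default recipes for all seven patterns
#' @return Named list of `pattern_recipe`s.
#' @export
default_recipes <- function() {
  stats::setNames(lapply(bcc_patterns(), pattern_recipe), bcc_patterns())
}

# ---- low-level drawing ------------------------------------------------------

.blank_tile <- function(size, bg, noise_sd) {
  h <- size[1L]; w <- size[2L]
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3L))
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(h * w * 3L, 0, noise_sd), dim = dim(img))
  }
  pmin(pmax(img, 0), 1)
}

# paint masked pixels with a colour plus slight per-pixel jitter
.paint <- function(img, mask, color, jitter = 0.03) {
  k <- sum(mask)
  if (k == 0L) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- pmin(pmax(color[ch] + stats::rnorm(k, 0, jitter), 0), 1)
    img[, , ch] <- plane
  }
  img
}

.grid_coords <- function(h, w) {
  list(rr = matrix(seq_len(h), h, w), cc = matrix(seq_len(w), h, w, byrow = TRUE))
}

.ellipse_mask <- function(h, w, cy, cx, ra, rb, theta = 0) {
  g <- .grid_coords(h, w)
  dy <- g$rr - cy; dx <- g$cc - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / ra)^2 + (v / rb)^2 <= 1
}

.disc_mask <- function(h, w, cy, cx, r) .ellipse_mask(h, w, cy, cx, r, r)

# pixels within `thick/2` of the segment p1 -> p2
.segment_mask <- function(h, w, p1, p2, thick) {
  g <- .grid_coords(h, w)
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) return(.disc_mask(h, w, p1[1L], p1[2L], thick / 2))
  t <- ((g$rr - p1[1L]) * d[1L] + (g$cc - p1[2L]) * d[2L]) / len2
  t <- pmin(pmax(t, 0), 1)
  py <- p1[1L] + t * d[1L]; px <- p1[2L] + t * d[2L]
  (g$rr - py)^2 + (g$cc - px)^2 <= (thick / 2)^2
}

.pick_color <- function(recipe) {
  recipe$fg_colors[[sample.int(length(recipe$fg_colors), 1L)]]
}

# ---- motif renderers (random state comes from the caller's seed) ------------

.draw_reticular_mesh <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  spacing <- max(6, s / (8 * recipe$density))
  thick <- max(1.2, s / 90) * recipe$scale
  amp <- spacing / 3
  per <- s / stats::runif(1, 3, 5)
  ph <- stats::runif(2, 0, 2 * pi)
  g <- .grid_coords(h, w)
  mv <- (g$cc + amp * sin(g$rr / per * 2 * pi + ph[1L])) %% spacing
  mh <- (g$rr + amp * sin(g$cc / per * 2 * pi + ph[2L])) %% spacing
  mask <- (mv < thick) | (mh < thick)
  .paint(img, mask, .pick_color(recipe))
}

.draw_erosion_patch <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  cy <- h / 2 + stats::rnorm(1, 0, s / 10)
  cx <- w / 2 + stats::rnorm(1, 0, s / 10)
  r0 <- s * 0.22 * recipe$scale
  a <- stats::rnorm(4, 0, 0.12)
  phi <- stats::runif(4, 0, 2 * pi)
  g <- .grid_coords(h, w)
  dy <- g$rr - cy; dx <- g$cc - cx
  th <- atan2(dy, dx)
  rad <- sqrt(dy^2 + dx^2)
  rb <- r0 * (1 + a[1L] * sin(th + phi[1L]) + a[2L] * sin(2 * th + phi[2L]) +
                a[3L] * sin(3 * th + phi[3L]) + a[4L] * sin(4 * th + phi[4L]))
  outer_m <- rad <= rb
  core <- rad <= 0.55 * rb
  img <- .paint(img, outer_m, recipe$fg_colors[[1L]])
  if (length(recipe$fg_colors) > 1L) {
    img <- .paint(img, core, recipe$fg_colors[[2L]])
  }
  img
}

.draw_ovoid_blobs <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  n <- max(1L, round(4 * recipe$density))
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 0.2 * h, 0.8 * h)
    cx <- stats::runif(1, 0.2 * w, 0.8 * w)
    ra <- s * stats::runif(1, 0.08, 0.14) * recipe$scale
    rb <- ra * stats::runif(1, 0.55, 0.9)
    mask <- .ellipse_mask(h, w, cy, cx, ra, rb, stats::runif(1, 0, pi))
    img <- .paint(img, mask, .pick_color(recipe))
  }
  img
}

.draw_scattered_globules <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  n <- max(1L, round(30 * recipe$density))
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 0.1 * h, 0.9 * h)
    cx <- stats::runif(1, 0.1 * w, 0.9 * w)
    r <- max(1.5, s * stats::runif(1, 0.012, 0.025) * recipe$scale)
    img <- .paint(img, .disc_mask(h, w, cy, cx, r), .pick_color(recipe))
  }
  img
}

.draw_leaflets <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  n <- max(2L, round(6 * recipe$density))
  arc0 <- stats::runif(1, 0, 2 * pi)
  R <- s * 0.33
  for (i in seq_len(n)) {
    ang <- arc0 + (i - 1) * stats::runif(1, 0.25, 0.4)
    cy <- h / 2 + R * sin(ang)
    cx <- w / 2 + R * cos(ang)
    ra <- s * stats::runif(1, 0.045, 0.07) * recipe$scale
    mask <- .ellipse_mask(h, w, cy, cx, ra, ra * stats::runif(1, 0.5, 0.8),
                          ang + pi / 2)
    img <- .paint(img, mask, .pick_color(recipe))
  }
  img
}

.draw_radial_spokes <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  n <- max(3L, round(10 * recipe$density))
  cy <- stats::runif(1, 0.35 * h, 0.65 * h)
  cx <- stats::runif(1, 0.35 * w, 0.65 * w)
  len <- s * 0.2 * recipe$scale
  thick <- max(1.5, s / 70)
  col <- .pick_color(recipe)
  for (i in seq_len(n)) {
    ang <- 2 * pi * i / n + stats::rnorm(1, 0, 0.08)
    p2 <- c(cy + len * sin(ang), cx + len * cos(ang))
    img <- .paint(img, .segment_mask(h, w, c(cy, cx), p2, thick), col)
  }
  .paint(img, .disc_mask(h, w, cy, cx, s * 0.04 * recipe$scale), col)
}

.draw_branching_lines <- function(img, recipe) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  s <- min(h, w)
  thick <- max(1.2, s / 110)
  col <- .pick_color(recipe)
  n_trees <- max(1L, round(2 * recipe$density))
  for (tree in seq_len(n_trees)) {
    p <- c(stats::runif(1, 0.25 * h, 0.75 * h), stats::runif(1, 0.25 * w, 0.75 * w))
    ang <- stats::runif(1, 0, 2 * pi)
    stack <- list(list(p = p, ang = ang, depth = 0L))
    while (length(stack) > 0L) {
      node <- stack[[1L]]; stack <- stack[-1L]
      len <- s * 0.11 * recipe$scale * 0.85^node$depth
      p2 <- node$p + len * c(sin(node$ang), cos(node$ang))
      img <- .paint(img, .segment_mask(h, w, node$p, p2,
                                       thick * 0.9^node$depth), col)
      if (node$depth < 3L) {
        for (dd in c(-1, 1)) {
          stack[[length(stack) + 1L]] <- list(
            p = p2, ang = node$ang + dd * stats::runif(1, 0.3, 0.7),
            depth = node$depth + 1L)
        }
      }
    }
  }
  img
}

.motif_renderers <- function() list(
  reticular_mesh = .draw_reticular_mesh,
  erosion_patch = .draw_erosion_patch,
  ovoid_blobs = .draw_ovoid_blobs,
  scattered_globules = .draw_scattered_globules,
  leaflets = .draw_leaflets,
  radial_spokes = .draw_radial_spokes,
  branching_lines = .draw_branching_lines)

# ---- public generator -------------------------------------------------------

.one_hot <- function(patterns) {
  y <- stats::setNames(rep(0L, 7L), bcc_patterns())
  y[patterns] <- 1L
  y
}

#' Generate one synthetic pattern tile
#'
#' Background filled with the recipe's skin tone plus Gaussian channel noise,
#' then the pattern's motif rendered with its foreground colours.
#' Deterministic given the seed; `density = 0` yields a motif-free tile whose
#' label is still the recipe's one-hot.
#'
#' @param recipe A [pattern_recipe()].
#' @param size `c(H, W)`, at least 32 x 32.
#' @param seed Integer seed.
#' @return List with `image` (H x W x 3 sRGB array) and `label` (named
#'   length-7 0/1 vector).
#' @export
make_pattern_image <- function(recipe, size = c(256, 256), seed = 1) {
  stopifnot(inherits(recipe, "pattern_recipe"))
  size <- rep(as.integer(size), length.out = 2L)
  if (any(size < 32L)) stop("tile size must be at least 32 x 32")
  set.seed(seed)
  img <- .blank_tile(size, recipe$bg_color, recipe$noise_sd)
  if (recipe$density > 0) {
    img <- .motif_renderers()[[recipe$motif]](img, recipe)
  }
  list(image = img, label = .one_hot(recipe$pattern))
}

#' Compose several pattern motifs on one tile
#'
#' Motifs are rendered sequentially on a single background (the first
#' recipe's); the label is the union of the recipes' one-hots.
#'
#' @param recipes List of [pattern_recipe()]s (at least one).
#' @param size,seed As in [make_pattern_image()].
#' @return List with `image` and the multilabel `label`.
#' @export
compose_multi_pattern <- function(recipes, size = c(256, 256), seed = 1) {
  if (inherits(recipes, "pattern_recipe")) recipes <- list(recipes)
  if (length(recipes) < 1L) stop("need at least one recipe")
  size <- rep(as.integer(size), length.out = 2L)
  if (any(size < 32L)) stop("tile size must be at least 32 x 32")
  set.seed(seed)
  img <- .blank_tile(size, recipes[[1L]]$bg_color, recipes[[1L]]$noise_sd)
  for (rc in recipes) {
    if (rc$density > 0) img <- .motif_renderers()[[rc$motif]](img, rc)
  }
  list(image = img,
       label = .one_hot(vapply(recipes, `[[`, character(1L), "pattern")))
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_per_pattern` single-pattern tiles per pattern, plus a
#' configurable fraction of two-pattern composites and (optionally)
#' pattern-free "benign" tiles. Fully reproducible from the seed.
#'
#' @param n_per_pattern Singles per pattern (>= 1).
#' @param size Tile size `c(H, W)`.
#' @param seed Integer seed.
#' @param include_nonbcc Include pattern-free tiles (default `TRUE`).
#' @param composite_frac Composites as a fraction of the 7 x n singles
#'   (default 0.2; 0 disables).
#' @param benign_frac Pattern-free tiles as a fraction of the singles
#'   (default 0.2; only if `include_nonbcc`).
#' @param recipes Named list of recipes (default [default_recipes()]).
#' @return List of class `synthetic_dataset`: `images` (list of arrays),
#'   `labels` (n x 7 integer matrix), `ids`, `seed`, `recipes`.
#' @export
make_dataset <- function(n_per_pattern = 50, size = c(256, 256), seed = 1,
                         include_nonbcc = TRUE, composite_frac = 0.2,
                         benign_frac = 0.2, recipes = default_recipes()) {
  if (n_per_pattern < 1L) stop("n_per_pattern must be at least 1")
  patterns <- bcc_patterns()
  n_comp <- round(composite_frac * 7 * n_per_pattern)
  n_ben <- if (include_nonbcc) round(benign_frac * 7 * n_per_pattern) else 0L
  total <- 7L * n_per_pattern + n_comp + n_ben
  set.seed(seed)
  tile_seeds <- sample.int(2^31 - 1, total)
  comp_pairs <- replicate(max(n_comp, 1L), sample(patterns, 2L),
                          simplify = FALSE)

  images <- vector("list", total)
  labels <- matrix(0L, total, 7L, dimnames = list(NULL, patterns))
  ids <- character(total)
  i <- 0L
  for (p in patterns) for (k in seq_len(n_per_pattern)) {
    i <- i + 1L
    out <- make_pattern_image(recipes[[p]], size, tile_seeds[i])
    images[[i]] <- out$image; labels[i, ] <- out$label
    ids[i] <- sprintf("%s_%03d", p, k)
  }
  for (k in seq_len(n_comp)) {
    i <- i + 1L
    pair <- comp_pairs[[k]]
    out <- compose_multi_pattern(recipes[pair], size, tile_seeds[i])
    images[[i]] <- out$image; labels[i, ] <- out$label
    ids[i] <- sprintf("composite_%03d", k)
  }
  for (k in seq_len(n_ben)) {
    i <- i + 1L
    rc <- pattern_recipe("pigment_network", density = 0)
    out <- make_pattern_image(rc, size, tile_seeds[i])
    images[[i]] <- out$image  # label stays all-zero: pattern-free tile
    ids[i] <- sprintf("benign_%03d", k)
  }
  structure(list(images = images, labels = labels, ids = ids, seed = seed,
                 recipes = recipes),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d tiles (%d x %d), seed %d\n",
              length(x$images), dim(x$images[[1L]])[1L],
              dim(x$images[[1L]])[2L], x$seed))
  print(colSums(x$labels))
  invisible(x)
}

# 90-degree rotation and flips of an H x W x 3 array
.rot90_img <- function(img) {
  out <- array(0, dim = c(dim(img)[2L], dim(img)[1L], 3L))
  for (ch in 1:3) out[, , ch] <- t(img[dim(img)[1L]:1, , ch])
  out
}
.flip_h <- function(img) img[, dim(img)[2L]:1, , drop = FALSE]
.flip_v <- function(img) img[dim(img)[1L]:1, , , drop = FALSE]

#' Rotation/flip data augmentation
#'
#' For each input tile emits four variants — the original and its 90, 180 and
#' 270 degree rotations — multiplying the set size exactly by 4; each variant
#' is then independently flipped horizontally and/or vertically with
#' probability one half (seeded). Labels are duplicated unchanged. No colour
#' transformation is applied: the diagnosis is colour-based, so colour jitter
#' would corrupt the labels.
#'
#' @param images List of H x W x 3 arrays (or a `synthetic_dataset`).
#' @param labels Optional n x 7 label matrix to duplicate alongside.
#' @param seed Integer seed for the random flips.
#' @return List with `images` (length 4n) and `labels` (or `NULL`).
#' @export
augment <- function(images, labels = NULL, seed = 1) {
  if (inherits(images, "synthetic_dataset")) {
    labels <- images$labels
    images <- images$images
  }
  set.seed(seed)
  n <- length(images)
  out <- vector("list", 4L * n)
  keep <- integer(4L * n)
  j <- 0L
  for (i in seq_len(n)) {
    variant <- images[[i]]
    for (rot in 0:3) {
      if (rot > 0) variant <- .rot90_img(variant)
      v <- variant
      if (stats::runif(1) < 0.5) v <- .flip_h(v)
      if (stats::runif(1) < 0.5) v <- .flip_v(v)
      j <- j + 1L
      out[[j]] <- v
      keep[j] <- i
    }
  }
  list(images = out,
       labels = if (is.null(labels)) NULL else labels[keep, , drop = FALSE])
}

#' Read / write image tiles as PNG
#'
#' Thin wrappers over the `png` package for the command-line interface.
#'
#' @param path PNG file path.
#' @return For `read_tile`, an H x W x 3 array in `[0, 1]`.
#' @export
read_tile <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) stop("needs the `png` package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_tile
#' @param img H x W x 3 array in `[0, 1]`.
#' @export
write_tile <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) stop("needs the `png` package")
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
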