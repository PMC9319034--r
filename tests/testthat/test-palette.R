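# Two-step perceptual palette learning and nearest-centroid quantization.

test_that("K-means recovers planted colour clusters", {
  set.seed(10)
  m1 <- c(20, 5, -10); m2 <- c(70, -15, 25)
  px <- rbind(sweep(matrix(rnorm(300 * 3, sd = 0.5), ncol = 3), 2, m1, "+"),
              sweep(matrix(rnorm(200 * 3, sd = 0.5), ncol = 3), 2, m2, "+"))
  cs <- cluster_pattern_colors(px, k = 2, seed = 4)
  d <- apply(cs$colors, 1, function(cc) min(sqrt(sum((cc - m1)^2)),
                                            sqrt(sum((cc - m2)^2))))
  expect_true(all(d < 1))
  expect_setequal(cs$weights, c(300, 200))
  # assignment invariant: each pixel nearest its own centroid
  idx <- nearest_centroid(px, cs$colors)
  heavier <- which.max(cs$weights)
  expect_equal(sum(idx == heavier), 300)
})

test_that("constant input clusters to its single colour", {
  px <- matrix(rep(c(10, 2, 3), each = 50), ncol = 3)
  cs <- cluster_pattern_colors(px, k = 1, seed = 1)
  expect_equal(unname(cs$colors[1, ]), c(10, 2, 3))
  expect_equal(cs$weights, 50)
  expect_error(cluster_pattern_colors(px, k = 2, seed = 1), "distinct")
})

test_that("identical seeds give identical clusterings", {
  set.seed(20)
  px <- matrix(runif(900, 0, 100), ncol = 3)
  a <- cluster_pattern_colors(px, k = 5, seed = 77)
  b <- cluster_pattern_colors(px, k = 5, seed = 77)
  expect_identical(a$colors, b$colors)
  expect_identical(a$weights, b$weights)
})

test_that("merge_step follows the threshold graph and conserves weight", {
  # three collinear colours at Delta E spacings (2, 10)
  cols <- rbind(c(0, 0, 0), c(2, 0, 0), c(12, 0, 0))
  cs <- dermccm:::.centroid_set(cols, matrix(0.5, 3, 3), c(1, 3, 2),
                                list("a", "b", "c"))
  merged <- merge_step(cs, threshold = 5)
  expect_equal(nrow(merged$colors), 2)
  expect_equal(unname(merged$colors[1, ]), c(1.5, 0, 0))  # weighted mean
  expect_equal(merged$weights, c(4, 2))
  expect_equal(sum(merged$weights), sum(cs$weights))
  expect_setequal(merged$sources[[1]], c("a", "b"))
  # threshold below all pairwise distances: unchanged
  none <- merge_step(cs, threshold = 1)
  expect_equal(none$colors, cols, ignore_attr = TRUE)
  # threshold above all: single global weighted mean
  all1 <- merge_step(cs, threshold = 100)
  expect_equal(nrow(all1$colors), 1)
  expect_equal(unname(all1$colors[1, ]),
               c(sum(cols[, 1] * c(1, 3, 2)) / 6, 0, 0))
})

test_that("build_master_palette hits the target size exactly", {
  set.seed(30)
  for (rep in 1:10) {
    n_in <- sample(25:60, 1)
    target <- sample(5:20, 1)
    cs <- dermccm:::.centroid_set(matrix(runif(n_in * 3, 0, 100), ncol = 3),
                                  matrix(runif(n_in * 3), ncol = 3),
                                  runif(n_in, 1, 10),
                                  as.list(rep(NA_character_, n_in)))
    pal <- build_master_palette(cs, target_n = target, space = "lab")
    expect_equal(palette_size(pal), target)
    expect_equal(sum(pal$weights), sum(cs$weights), tolerance = 1e-9)
  }
})

test_that("master palette merging handles edge cases", {
  cols <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0), c(0, 0, 50))
  cs <- dermccm:::.centroid_set(cols, matrix(0.2, 4, 3), rep(1, 4),
                                as.list(letters[1:4]))
  # target equal to the input count: identity
  pal <- build_master_palette(cs, target_n = 4, space = "lab")
  expect_equal(pal$colors, cols, ignore_attr = TRUE)
  expect_error(build_master_palette(cs, target_n = 5), "exceeds")
  # exact duplicates always merge first, weights add
  cs2 <- dermccm:::.centroid_set(rbind(cols, c(0, 0, 0)),
                                 matrix(0.2, 5, 3), c(1, 1, 1, 1, 3),
                                 as.list(letters[1:5]))
  pal2 <- build_master_palette(cs2, target_n = 4, space = "lab")
  expect_equal(palette_size(pal2), 4)
  i0 <- which(apply(pal2$colors, 1, function(r) all(r == 0)))
  expect_equal(pal2$weights[i0], 4)
  expect_setequal(pal2$sources[[i0]], c("a", "e"))
})

test_that("quantization agrees with the exhaustive distance scan", {
  set.seed(40)
  centers <- matrix(runif(8 * 3, 0, 100), ncol = 3)
  pal <- hand_palette(centers, space = "lab")
  img <- random_tile(16, 16, seed = 41)
  q <- quantize(img, pal)
  wp <- srgb_to_working(matrix(img, ncol = 3), "lab")
  expected <- apply(wp, 1, function(p) {
    which.min(sqrt(colSums((t(centers) - p)^2)))
  })
  expect_identical(as.integer(q$indices), as.integer(expected))
  expect_true(all(q$indices >= 1 & q$indices <= 8))
})

test_that("quantization ties break to the lowest palette index", {
  centers <- rbind(c(0, 0, 0), c(0, 0, 0), c(90, 0, 0))
  expect_identical(nearest_centroid(rbind(c(0, 0, 0), c(1, 0, 0)), centers),
                   c(1L, 1L))
})

test_that("constant images quantize to a constant index map", {
  pal <- hand_palette(matrix(c(10, 0, 0, 80, 0, 0), 2, byrow = TRUE), "lab")
  img <- array(rep(c(0.9, 0.9, 0.9), each = 64), dim = c(8, 8, 3))
  q <- quantize(img, pal)
  expect_true(all(q$indices == q$indices[1, 1]))
})

test_that("rendering round-trips through quantization", {
  set.seed(50)
  cols <- matrix(runif(5 * 3, c(20, -30, -30), c(90, 30, 30)), ncol = 3,
                 byrow = TRUE)
  pal <- new_palette(cols, working_to_srgb(cols, "lab"), space = "lab")
  idx <- matrix(sample.int(5, 48, replace = TRUE), 6, 8)
  q <- quantized_from_indices(idx, pal)
  img <- render_quantized(q)
  expect_equal(dim(img), c(6, 8, 3))
  q2 <- quantize(img, pal)
  expect_identical(q2$indices, idx)
  # relabeling invariance: permuting palette + indices renders identically
  perm <- sample(5)
  pal_p <- new_palette(cols[perm, ], pal$srgb[perm, ], space = "lab")
  idx_p <- matrix(match(idx, perm), 6, 8)
  expect_equal(render_quantized(quantized_from_indices(idx_p, pal_p)), img)
})

test_that("palette JSON round trip is lossless and validates its schema", {
  set.seed(60)
  cols <- matrix(rnorm(9, 50, 20), 3)
  pal <- new_palette(cols, matrix(runif(9), 3), weights = c(5, 2.5, 1),
                     sources = list("ulceration", c("maple_leaf", "ovoid_nest"),
                                    "telangiectasia"),
                     space = "cam16ucs", threshold = 3.25)
  f <- withr::local_tempfile(fileext = ".json")
  write_palette(pal, f)
  pal2 <- read_palette(f)
  expect_identical(pal$colors, pal2$colors)
  expect_identical(pal$srgb, pal2$srgb)
  expect_identical(pal$weights, pal2$weights)
  expect_identical(pal$threshold, pal2$threshold)
  expect_identical(lapply(pal$sources, sort), lapply(pal2$sources, sort))
  expect_identical(pal$space, pal2$space)

  bad <- jsonlite::read_json(f)
  bad$space <- "hsv"
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(read_palette(f2), "space")

  bad2 <- jsonlite::read_json(f)
  bad2$centroids[[2]]$color <- NULL
  jsonlite::write_json(bad2, f2, auto_unbox = TRUE)
  expect_error(read_palette(f2), "color")
})

test_that("a hand-written two-colour palette file loads and quantizes", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "space": "lab",
    "centroids": [
      {"color": [30, 10, 5], "srgb": [0.3, 0.2, 0.2], "weight": 1, "sources": ["ulceration"]},
      {"color": [85, 0, 0], "srgb": [0.85, 0.83, 0.82], "weight": 2, "sources": []}
    ]
  }', f)
  pal <- read_palette(f)
  expect_equal(palette_size(pal), 2)
  q <- quantize(random_tile(8, 8, seed = 3), pal)
  expect_true(all(q$indices %in% 1:2))
})
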