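# GLCM and the Delta-E-weighted colour co-occurrence matrix with its five
# texture statistics, cross-checked against brute-force pair enumeration and
# a literal double-loop transcription of the formulas.

axial_offsets <- function() matrix(c(0L, 1L, -1L, 0L), ncol = 2, byrow = TRUE)

test_that("GLCM of a tiny image matches hand enumeration", {
  gray <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  m <- compute_glcm(gray, levels = 2, value_range = c(0, 1),
                    spec = offset_spec(matrix(c(0L, 1L), 1), symmetric = TRUE))
  expect_equal(m$P, matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(sum(m$P), 1)
  expect_identical(m$P, t(m$P))
})

test_that("a constant image concentrates all mass on one diagonal cell", {
  m <- compute_glcm(matrix(42, 6, 6), levels = 8, value_range = c(0, 100))
  expect_equal(sum(diag(m$P)), 1)
  expect_equal(sum(m$P > 0), 1)
  f <- glcm_features(m)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$variance, 0)
  expect_equal(f$correlation, 0)  # sigma = 0 convention
  expect_equal(f$entropy, 0)
})

test_that("checkerboard entropy is ln 2 under axial symmetric offsets", {
  board <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  m <- compute_glcm(board, levels = 2, value_range = c(0, 1),
                    spec = offset_spec(axial_offsets(), symmetric = TRUE))
  expect_equal(glcm_features(m)$entropy, log(2))
  expect_equal(unname(diag(m$P)), c(0, 0))
})

test_that("co-occurrence counts equal brute-force pair enumeration", {
  set.seed(70)
  for (rep in 1:30) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    n <- sample(2:6, 1)
    idx <- matrix(sample.int(n, h * w, replace = TRUE), h, w)
    offs <- haralick_offsets()[sample(1:4, sample(1:4, 1)), , drop = FALSE]
    sym <- sample(c(TRUE, FALSE), 1)
    pal <- hand_palette(matrix(runif(n * 3, 0, 100), ncol = 3), "lab")
    m <- compute_ccm(quantized_from_indices(idx, pal),
                     offset_spec(offs, symmetric = sym))
    oc <- oracle_cooc_counts(idx, n, offs, symmetric = sym)
    expect_identical(m$counts, oc)
    expect_equal(sum(m$P), 1, tolerance = 1e-9)
    if (sym) expect_identical(m$P, t(m$P))
  }
})

test_that("offsets larger than the image raise an error", {
  idx <- matrix(1L, 2, 2)
  pal <- hand_palette(matrix(runif(6, 0, 100), 2), "lab")
  expect_error(compute_ccm(quantized_from_indices(idx, pal),
                           offset_spec(matrix(c(0L, 5L), 1))),
               "smaller than offset")
  expect_error(offset_spec(matrix(c(0L, 0L), 1)), "not allowed")
})

test_that("two-colour stripes put all CCM mass off the diagonal", {
  pal <- hand_palette(rbind(c(10, 0, 0), c(60, 0, 0)), "lab")
  idx <- matrix(rep(c(1L, 2L), 4), 4, 8, byrow = TRUE)[, 1:8]
  m <- compute_ccm(quantized_from_indices(idx, pal),
                   offset_spec(matrix(c(0L, 1L), 1), symmetric = TRUE))
  expect_equal(m$P[1, 2], 0.5)
  expect_equal(m$P[2, 1], 0.5)
  expect_equal(sum(diag(m$P)), 0)
})

test_that("the centroid distance table is a valid Delta E table", {
  set.seed(71)
  cols <- matrix(runif(15, 0, 100), 5)
  pal <- hand_palette(cols, "cam16ucs")
  D <- ccm_distance_table(pal)
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_identical(D, t(D))
  expect_equal(D[2, 4], delta_e_ucs(cols[2, ], cols[4, ]))
  expect_equal(D[1, 3], delta_e_lab(cols[1, ], cols[3, ]))  # both Euclidean
})

test_that("CCM features of a constant image follow the conventions", {
  pal <- hand_palette(matrix(runif(12, 0, 100), 4), "lab")
  idx <- matrix(3L, 7, 7)
  f <- ccm_features(compute_ccm(quantized_from_indices(idx, pal)))
  expect_equal(f$homogeneity, 1)
  expect_equal(unname(f$mean), unname(pal$colors[3, ]))
  expect_equal(f$variance, 0)
  expect_equal(f$correlation, 0)
  expect_equal(f$entropy, 0)  # entropy of a constant image is 0
})

test_that("checkerboard CCM features match the closed-form table", {
  c1 <- c(20, 0, 0); c2 <- c(20 + 8, 0, 0)  # Delta E = 8
  pal <- hand_palette(rbind(c1, c2), "lab")
  idx <- outer(1:8, 1:8, function(i, j) (i + j) %% 2L) + 1L
  m <- compute_ccm(quantized_from_indices(idx, pal),
                   offset_spec(axial_offsets(), symmetric = TRUE))
  # P has the two off-diagonal cells at 0.5 each
  expect_equal(m$P[1, 2], 0.5)
  f <- ccm_features(m)
  d <- 8
  expect_equal(f$homogeneity, 1 / (1 + d^2))
  expect_equal(unname(f$mean), (c1 + c2) / 2)
  expect_equal(f$variance, (d / 2)^2)
  expect_equal(f$correlation, 1)
  expect_equal(f$entropy, log(2))
})

test_that("both feature sets match the literal double-loop transcription", {
  set.seed(72)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    idx <- matrix(sample.int(n, 64, replace = TRUE), 8, 8)
    cols <- matrix(runif(n * 3, 0, 100), ncol = 3)
    pal <- hand_palette(cols, "lab")
    m <- compute_ccm(quantized_from_indices(idx, pal))
    f <- ccm_features(m)
    o <- oracle_cooc_features(m$P,
                              dist_fun = function(i, j) sqrt(sum((cols[i, ] - cols[j, ])^2)),
                              coord = function(i) cols[i, ])
    expect_equal(f$homogeneity, o$homogeneity)
    expect_equal(unname(f$mean), unname(o$mean))
    expect_equal(f$variance, o$variance)
    expect_equal(f$correlation, o$correlation)
    expect_equal(f$entropy, o$entropy)

    g <- compute_glcm(matrix(runif(64, 0, 100), 8), levels = 6)
    fg <- glcm_features(g)
    og <- oracle_cooc_features(g$P, function(i, j) abs(i - j),
                               function(i) i)
    expect_equal(fg$homogeneity, og$homogeneity)
    expect_equal(fg$mean, og$mean)
    expect_equal(fg$variance, og$variance)
    expect_equal(fg$correlation, og$correlation)
    expect_equal(fg$entropy, og$entropy)
  }
})

test_that("feature ranges respect their analytic bounds", {
  set.seed(73)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    idx <- matrix(sample.int(n, 100, replace = TRUE), 10, 10)
    pal <- hand_palette(matrix(runif(n * 3, 0, 100), ncol = 3), "lab")
    f <- ccm_features(compute_ccm(quantized_from_indices(idx, pal)))
    expect_gt(f$homogeneity, 0)
    expect_lte(f$homogeneity, 1)
    expect_gte(f$variance, 0)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, log(n^2))
  }
})

test_that("features are invariant to palette relabeling", {
  set.seed(74)
  n <- 6
  cols <- matrix(runif(n * 3, 0, 100), ncol = 3)
  srgb <- matrix(runif(n * 3), ncol = 3)
  idx <- matrix(sample.int(n, 144, replace = TRUE), 12, 12)
  pal <- new_palette(cols, srgb, space = "lab")
  f <- ccm_features(compute_ccm(quantized_from_indices(idx, pal)))
  perm <- sample(n)
  pal_p <- new_palette(cols[perm, ], srgb[perm, ], space = "lab")
  idx_p <- matrix(match(idx, perm), 12, 12)
  f_p <- ccm_features(compute_ccm(quantized_from_indices(idx_p, pal_p)))
  for (k in c("homogeneity", "variance", "correlation", "entropy")) {
    expect_lt(abs(f[[k]] - f_p[[k]]), 1e-12)
  }
  expect_equal(unname(f$mean), unname(f_p$mean), tolerance = 1e-12)
})

test_that("GLCM features reduce to CCM features on a unit-spaced gray ramp", {
  n <- 5L
  # palette of gray centroids spaced exactly 1 apart in working space
  pal <- hand_palette(cbind(seq_len(n), 0, 0), "lab")
  set.seed(75)
  idx <- matrix(sample.int(n, 80, replace = TRUE), 8, 10)
  fc <- ccm_features(compute_ccm(quantized_from_indices(idx, pal)))
  # gray image whose uniform bins reproduce the same index map
  gray <- (idx - 0.5) / n * 100
  fg <- glcm_features(compute_glcm(gray, levels = n))
  expect_equal(fc$homogeneity, fg$homogeneity)
  expect_equal(fc$variance, fg$variance)
  expect_equal(fc$correlation, fg$correlation)
  expect_equal(fc$entropy, fg$entropy)
  expect_equal(fc$mean[1], fg$mean)  # ramp coordinate = bin index
})

test_that("the printed sigma-squared correlation variant is exposed", {
  set.seed(76)
  n <- 4
  idx <- matrix(sample.int(n, 64, replace = TRUE), 8, 8)
  pal <- hand_palette(matrix(runif(n * 3, 0, 100), ncol = 3), "lab")
  m <- compute_ccm(quantized_from_indices(idx, pal))
  f1 <- ccm_features(m, correlation_denominator = "sigma_product")
  f2 <- ccm_features(m, correlation_denominator = "sigma_squared_product")
  s <- f1$marginals$sigma_row * f1$marginals$sigma_col
  expect_equal(f2$correlation, f1$correlation / s)
})

test_that("image feature records average directions and resist rotation", {
  img <- random_tile(12, 12, seed = 77)
  pal <- hand_palette(matrix(runif(4 * 3, 0, 100), ncol = 3), "lab")
  f <- image_features(img, pal, mode = "ccm")
  expect_named(f, c("homogeneity", "mean_1", "mean_2", "mean_3", "variance",
                    "correlation", "entropy"))
  # 90-degree rotation with the closed 4-direction offset set
  rot <- dermccm:::.rot90_img(img)
  expect_equal(image_features(rot, pal, mode = "ccm"), f, tolerance = 1e-9)
  fg <- image_features(img, mode = "glcm")
  expect_named(fg, c("homogeneity", "mean", "variance", "correlation",
                     "entropy"))
  expect_equal(image_features(rot, mode = "glcm"), fg, tolerance = 1e-9)
})

test_that("constant tiles give the constant-image record in both modes", {
  img <- array(rep(c(0.55, 0.4, 0.35), each = 100), dim = c(10, 10, 3))
  pal <- hand_palette(matrix(runif(9, 0, 100), 3), "lab")
  f <- image_features(img, pal, mode = "ccm")
  expect_equal(unname(f[c("homogeneity", "variance", "correlation", "entropy")]),
               c(1, 0, 0, 0))
  fg <- image_features(img, mode = "glcm")
  expect_equal(unname(fg[c("homogeneity", "variance", "correlation", "entropy")]),
               c(1, 0, 0, 0))
})

test_that("the assembled record matches a manual pipeline of the parts", {
  pal <- hand_palette(rbind(c(20, 0, 0), c(70, 10, -5)), "lab",
                      srgb = rbind(c(0.2, 0.2, 0.2), c(0.7, 0.6, 0.6)))
  img <- render_quantized(quantized_from_indices(
    matrix(rep(c(1L, 2L), 18), 6, 6), pal))
  rec <- image_features(img, pal, mode = "ccm")
  q <- quantize(img, pal)
  manual <- sapply(seq_len(4), function(r) {
    f <- ccm_features(compute_ccm(q, offset_spec(haralick_offsets()[r, , drop = FALSE])))
    c(f$homogeneity, f$mean, f$variance, f$correlation, f$entropy)
  })
  expect_equal(unname(rec), unname(rowMeans(manual)))
})
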