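# Independent oracles used to cross-check the package implementation.
# These are deliberately naive (scalar loops, pair enumeration) and share no
# code with the R/ implementation.

# brute-force co-occurrence counts: enumerate every pixel pair per offset
oracle_cooc_counts <- function(idx, n, offsets, symmetric = TRUE) {
  counts <- matrix(0, n, n)
  h <- nrow(idx); w <- ncol(idx)
  for (r in seq_len(nrow(offsets))) {
    dy <- offsets[r, 1L]; dx <- offsets[r, 2L]
    for (y in seq_len(h)) for (x in seq_len(w)) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 >= 1 && y2 <= h && x2 >= 1 && x2 <= w) {
        i <- idx[y, x]; j <- idx[y2, x2]
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts
}

# literal double-loop transcription of the five co-occurrence statistics;
# dist_fun(i, j) gives the level distance, coord(i) the level coordinate
oracle_cooc_features <- function(P, dist_fun, coord) {
  n <- nrow(P)
  H <- 0; S <- 0
  mu <- 0 * coord(1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    H <- H + P[i, j] / (1 + dist_fun(i, j)^2)
    mu <- mu + coord(i) * P[i, j]
    if (P[i, j] > 0) S <- S - P[i, j] * log(P[i, j])
  }
  mu_col <- 0 * coord(1L)
  for (i in seq_len(n)) for (j in seq_len(n)) mu_col <- mu_col + coord(j) * P[i, j]
  de_row <- function(i) sqrt(sum((coord(i) - mu)^2))
  de_col <- function(j) sqrt(sum((coord(j) - mu_col)^2))
  v <- 0; s_row2 <- 0; s_col2 <- 0; num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- v + de_row(i)^2 * P[i, j]
    s_row2 <- s_row2 + de_row(i)^2 * P[i, j]
    num <- num + de_row(i) * de_col(j) * P[i, j]
  }
  for (j in seq_len(n)) s_col2 <- s_col2 + de_col(j)^2 * sum(P[, j])
  denom <- sqrt(s_row2) * sqrt(s_col2)
  rho <- if (denom <= 0) 0 else num / denom
  list(homogeneity = H, mean = mu, variance = v, correlation = rho,
       entropy = S)
}

# Mann-Whitney pair-counting AUC (ties counted one half)
oracle_auc <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# random sRGB tile
random_tile <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3L))
}

# quantized_image wrapper around an explicit index matrix (for texture tests)
quantized_from_indices <- function(idx, palette) {
  structure(list(indices = idx, palette = palette,
                 shape = dim(idx)),
            class = "quantized_image")
}

# small hand palette in working space; srgb is a display stand-in
hand_palette <- function(colors, space = "lab", srgb = NULL) {
  n <- nrow(colors)
  if (is.null(srgb)) srgb <- matrix(runif(n * 3), n, 3)
  new_palette(colors, srgb, weights = rep(1, n), space = space)
}
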