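# Forward colorimetry: sRGB -> XYZ -> {CIELAB, CIECAM16 -> CAM16-UCS} and the
# two perceptual colour-difference metrics used throughout the package.
#
# Conventions: XYZ is D65-relative on the 0-100 scale (Y of the adopted white
# is 100); colours are length-3 numeric vectors or N x 3 matrices, one colour
# per row. All transforms are vectorised over rows.

# IEC 61966-2-1 sRGB -> XYZ (D65, 2 deg observer), linear-light matrix
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

#' D65 reference white
#'
#' Tristimulus values of the CIE D65 illuminant (2 degree observer) on the
#' 0-100 scale used throughout the package.
#'
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
d65_white <- function() c(X = 95.047, Y = 100, Z = 108.883)

# Coerce a colour argument to an N x 3 matrix; remembers whether the input was
# a single colour so results can be dropped back to a vector.
.as_color_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(sprintf("`%s` must be a length-3 vector or an N x 3 matrix", arg))
    }
    x <- matrix(as.numeric(x), nrow = 1L)
    attr(x, "single") <- TRUE
  } else {
    if (ncol(x) != 3L) stop(sprintf("`%s` must have 3 columns", arg))
    x <- matrix(as.numeric(x), ncol = 3L, dimnames = NULL)
  }
  x
}

.drop_single <- function(m, x, names) {
  colnames(m) <- names
  if (isTRUE(attr(x, "single"))) {
    v <- m[1L, ]
    names(v) <- names
    return(v)
  }
  m
}

#' Convert sRGB to CIE XYZ
#'
#' Decodes the IEC 61966-2-1 piecewise sRGB gamma and applies the D65 linear
#' matrix. Channels must lie in the unit interval; 8-bit values should be
#' divided by 255 at the I/O boundary before calling.
#'
#' @param x Length-3 vector `c(r, g, b)` in `[0, 1]`, or an N x 3 matrix of
#'   such rows.
#' @return XYZ coordinates (0-100 scale), same shape as the input.
#' @examples
#' srgb_to_xyz(c(1, 1, 1))  # the D65 white, (95.047, 100, 108.883)
#' @export
srgb_to_xyz <- function(x) {
  m <- .as_color_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) stop("sRGB channels must be finite")
  if (any(m < 0) || any(m > 1)) stop("sRGB channels must lie in [0, 1]")
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- 100 * lin %*% t(.srgb_to_xyz_matrix)
  .drop_single(xyz, m, c("X", "Y", "Z"))
}

#' Convert CIE XYZ to CIELAB
#'
#' Standard CIE 1976 L*a*b* with the two-branch companding function (linear
#' below 216/24389).
#'
#' @param x XYZ colour(s) on the 0-100 scale (vector or N x 3 matrix).
#' @param white Reference white, default [d65_white()].
#' @return `c(L, a, b)` coordinates, same shape as the input.
#' @export
xyz_to_lab <- function(x, white = d65_white()) {
  m <- .as_color_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) stop("XYZ values must be finite")
  if (any(white <= 0)) stop("reference white must have positive components")
  eps <- 216 / 24389
  kap <- 24389 / 27
  t <- sweep(m, 2L, as.numeric(white), "/")
  f <- ifelse(t > eps, t^(1 / 3), (kap * t + 16) / 116)
  lab <- cbind(116 * f[, 2L] - 16,
               500 * (f[, 1L] - f[, 2L]),
               200 * (f[, 2L] - f[, 3L]))
  .drop_single(lab, m, c("L", "a", "b"))
}

#' CIELAB colour difference (Delta E*ab)
#'
#' Euclidean distance in (L*, a*, b*).
#'
#' @param c1,c2 CIELAB colour(s); vectors or conformable N x 3 matrices.
#' @return Non-negative distance(s).
#' @export
delta_e_lab <- function(c1, c2) {
  m1 <- .as_color_matrix(c1, "c1")
  m2 <- .as_color_matrix(c2, "c2")
  d <- sqrt(rowSums((m1 - m2)^2))
  if (isTRUE(attr(m1, "single")) && isTRUE(attr(m2, "single"))) d[[1L]] else d
}

#' Viewing conditions for the CIECAM16 model
#'
#' @param white Adopted white point (XYZ, 0-100 scale).
#' @param L_A Adapting field luminance in cd/m^2 (must be positive). The
#'   default 64 corresponds to typical office viewing of a display.
#' @param Y_b Relative background luminance in `(0, 100]`; 20 is the
#'   conventional "grey world" background.
#' @param surround One of `"average"`, `"dim"`, `"dark"`.
#' @param discount_illuminant If `TRUE` (default) the degree of adaptation D
#'   is forced to 1 (full chromatic adaptation), so the adopted white maps to
#'   a perfectly achromatic appearance; otherwise D follows the model's
#'   luminance-dependent formula, clamped to `[0, 1]`.
#' @return An object of class `viewing_conditions`.
#' @export
viewing_conditions <- function(white = d65_white(), L_A = 64, Y_b = 20,
                               surround = c("average", "dim", "dark"),
                               discount_illuminant = TRUE) {
  surround <- match.arg(surround)
  if (!is.numeric(L_A) || length(L_A) != 1L || !is.finite(L_A) || L_A <= 0) {
    stop("`L_A` must be a single positive number")
  }
  if (!is.numeric(Y_b) || length(Y_b) != 1L || Y_b <= 0 || Y_b > 100) {
    stop("`Y_b` must lie in (0, 100]")
  }
  white <- as.numeric(white)
  if (length(white) != 3L || any(!is.finite(white)) || any(white <= 0)) {
    stop("`white` must be a positive XYZ triple")
  }
  structure(list(white = white, L_A = L_A, Y_b = Y_b, surround = surround,
                 discount_illuminant = isTRUE(discount_illuminant)),
            class = "viewing_conditions")
}

#' @export
print.viewing_conditions <- function(x, ...) {
  cat(sprintf(
    "CIECAM16 viewing conditions: white (%.3f, %.3f, %.3f), L_A = %g cd/m^2, Y_b = %g, %s surround, D %s\n",
    x$white[1L], x$white[2L], x$white[3L], x$L_A, x$Y_b, x$surround,
    if (x$discount_illuminant) "= 1 (full adaptation)" else "luminance-derived"))
  invisible(x)
}

# surround parameters (c, Nc, F)
.cam16_surround <- function(surround) {
  switch(surround,
         average = c(c = 0.69, Nc = 1.0, F = 1.0),
         dim     = c(c = 0.59, Nc = 0.9, F = 0.9),
         dark    = c(c = 0.525, Nc = 0.8, F = 0.8))
}

# cone-like response matrix of CAM16 (shared by stimulus and white)
.cam16_M16 <- matrix(c(
  0.401288, 0.650173, -0.051461,
  -0.250268, 1.204414, 0.045854,
  -0.002079, 0.048952, 0.953127), nrow = 3, byrow = TRUE)

# model constants derived from the viewing conditions; cached per call chain
.cam16_params <- function(vc) {
  sur <- .cam16_surround(vc$surround)
  rgb_w <- as.numeric(.cam16_M16 %*% vc$white)
  D <- if (vc$discount_illuminant) 1 else {
    d <- sur[["F"]] * (1 - (1 / 3.6) * exp((-vc$L_A - 42) / 92))
    min(1, max(0, d))
  }
  D_rgb <- D * vc$white[2L] / rgb_w + 1 - D
  k <- 1 / (5 * vc$L_A + 1)
  F_L <- 0.2 * k^4 * 5 * vc$L_A + 0.1 * (1 - k^4)^2 * (5 * vc$L_A)^(1 / 3)
  n <- vc$Y_b / vc$white[2L]
  z <- 1.48 + sqrt(n)
  N_bb <- 0.725 * (1 / n)^0.2
  rgb_wc <- D_rgb * rgb_w
  x <- (F_L * rgb_wc / 100)^0.42
  rgb_aw <- 400 * x / (x + 27.13) + 0.1
  A_w <- (2 * rgb_aw[1L] + rgb_aw[2L] + rgb_aw[3L] / 20 - 0.305) * N_bb
  list(c = sur[["c"]], Nc = sur[["Nc"]], D_rgb = D_rgb, F_L = F_L, n = n,
       z = z, N_bb = N_bb, N_cb = N_bb, A_w = A_w)
}

# unique-hue data for the hue composition H
.cam16_hue_data <- list(h = c(20.14, 90, 164.25, 237.53, 380.14),
                        e = c(0.8, 0.7, 1.0, 1.2, 0.8),
                        H = c(0, 100, 200, 300, 400))

#' CIECAM16 forward transform
#'
#' Computes the seven appearance correlates of the CIECAM16 colour appearance
#' model: lightness J, chroma C, hue composition H, hue angle h (degrees),
#' colourfulness M, saturation s and brightness Q.
#'
#' @param x XYZ colour(s) on the 0-100 scale (vector or N x 3 matrix).
#' @param vc A [viewing_conditions()] object.
#' @return A named vector (single colour) or N x 7 matrix with columns
#'   `J, C, H, h, M, s, Q`.
#' @export
cam16_forward <- function(x, vc = viewing_conditions()) {
  if (!inherits(vc, "viewing_conditions")) stop("`vc` must be viewing_conditions()")
  m <- .as_color_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) stop("XYZ values must be finite")
  p <- .cam16_params(vc)

  rgb <- m %*% t(.cam16_M16)
  rgb_c <- sweep(rgb, 2L, p$D_rgb, "*")
  u <- (p$F_L * abs(rgb_c) / 100)^0.42
  rgb_a <- sign(rgb_c) * 400 * u / (u + 27.13) + 0.1

  a <- rgb_a[, 1L] - 12 * rgb_a[, 2L] / 11 + rgb_a[, 3L] / 11
  b <- (rgb_a[, 1L] + rgb_a[, 2L] - 2 * rgb_a[, 3L]) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  e_t <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)

  A <- (2 * rgb_a[, 1L] + rgb_a[, 2L] + rgb_a[, 3L] / 20 - 0.305) * p$N_bb
  J <- 100 * pmax(A / p$A_w, 0)^(p$c * p$z)
  Q <- (4 / p$c) * sqrt(J / 100) * (p$A_w + 4) * p$F_L^0.25
  t <- (50000 / 13) * p$Nc * p$N_cb * e_t * sqrt(a^2 + b^2) /
    (rgb_a[, 1L] + rgb_a[, 2L] + 21 / 20 * rgb_a[, 3L])
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^p$n)^0.73
  M <- C * p$F_L^0.25
  s <- ifelse(Q > 0, 100 * sqrt(M / Q), 0)

  # hue composition by linear interpolation between the unique hues
  hd <- .cam16_hue_data
  hp <- ifelse(h < hd$h[1L], h + 360, h)
  i <- findInterval(hp, hd$h)
  num <- (hp - hd$h[i]) / hd$e[i]
  H <- hd$H[i] + 100 * num / (num + (hd$h[i + 1L] - hp) / hd$e[i + 1L])

  out <- cbind(J, C, H, h, M, s, Q)
  .drop_single(out, m, c("J", "C", "H", "h", "M", "s", "Q"))
}

# coerce appearance input (named vector or matrix with J, M, h columns)
.as_appearance_matrix <- function(a) {
  if (is.null(dim(a))) {
    if (!all(c("J", "M", "h") %in% names(a))) {
      stop("appearance input needs named components J, M and h")
    }
    m <- matrix(c(a[["J"]], a[["M"]], a[["h"]]), nrow = 1L,
                dimnames = list(NULL, c("J", "M", "h")))
    attr(m, "single") <- TRUE
    m
  } else {
    if (!all(c("J", "M", "h") %in% colnames(a))) {
      stop("appearance input needs columns J, M and h")
    }
    cbind(J = a[, "J"], M = a[, "M"], h = a[, "h"])
  }
}

#' CAM16 appearance to CAM16-UCS coordinates
#'
#' Applies the uniform-colour-space compressions J' = 1.7 J / (1 + 0.007 J)
#' and M' = ln(1 + 0.0228 M) / 0.0228, with a' = M' cos(h), b' = M' sin(h).
#' M' is retained for traceability; `a'^2 + b'^2 = M'^2` by construction.
#'
#' @param a Output of [cam16_forward()] (named vector or matrix); only the
#'   J, M and h correlates are used.
#' @return `c(Jp, ap, bp, Mp)`, same shape convention as the input.
#' @export
cam16_to_ucs <- function(a) {
  m <- .as_appearance_matrix(a)
  Jp <- 1.7 * m[, "J"] / (1 + 0.007 * m[, "J"])
  Mp <- log(1 + 0.0228 * m[, "M"]) / 0.0228
  hr <- m[, "h"] * pi / 180
  out <- cbind(Jp, Mp * cos(hr), Mp * sin(hr), Mp)
  .drop_single(out, m, c("Jp", "ap", "bp", "Mp"))
}

#' CAM16-UCS colour difference (Delta E')
#'
#' Euclidean distance over (J', a', b').
#'
#' @param u1,u2 UCS colour(s): vectors `c(Jp, ap, bp)` (a fourth M' component
#'   is ignored) or conformable matrices.
#' @return Non-negative distance(s).
#' @export
delta_e_ucs <- function(u1, u2) {
  take3 <- function(u, arg) {
    if (is.null(dim(u))) {
      if (length(u) < 3L) stop(sprintf("`%s` needs at least (Jp, ap, bp)", arg))
      u <- u[1:3]
    } else {
      u <- u[, 1:3, drop = FALSE]
    }
    .as_color_matrix(u, arg)
  }
  m1 <- take3(u1, "u1")
  m2 <- take3(u2, "u2")
  d <- sqrt(rowSums((m1 - m2)^2))
  if (isTRUE(attr(m1, "single")) && isTRUE(attr(m2, "single"))) d[[1L]] else d
}

#' sRGB to working colour space
#'
#' Composes the forward transforms to map sRGB colours into one of the two
#' perceptually uniform working spaces used by the palette and texture
#' machinery: CIELAB `(L*, a*, b*)` or CAM16-UCS `(J', a', b')`. Euclidean
#' distance in either space is the corresponding Delta E.
#'
#' @param x sRGB colour(s) in `[0, 1]` (vector or N x 3 matrix).
#' @param space `"lab"` or `"cam16ucs"`.
#' @param vc Viewing conditions (used by the CAM16-UCS path; the CIELAB path
#'   uses its white point).
#' @return 3-column coordinates in the working space, same shape as input.
#' @export
srgb_to_working <- function(x, space = c("cam16ucs", "lab"),
                            vc = viewing_conditions()) {
  space <- match.arg(space)
  xyz <- srgb_to_xyz(x)
  if (space == "lab") {
    out <- xyz_to_lab(xyz, white = vc$white)
    if (is.null(dim(out))) names(out) <- c("L", "a", "b")
    return(out)
  }
  app <- cam16_forward(xyz, vc)
  ucs <- cam16_to_ucs(app)
  if (is.null(dim(ucs))) ucs[1:3] else ucs[, 1:3, drop = FALSE]
}

#' Working colour space to sRGB (display rendering)
#'
#' Inverse mapping used only to render palette centroids for display. The
#' CIELAB branch is analytic; the CAM16-UCS branch inverts the forward model
#' numerically (Nelder-Mead least squares in the UCS coordinates, seeded from
#' a CIELAB-based guess). Out-of-gamut results are clipped to `[0, 1]`.
#'
#' @param x Working-space colour(s) (vector or N x 3 matrix).
#' @param space `"lab"` or `"cam16ucs"`.
#' @param vc Viewing conditions.
#' @return sRGB colour(s) in `[0, 1]`.
#' @export
working_to_srgb <- function(x, space = c("cam16ucs", "lab"),
                            vc = viewing_conditions()) {
  space <- match.arg(space)
  m <- .as_color_matrix(x)
  lab_to_srgb <- function(lab) {
    fy <- (lab[, 1L] + 16) / 116
    fx <- fy + lab[, 2L] / 500
    fz <- fy - lab[, 3L] / 200
    eps <- 216 / 24389
    kap <- 24389 / 27
    finv <- function(f) ifelse(f^3 > eps, f^3, (116 * f - 16) / kap)
    xyz <- cbind(finv(fx), finv(fy), finv(fz))
    xyz <- sweep(xyz, 2L, vc$white, "*")
    lin <- xyz %*% t(solve(.srgb_to_xyz_matrix)) / 100
    lin <- pmin(pmax(lin, 0), 1)
    ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  }
  if (space == "lab") {
    out <- lab_to_srgb(m)
  } else {
    out <- matrix(0, nrow(m), 3L)
    for (i in seq_len(nrow(m))) {
      target <- m[i, 1:3]
      # seed the search from the CIELAB rendering of a comparable colour
      guess <- lab_to_srgb(matrix(target, nrow = 1L))
      obj <- function(v) {
        v <- pmin(pmax(v, 0), 1)
        sum((srgb_to_working(v, space = "cam16ucs", vc = vc) - target)^2)
      }
      fit <- stats::optim(as.numeric(guess), obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-12))
      out[i, ] <- pmin(pmax(fit$par, 0), 1)
    }
  }
  .drop_single(out, m, c("r", "g", "b"))
}
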