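# Image resampling at arbitrary (fractional) source coordinates.
#
# All warps are gather operations: for every output pixel the caller supplies
# the source coordinate (sx, sy), in 1-based pixel units, and the sampler
# interpolates the input there. Out-of-frame samples receive a fill value so
# that content leaving the field of view never wraps around.

# Catmull-Rom cubic convolution kernel (a = -1/2), support [-2, 2].
kernel_catmull <- function(t) {
  a <- abs(t)
  w <- numeric(length(a))
  i1 <- a < 1
  w[i1] <- 1.5 * a[i1]^3 - 2.5 * a[i1]^2 + 1
  i2 <- !i1 & a < 2
  w[i2] <- -0.5 * a[i2]^3 + 2.5 * a[i2]^2 - 4 * a[i2] + 2
  w
}

# Cubic B-spline kernel, support [-2, 2]. Used on prefiltered coefficients.
kernel_bspline3 <- function(t) {
  a <- abs(t)
  w <- numeric(length(a))
  i1 <- a < 1
  w[i1] <- 2 / 3 - a[i1]^2 + a[i1]^3 / 2
  i2 <- !i1 & a < 2
  w[i2] <- (2 - a[i2])^3 / 6
  w
}

# In-place recursive prefilter along the first dimension so that sampling the
# coefficients with the cubic B-spline kernel interpolates the original data
# (Unser's causal/anticausal IIR with pole sqrt(3) - 2).
bspline_prefilter_dim1 <- function(M) {
  z <- sqrt(3) - 2
  n <- nrow(M)
  if (n == 1) return(M)
  M <- M * 6
  K <- min(n, ceiling(log(1e-12) / log(abs(z))))
  c0 <- M[1, , drop = FALSE]
  zk <- z
  if (K >= 2) {
    for (k in 2:K) {
      c0 <- c0 + zk * M[k, , drop = FALSE]
      zk <- zk * z
    }
  }
  cp <- M
  cp[1, ] <- c0
  for (k in 2:n) cp[k, ] <- M[k, ] + z * cp[k - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (k in (n - 1):1) cm[k, ] <- z * (cm[k + 1, ] - cp[k, ])
  cm
}

bspline_prefilter <- function(img) {
  t(bspline_prefilter_dim1(t(bspline_prefilter_dim1(img))))
}

#' Resample an image at arbitrary source coordinates
#'
#' @param img numeric matrix, indexed `[x, y]`.
#' @param sx,sy numeric matrices (or vectors) of source coordinates in
#'   1-based pixel units; `out[p] = img(sx[p], sy[p])`.
#' @param method `"bicubic"` (Catmull-Rom, default), `"bilinear"`, or
#'   `"bspline"` (true cubic B-spline interpolation with IIR prefilter).
#' @param fill value for samples falling outside the image.
#' @return numeric matrix shaped like `sx`.
#' @keywords internal
warp_image <- function(img, sx, sy,
                       method = c("bicubic", "bilinear", "bspline"),
                       fill = 0) {
  method <- match.arg(method)
  nx <- nrow(img)
  ny <- ncol(img)
  dims_out <- dim(sx)
  sx <- as.vector(sx)
  sy <- as.vector(sy)

  if (method == "bspline") {
    coefs <- bspline_prefilter(img)
    kern <- kernel_bspline3
  } else {
    coefs <- img
    kern <- kernel_catmull
  }
  cv <- as.vector(coefs)

  valid <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny

  i0 <- floor(sx)
  j0 <- floor(sy)
  tx <- sx - i0
  ty <- sy - j0
  out <- numeric(length(sx))

  if (method == "bilinear") {
    taps <- 0:1
    wx <- function(a) if (a == 0) 1 - tx else tx
    wy <- function(b) if (b == 0) 1 - ty else ty
  } else {
    taps <- -1:2
    wx <- function(a) kern(tx - a)
    wy <- function(b) kern(ty - b)
  }
  # mirror boundary, matching the prefilter's implicit symmetric extension
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  for (a in taps) {
    ia <- reflect(i0 + a, nx)
    wa <- wx(a)
    for (b in taps) {
      jb <- reflect(j0 + b, ny)
      out <- out + wa * wy(b) * cv[(jb - 1) * nx + ia]
    }
  }
  out[!valid] <- fill
  if (!is.null(dims_out)) dim(out) <- dims_out
  out
}
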