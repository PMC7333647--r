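# Intensity normalization, gray-level discretization, and the transform bank
# (wavelet sub-bands, pointwise maps, gradient magnitude, local binary
# patterns) that produces derived images for feature extraction.

# Coiflet-1 orthonormal analysis low-pass filter; high-pass by QMF below.
COIF1_LO <- c(-0.015655728135464786, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.33789766245748187,  -0.07273261951252645)

qmf_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# Circular shift of a 3D array along one axis by s (x[i] <- x[i+s], periodic).
shift_axis <- function(a, axis, s) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 + s) %% n) + 1
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Periodic convolution along one axis: y[i] = sum_k h[k] * x[i + k - 1].
conv_axis_periodic <- function(a, axis, h) {
  out <- array(0, dim(a))
  for (k in seq_along(h)) out <- out + h[k] * shift_axis(a, axis, k - 1L)
  out
}

# Keep every second sample along an axis (phase 1).
downsample_axis <- function(a, axis) {
  n <- dim(a)[axis]
  idx <- seq(1L, n, by = 2L)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' One-level 3D wavelet sub-band decomposition
#'
#' Separable one-level decomposition with an orthonormal Coiflet-1 filter
#' pair. Each axis is split into low (L) and high (H) frequency halves,
#' giving the eight sub-bands LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH (band
#' letters ordered x, y, z). The default is the stationary (undecimated)
#' variant, so every sub-band lives on the input lattice and one ROI mask
#' serves all of them. The decimated orthogonal variant (even dimensions
#' required) is retained because it conserves energy exactly and anchors the
#' Parseval test.
#'
#' @param vol [image_volume()] or 3D array; every dimension must be at least
#'   the filter length (6), and even for `decimated = TRUE`.
#' @param decimated logical; downsample by 2 per axis (classic DWT) instead
#'   of the stationary transform.
#' @return named list of eight volumes (`LLL` ... `HHH`).
#' @export
wavelet_subbands <- function(vol, decimated = FALSE) {
  a <- as_volume_array(vol)
  h <- COIF1_LO
  g <- qmf_highpass(h)
  if (any(dim(a) < length(h))) {
    stop_cfg("volume dimensions must be >= filter length (", length(h), ")")
  }
  if (decimated && any(dim(a) %% 2L != 0L)) {
    stop_cfg("decimated transform requires even dimensions")
  }
  bands <- list(`_` = a)
  for (axis in 1:3) {
    nxt <- list()
    for (nm in names(bands)) {
      lo <- conv_axis_periodic(bands[[nm]], axis, h)
      hi <- conv_axis_periodic(bands[[nm]], axis, g)
      if (decimated) {
        lo <- downsample_axis(lo, axis)
        hi <- downsample_axis(hi, axis)
      }
      nxt[[paste0(nm, "L")]] <- lo
      nxt[[paste0(nm, "H")]] <- hi
    }
    bands <- nxt
  }
  names(bands) <- sub("^_", "", names(bands))
  order8 <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands[order8]
}

#' White-stripe intensity normalization
#'
#' Standardizes MR intensities against the normal-appearing white-matter
#' histogram mode: the dominant upper mode of the smoothed in-brain intensity
#' density is located, the "stripe" is the set of intensities within a
#' +/- `tau` quantile-width window around the mode, and the whole volume is
#' mapped to `(x - mode) / sd(stripe)`. Histogram smoothing uses a kernel
#' density with bandwidth twice the histogram bin width (range/`nbins`).
#' Falls back to a whole-brain z-score (with a warning) when the stripe has
#' fewer than 50 voxels.
#'
#' @param vol [image_volume()] or 3D array.
#' @param brain binary brain mask on the same lattice.
#' @param tau half-width of the stripe window on the quantile scale.
#' @param nbins number of histogram bins used to set the smoothing bandwidth.
#' @return normalized volume (same class as input), with attributes
#'   `ws_mode` and `ws_sd`.
#' @export
whitestripe_normalize <- function(vol, brain, tau = 0.05, nbins = 128L) {
  a <- as_volume_array(vol)
  m <- as_volume_array(brain) > 0
  if (!any(m)) stop_data("degenerate brain mask")
  v <- a[m]
  rng <- range(v)
  if (diff(rng) == 0 || stats::sd(v) == 0) {
    stop_data("constant image cannot be white-stripe normalized")
  }
  binw <- diff(rng) / nbins
  d <- stats::density(v, bw = 2 * binw, n = 1024)
  # local maxima of the smoothed density
  ym <- d$y
  is_peak <- c(FALSE, ym[2:(length(ym) - 1)] > ym[1:(length(ym) - 2)] &
                 ym[2:(length(ym) - 1)] >= ym[3:length(ym)], FALSE)
  peaks_x <- d$x[is_peak]; peaks_y <- d$y[is_peak]
  # one-bandwidth slack so the main peak of a unimodal histogram (which sits
  # numerically at/just below the median) still counts as "upper"
  upper <- peaks_x >= stats::median(v) - d$bw
  mode_x <- if (any(upper)) {
    peaks_x[upper][which.max(peaks_y[upper])]
  } else if (length(peaks_x)) {
    peaks_x[which.max(peaks_y)]
  } else {
    d$x[which.max(d$y)]
  }
  Fhat <- stats::ecdf(v)
  q0 <- Fhat(mode_x)
  qlo <- stats::quantile(v, max(0, q0 - tau), names = FALSE)
  qhi <- stats::quantile(v, min(1, q0 + tau), names = FALSE)
  stripe <- v[v >= qlo & v <= qhi]
  if (length(stripe) < 50L || stats::sd(stripe) == 0) {
    warning("white-stripe has < 50 voxels; falling back to whole-brain z-score")
    mode_x <- mean(v)
    s <- stats::sd(v)
  } else {
    s <- stats::sd(stripe)
  }
  out <- (a - mode_x) / s
  res <- if (inherits(vol, "image_volume")) {
    image_volume(out, vol$spacing)
  } else {
    out
  }
  attr(res, "ws_mode") <- mode_x
  attr(res, "ws_sd") <- s
  res
}

#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width discretization: `level(x) = floor((x - min_roi) / width)
#' + 1`, assigned only inside the ROI (outside voxels are `NA`). Levels run
#' 1..Ng.
#'
#' @param vol volume or 3D array.
#' @param roi binary mask.
#' @param bin_width positive bin width in intensity units; alternatively set
#'   `n_bins` to derive the width from the ROI range.
#' @param n_bins optional bin count; when given, `bin_width = range / n_bins`
#'   (a constant ROI still yields a single level).
#' @return list with `gray` (integer 3D array, `NA` outside ROI) and `ng`.
#' @export
discretize <- function(vol, roi, bin_width = NULL, n_bins = NULL) {
  a <- as_volume_array(vol)
  m <- as_volume_array(roi) > 0
  if (!any(m)) stop_data("empty ROI")
  v <- a[m]
  if (is.null(bin_width)) {
    if (is.null(n_bins)) stop_cfg("give bin_width or n_bins")
    bin_width <- diff(range(v)) / n_bins
    if (bin_width <= 0) bin_width <- 1
  }
  if (bin_width <= 0) stop_cfg("bin_width must be > 0")
  lev <- floor((v - min(v)) / bin_width) + 1
  # guard the exact-top edge so max(v) maps to the top bin, not one past it
  # (only when max(v) falls exactly on a bin boundary does floor() overshoot
  # the intended 1..Ng range by the spec's own arithmetic; it does not: the
  # rule is taken literally, e.g. 0..74 at width 25 -> levels 1..3)
  gray <- array(NA_integer_, dim(a))
  gray[m] <- as.integer(lev)
  list(gray = gray, ng = as.integer(max(lev)))
}

#' Pointwise intensity transforms
#'
#' Monotone pointwise maps rescaled so the output magnitude matches the
#' input magnitude `M = max(|x|)` (all maps send the zero volume to zero and
#' preserve intensity ranking):
#' \itemize{
#'   \item square: `sign(x) * x^2 / M`
#'   \item squareroot: `sign(x) * sqrt(M * |x|)`
#'   \item logarithm: `sign(x) * M * log1p(|x|) / log1p(M)`
#'   \item exponential: `M * exp(x / M) / max(exp(x / M))`
#' }
#'
#' @param vol volume or 3D array (finite values).
#' @param kind one of `"square"`, `"squareroot"`, `"logarithm"`,
#'   `"exponential"`.
#' @return transformed volume (same container as input).
#' @export
pointwise_transform <- function(vol, kind = c("square", "squareroot",
                                              "logarithm", "exponential")) {
  kind <- match.arg(kind)
  a <- as_volume_array(vol)
  M <- max(abs(a))
  out <- if (M == 0) {
    a
  } else {
    switch(kind,
      square      = sign(a) * a^2 / M,
      squareroot  = sign(a) * sqrt(M * abs(a)),
      logarithm   = sign(a) * M * log1p(abs(a)) / log1p(M),
      exponential = {e <- exp(a / M); M * e / max(abs(e))})
  }
  if (inherits(vol, "image_volume")) image_volume(out, vol$spacing) else out
}

#' Gradient magnitude volume
#'
#' Euclidean norm of the spatial intensity gradient, estimated by central
#' differences in the interior and one-sided differences at the boundary,
#' scaled by voxel spacing.
#'
#' @param vol volume or 3D array with all dimensions >= 3.
#' @param spacing voxel spacing; taken from the volume when available.
#' @return gradient-magnitude volume.
#' @export
gradient_magnitude <- function(vol, spacing = c(1, 1, 1)) {
  a <- as_volume_array(vol)
  spacing <- vol_spacing(vol, spacing)
  if (any(dim(a) < 3L)) stop_cfg("gradient needs all dimensions >= 3")
  g2 <- array(0, dim(a))
  for (axis in 1:3) {
    n <- dim(a)[axis]
    fwd <- shift_axis(a, axis, 1L)
    bwd <- shift_axis(a, axis, -1L)
    d <- (fwd - bwd) / (2 * spacing[axis])
    # one-sided at the two boundary slabs (overwrite the wrapped values)
    sel_first <- slice_index(dim(a), axis, 1L)
    sel_second <- slice_index(dim(a), axis, 2L)
    sel_last <- slice_index(dim(a), axis, n)
    sel_prev <- slice_index(dim(a), axis, n - 1L)
    d[sel_first] <- (a[sel_second] - a[sel_first]) / spacing[axis]
    d[sel_last] <- (a[sel_last] - a[sel_prev]) / spacing[axis]
    g2 <- g2 + d^2
  }
  out <- sqrt(g2)
  if (inherits(vol, "image_volume")) image_volume(out, vol$spacing) else out
}

# Logical index selecting one slab orthogonal to `axis`.
slice_index <- function(dims, axis, i) {
  sel <- array(FALSE, dims)
  switch(axis,
         sel[i, , ] <- TRUE,
         sel[, i, ] <- TRUE,
         sel[, , i] <- TRUE)
  sel
}

# 8 ring offsets at chessboard radius r, in circular (angular) order.
lbp_ring_offsets <- function(r) {
  list(c(r, 0), c(r, r), c(0, r), c(-r, r),
       c(-r, 0), c(-r, -r), c(0, -r), c(r, -r))
}

#' Slice-wise rotation-invariant uniform 2D local binary patterns
#'
#' For every axial slice, each pixel is compared with its 8 ring neighbors at
#' chessboard radius `radius` (out-of-slice neighbors are clamped to the
#' edge). Uniform patterns (at most two 0/1 transitions around the ring) are
#' coded by their number of ones (0..8); non-uniform patterns share code 9.
#' Codes depend only on neighbor-vs-center comparisons, so they are invariant
#' to intensity offsets.
#'
#' @param vol volume or 3D array.
#' @param radius ring radius in voxels (>= 1, must fit in a slice).
#' @return code volume (same container as input).
#' @export
lbp2d <- function(vol, radius = 1L) {
  a <- as_volume_array(vol)
  d <- dim(a)
  if (radius < 1L) stop_cfg("radius must be >= 1")
  if (2L * radius + 1L > min(d[1], d[2])) {
    stop_cfg("LBP radius exceeds slice extent")
  }
  offs <- lbp_ring_offsets(radius)
  bits <- vector("list", 8L)
  xi <- seq_len(d[1]); yi <- seq_len(d[2])
  for (k in seq_along(offs)) {
    ox <- pmin(pmax(xi + offs[[k]][1], 1L), d[1])
    oy <- pmin(pmax(yi + offs[[k]][2], 1L), d[2])
    bits[[k]] <- (a[ox, oy, , drop = FALSE] >= a) * 1L
  }
  ones <- Reduce(`+`, bits)
  trans <- array(0L, d)
  for (k in seq_along(bits)) {
    nk <- bits[[if (k == 8L) 1L else k + 1L]]
    trans <- trans + (bits[[k]] != nk)
  }
  out <- ifelse(trans <= 2L, ones, 9L)
  out <- array(as.numeric(out), d)
  if (inherits(vol, "image_volume")) image_volume(out, vol$spacing) else out
}

# 26 unit directions (all nonzero offsets with chebyshev norm 1), normalized.
sphere_offsets <- function(r) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  nrm <- sqrt(g$dx^2 + g$dy^2 + g$dz^2)
  off <- unique(round(r * g / nrm))
  off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), , drop = FALSE]
}

#' Rotation-invariant 3D local binary pattern response images
#'
#' Simplified spherical LBP operator: for each radius, each voxel is compared
#' with neighbors sampled on a sphere of that radius (26 quantized
#' directions; out-of-volume neighbors clamped). The rotation-invariant
#' pooled response is the count of neighbors at least as bright as the
#' center, which is invariant to both rotations of the sampling sphere and
#' intensity offsets. One response image per radius.
#'
#' @param vol volume or 3D array.
#' @param radii integer radii in voxels (default 1, 2, 3).
#' @return named list of code volumes (`m1`, `m2`, ...).
#' @export
lbp3d <- function(vol, radii = c(1L, 2L, 3L)) {
  a <- as_volume_array(vol)
  d <- dim(a)
  out <- list()
  for (i in seq_along(radii)) {
    r <- radii[i]
    if (2L * r + 1L > min(d)) stop_cfg("LBP3D radius exceeds volume extent")
    offs <- sphere_offsets(r)
    code <- array(0, d)
    xi <- seq_len(d[1]); yi <- seq_len(d[2]); zi <- seq_len(d[3])
    for (k in seq_len(nrow(offs))) {
      ox <- pmin(pmax(xi + offs$dx[k], 1L), d[1])
      oy <- pmin(pmax(yi + offs$dy[k], 1L), d[2])
      oz <- pmin(pmax(zi + offs$dz[k], 1L), d[3])
      code <- code + (a[ox, oy, oz, drop = FALSE] >= a)
    }
    nm <- paste0("m", i)
    out[[nm]] <- if (inherits(vol, "image_volume")) {
      image_volume(code, vol$spacing)
    } else {
      code
    }
  }
  out
}

#' The default transform bank
#'
#' Returns the named list of derived images the extractor iterates over:
#' original, the 8 stationary wavelet sub-bands, the four pointwise maps,
#' gradient magnitude, 2D LBP and the three 3D LBP radii. Names match the
#' transform labels used in feature names (e.g. `wavelet-LHL`, `lbp-3D-m1`).
#'
#' @param vol [image_volume()].
#' @param transforms character vector of transform labels to compute;
#'   defaults to the full bank.
#' @return named list of [image_volume()]s, always including `original`.
#' @export
transform_bank <- function(vol, transforms = default_transform_labels()) {
  stopifnot(inherits(vol, "image_volume"))
  out <- list()
  if ("original" %in% transforms) out[["original"]] <- vol
  wl <- grep("^wavelet-", transforms, value = TRUE)
  if (length(wl)) {
    sb <- wavelet_subbands(vol$values, decimated = FALSE)
    for (nm in wl) {
      band <- sub("^wavelet-", "", nm)
      out[[nm]] <- image_volume(sb[[band]], vol$spacing)
    }
  }
  for (k in intersect(c("square", "squareroot", "logarithm", "exponential"),
                      transforms)) {
    out[[k]] <- pointwise_transform(vol, k)
  }
  if ("gradient" %in% transforms) out[["gradient"]] <- gradient_magnitude(vol)
  if ("lbp-2D" %in% transforms) out[["lbp-2D"]] <- lbp2d(vol)
  l3 <- grep("^lbp-3D-m", transforms, value = TRUE)
  if (length(l3)) {
    radii <- as.integer(sub("^lbp-3D-m", "", l3))
    resp <- lbp3d(vol, radii = radii)
    for (i in seq_along(l3)) out[[l3[i]]] <- resp[[i]]
  }
  out
}

#' @rdname transform_bank
#' @export
default_transform_labels <- function() {
  c("original",
    paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                         "HLL", "HLH", "HHL", "HHH")),
    "square", "squareroot", "logarithm", "exponential",
    "gradient", "lbp-2D", paste0("lbp-3D-m", 1:3))
}
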