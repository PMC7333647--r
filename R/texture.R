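# Radiomics texture features from masked, discretized volumes: first-order
# statistics plus the GLCM, GLSZM, GLDM and NGTDM families.
#
# All matrix builders run on one shared primitive: the list of in-ROI voxel
# pairs at a given lattice offset. Brute-force per-voxel oracles for each
# matrix live in the test suite, not here.

# The 13 unique 3D directions at Chebyshev distance 1 (up to sign).
GLCM_OFFSETS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# All 26 neighbor offsets (both signs).
ALL_OFFSETS_26 <- rbind(GLCM_OFFSETS, -GLCM_OFFSETS)

# For one offset, return the linear indices (i, j) of in-ROI voxel pairs
# with j displaced from i by `off` (no wrap-around).
roi_offset_pairs <- function(mask, off) {
  d <- dim(mask)
  co <- which(mask, arr.ind = TRUE)
  tx <- co[, 1] + off[1]; ty <- co[, 2] + off[2]; tz <- co[, 3] + off[3]
  ok <- tx >= 1L & tx <= d[1] & ty >= 1L & ty <= d[2] & tz >= 1L & tz <= d[3]
  if (!any(ok)) return(cbind(i = integer(), j = integer()))
  i <- (co[ok, 3] - 1L) * d[1] * d[2] + (co[ok, 2] - 1L) * d[1] + co[ok, 1]
  j <- (tz[ok] - 1L) * d[1] * d[2] + (ty[ok] - 1L) * d[1] + tx[ok]
  keep <- mask[j]
  cbind(i = i[keep], j = j[keep])
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## ---------------------------------------------------------------- first order

#' First-order intensity statistics over an ROI
#'
#' Statistics of raw (non-discretized) intensities over ROI voxels only.
#' Variance and standard deviation are the population forms; skewness and
#' kurtosis are moment ratios with kurtosis in the non-excess (Pearson)
#' convention, so a normal sample approaches 3. On a zero-variance ROI,
#' skewness and kurtosis are reported as the sentinel 0. Entropy and
#' uniformity use a fixed-bin-count histogram (`n_bins`).
#'
#' @param vol volume or 3D array.
#' @param roi binary mask with at least one voxel.
#' @param n_bins histogram bins for entropy/uniformity.
#' @return named numeric vector.
#' @export
firstorder_features <- function(vol, roi, n_bins = 16L) {
  a <- as_volume_array(vol)
  m <- as_volume_array(roi) > 0
  if (!any(m)) stop_data("empty ROI")
  v <- a[m]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  br <- range(v)
  p <- if (diff(br) == 0) {
    1
  } else {
    h <- tabulate(pmin(floor((v - br[1]) / (diff(br) / n_bins)) + 1, n_bins),
                  nbins = n_bins)
    h / n
  }
  c(Mean = mu,
    Median = stats::median(v),
    Minimum = min(v),
    Maximum = max(v),
    Range = diff(br),
    Variance = m2,
    StandardDeviation = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(v^2),
    RootMeanSquared = sqrt(mean(v^2)),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    Percentile10 = stats::quantile(v, 0.10, names = FALSE),
    Percentile90 = stats::quantile(v, 0.90, names = FALSE),
    InterquartileRange = stats::quantile(v, 0.75, names = FALSE) -
      stats::quantile(v, 0.25, names = FALSE),
    Entropy = entropy2(p),
    Uniformity = sum(p^2))
}

## ----------------------------------------------------------------------- GLCM

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts ordered pairs of gray levels at displacement `off` with both voxels
#' in the ROI, symmetrized (the reverse direction is added) and normalized to
#' probabilities.
#'
#' @param gray integer gray-level array (`NA` outside ROI) as from
#'   [discretize()].
#' @param ng number of gray levels.
#' @param off integer length-3 displacement.
#' @return `ng x ng` probability matrix (all zeros if no pairs exist).
#' @export
glcm_matrix <- function(gray, ng, off) {
  mask <- !is.na(gray)
  pr <- roi_offset_pairs(mask, off)
  C <- matrix(0, ng, ng)
  if (nrow(pr)) {
    gi <- gray[pr[, "i"]]; gj <- gray[pr[, "j"]]
    tab <- tabulate((gj - 1L) * ng + gi, nbins = ng * ng)
    C <- matrix(tab, ng, ng)
    C <- C + t(C)
    C <- C / sum(C)
  }
  C
}

glcm_features_one <- function(P, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx2 <- sum((seq_len(ng) - mux)^2 * px)
  sy2 <- sum((seq_len(ng) - muy)^2 * py)
  HX <- entropy2(px); HY <- entropy2(py); HXY <- entropy2(P)
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  HXY1 <- -sum(P[pos] * log2(pxy[pos]))
  HXY2 <- entropy2(pxy)
  corr <- if (sx2 > 0 && sy2 > 0) {
    (sum(i * j * P) - mux * muy) / sqrt(sx2 * sy2)
  } else {
    1  # degenerate single-level convention
  }
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  ct <- sum((i + j - mux - muy)^2 * P)
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Idm = sum(P / (1 + (i - j)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Imc1 = imc1,
    Imc2 = imc2,
    ClusterTendency = ct,
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    MaximumProbability = max(P))
}

#' GLCM features averaged over the 13 3D directions
#'
#' Per-direction co-occurrence matrices at Chebyshev distance `delta` are
#' symmetrized and normalized; each feature is computed per direction and
#' averaged over directions with at least one voxel pair.
#'
#' @inheritParams glcm_matrix
#' @param delta displacement magnitude (default 1).
#' @param offsets direction matrix (rows = offsets); defaults to the 13
#'   unique 3D directions.
#' @return named numeric vector.
#' @export
glcm_features <- function(gray, ng, delta = 1L, offsets = GLCM_OFFSETS) {
  if (!any(!is.na(gray))) stop_data("empty ROI")
  offs <- offsets * delta
  per_dir <- list()
  for (k in seq_len(nrow(offs))) {
    P <- glcm_matrix(gray, ng, offs[k, ])
    if (sum(P) > 0) per_dir[[length(per_dir) + 1L]] <- glcm_features_one(P, ng)
  }
  if (!length(per_dir)) {
    # single isolated voxel: no pairs in any direction
    f <- glcm_features_one(matrix(0, ng, ng), ng)
    f[] <- 0
    f["Correlation"] <- 1
    return(f)
  }
  colMeans(do.call(rbind, per_dir))
}

## ---------------------------------------------------------------------- GLSZM

#' Gray-level size-zone inventory
#'
#' Zones are maximal 26-connected components of equal gray level within the
#' ROI. Connected components are found on the equal-level adjacency graph.
#'
#' @inheritParams glcm_matrix
#' @return data.frame with one row per zone: `level`, `size`.
#' @export
glszm_zones <- function(gray, ng) {
  mask <- !is.na(gray)
  if (!any(mask)) stop_data("empty ROI")
  vox <- which(mask)
  vid <- integer(length(gray))
  vid[vox] <- seq_along(vox)
  edges <- list()
  for (k in seq_len(nrow(GLCM_OFFSETS))) {
    pr <- roi_offset_pairs(mask, GLCM_OFFSETS[k, ])
    if (nrow(pr)) {
      eq <- gray[pr[, "i"]] == gray[pr[, "j"]]
      if (any(eq)) {
        edges[[length(edges) + 1L]] <- cbind(vid[pr[eq, "i"]],
                                             vid[pr[eq, "j"]])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  lev <- gray[vox]
  data.frame(level = as.integer(tapply(lev, comp$membership, `[`, 1L)),
             size = as.integer(comp$csize[sort(unique(comp$membership))]))
}

#' GLSZM features
#'
#' Size-zone statistics over the zone inventory; `SizeZoneNonUniformity
#' Normalized` (SZNN) is `sum_s (sum_g P(g,s))^2 / Nz^2`, and the emphasis
#' features use the standard `s^2`, `1/s^2`, `g^2`, `1/g^2` weightings.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
glszm_features <- function(gray, ng) {
  z <- glszm_zones(gray, ng)
  nz <- nrow(z)
  np <- sum(!is.na(gray))
  s <- as.numeric(z$size); g <- as.numeric(z$level)
  size_counts <- tapply(rep(1, nz), s, sum)
  level_counts <- tapply(rep(1, nz), g, sum)
  p_size <- as.numeric(size_counts)
  p_level <- as.numeric(level_counts)
  mu_g <- mean(g); mu_s <- mean(s)
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(p_level^2) / nz,
    GrayLevelNonUniformityNormalized = sum(p_level^2) / nz^2,
    SizeZoneNonUniformity = sum(p_size^2) / nz,
    SizeZoneNonUniformityNormalized = sum(p_size^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((g - mu_g)^2),
    ZoneVariance = mean((s - mu_s)^2),
    ZoneEntropy = entropy2(as.numeric(table(paste(g, s))) / nz),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (g^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LargeAreaHighGrayLevelEmphasis = mean(s^2 * g^2))
}

## ----------------------------------------------------------------------- GLDM

#' Gray-level dependence counts
#'
#' For every ROI voxel, the dependence count is the number of in-ROI
#' neighbors within Chebyshev distance `delta` whose gray level differs from
#' the center by at most `alpha`.
#'
#' @inheritParams glcm_matrix
#' @param delta Chebyshev neighborhood radius (default 1 = 26 neighbors).
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return data.frame with `level`, `dependence` per ROI voxel.
#' @export
gldm_dependence <- function(gray, ng, delta = 1L, alpha = 0) {
  mask <- !is.na(gray)
  if (!any(mask)) stop_data("empty ROI")
  vox <- which(mask)
  dep <- integer(length(gray))
  offs <- expand.grid(dx = -delta:delta, dy = -delta:delta, dz = -delta:delta)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  for (k in seq_len(nrow(offs))) {
    pr <- roi_offset_pairs(mask, c(offs$dx[k], offs$dy[k], offs$dz[k]))
    if (nrow(pr)) {
      ok <- abs(gray[pr[, "i"]] - gray[pr[, "j"]]) <= alpha
      if (any(ok)) {
        cnt <- table(pr[ok, "i"])
        ii <- as.integer(names(cnt))
        dep[ii] <- dep[ii] + as.integer(cnt)
      }
    }
  }
  data.frame(level = gray[vox], dependence = dep[vox])
}

#' GLDM features
#'
#' Dependence-matrix statistics; `DependenceNonUniformityNormalized` (DNN) is
#' `sum_d (sum_g P(g,d))^2 / N^2` with `N` the ROI voxel count. Size-style
#' weightings use the dependence size `j = dependence + 1` (the center voxel
#' counts itself), so single-voxel ROIs are well defined.
#'
#' @inheritParams gldm_dependence
#' @return named numeric vector.
#' @export
gldm_features <- function(gray, ng, delta = 1L, alpha = 0) {
  dd <- gldm_dependence(gray, ng, delta, alpha)
  n <- nrow(dd)
  g <- as.numeric(dd$level)
  j <- as.numeric(dd$dependence) + 1
  p_dep <- as.numeric(table(dd$dependence))
  p_level <- as.numeric(table(dd$level))
  mu_g <- mean(g); mu_j <- mean(j)
  c(SmallDependenceEmphasis = mean(1 / j^2),
    LargeDependenceEmphasis = mean(j^2),
    GrayLevelNonUniformity = sum(p_level^2) / n,
    GrayLevelNonUniformityNormalized = sum(p_level^2) / n^2,
    DependenceNonUniformity = sum(p_dep^2) / n,
    DependenceNonUniformityNormalized = sum(p_dep^2) / n^2,
    GrayLevelVariance = mean((g - mu_g)^2),
    DependenceVariance = mean((j - mu_j)^2),
    DependenceEntropy = entropy2(as.numeric(table(paste(g, j))) / n),
    LowGrayLevelEmphasis = mean(1 / g^2),
    HighGrayLevelEmphasis = mean(g^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (g^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = mean(g^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = mean(j^2 / g^2),
    LargeDependenceHighGrayLevelEmphasis = mean(j^2 * g^2))
}

## ---------------------------------------------------------------------- NGTDM

#' Neighborhood gray-tone difference table
#'
#' For each gray level g, `s_g` is the sum over ROI voxels of level g of the
#' absolute difference between g and the mean level of the voxel's in-ROI
#' 26-neighborhood. Voxels with no in-ROI neighbor are excluded.
#'
#' @inheritParams glcm_matrix
#' @return data.frame with per-level `level`, `n` (voxel count), `p`
#'   (probability), `s`; attribute `nvp` = number of contributing voxels.
#' @export
ngtdm_table <- function(gray, ng) {
  mask <- !is.na(gray)
  if (!any(mask)) stop_data("empty ROI")
  nsum <- numeric(length(gray))
  ncnt <- integer(length(gray))
  for (k in seq_len(nrow(ALL_OFFSETS_26))) {
    pr <- roi_offset_pairs(mask, ALL_OFFSETS_26[k, ])
    if (nrow(pr)) {
      nsum[pr[, "i"]] <- nsum[pr[, "i"]] + gray[pr[, "j"]]
      ncnt[pr[, "i"]] <- ncnt[pr[, "i"]] + 1L
    }
  }
  vox <- which(mask & ncnt > 0)
  lev <- gray[vox]
  diffs <- abs(lev - nsum[vox] / ncnt[vox])
  nvp <- length(vox)
  out <- data.frame(level = sort(unique(lev)))
  out$n <- as.integer(table(factor(lev, levels = out$level)))
  out$p <- out$n / nvp
  out$s <- as.numeric(tapply(diffs, factor(lev, levels = out$level), sum))
  attr(out, "nvp") <- nvp
  out
}

#' NGTDM features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' neighborhood gray-tone difference table. Degenerate denominators (e.g. a
#' constant ROI) return 0 by convention.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
ngtdm_features <- function(gray, ng) {
  tb <- ngtdm_table(gray, ng)
  nvp <- attr(tb, "nvp")
  i <- as.numeric(tb$level); p <- tb$p; s <- tb$s
  ngp <- sum(p > 0)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 0
  contrast <- if (ngp > 1 && nvp > 0) {
    sum(outer(p, p) * outer(i, i, `-`)^2) / (ngp * (ngp - 1)) * sum(s) / nvp
  } else {
    0
  }
  busy_den <- sum(abs(outer(i * p, i * p, `-`)))
  busy <- if (busy_den > 0) ps / busy_den else 0
  cx <- 0
  if (nvp > 0 && ngp > 1) {
    num <- outer(p * s, p * s, `+`)
    den <- outer(p, p, `+`)
    cx <- sum(abs(outer(i, i, `-`)) * num / den) / nvp
  }
  strength <- if (sum(s) > 0) {
    sum(outer(p, p, `+`) * outer(i, i, `-`)^2) / sum(s)
  } else {
    0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cx, Strength = strength)
}

## ------------------------------------------------------------- feature names

#' Encode / parse radiomics feature names
#'
#' Names follow the `<sequence>-<transform>_<family>_<feature>` convention,
#' e.g. `T2-wavelet-LHL_glszm_SizeZoneNonUniformityNormalized`. Sequences are
#' one of T1pre, T1post, T2, FLAIR; transform labels may contain hyphens but
#' never underscores, so parsing is unambiguous.
#'
#' @param sequence,transform,family,feature name components.
#' @return `encode_feature_name`: a character scalar.
#' @export
encode_feature_name <- function(sequence, transform, family, feature) {
  stopifnot(sequence %in% c("T1pre", "T1post", "T2", "FLAIR"))
  paste0(sequence, "-", transform, "_", family, "_", feature)
}

#' @rdname encode_feature_name
#' @param name encoded feature name.
#' @return `parse_feature_name`: a list with the four components.
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "_")[[1]]
  if (length(parts) < 3L) stop_data("malformed feature name: ", name)
  head <- parts[1]
  family <- parts[2]
  feature <- paste(parts[-(1:2)], collapse = "_")
  seq_tr <- strsplit(head, "-")[[1]]
  sequence <- seq_tr[1]
  if (!sequence %in% c("T1pre", "T1post", "T2", "FLAIR")) {
    stop_data("unknown sequence in feature name: ", name)
  }
  transform <- paste(seq_tr[-1], collapse = "-")
  list(sequence = sequence, transform = transform,
       family = family, feature = feature)
}

## --------------------------------------------------------------- extraction

TEXTURE_FAMILIES <- c("firstorder", "glcm", "glszm", "gldm", "ngtdm")

#' Extract all enabled features from one derived image
#'
#' @param vol derived image ([image_volume()] or array).
#' @param roi binary mask.
#' @param families subset of firstorder/glcm/glszm/gldm/ngtdm.
#' @param n_bins gray-level bins for the matrix families.
#' @return named numeric vector (names are `<family>_<Feature>`).
#' @export
extract_image_features <- function(vol, roi, families = TEXTURE_FAMILIES,
                                   n_bins = 16L) {
  out <- numeric(0)
  if ("firstorder" %in% families) {
    f <- firstorder_features(vol, roi, n_bins = n_bins)
    out <- c(out, stats::setNames(f, paste0("firstorder_", names(f))))
  }
  matrix_fams <- intersect(families, c("glcm", "glszm", "gldm", "ngtdm"))
  if (length(matrix_fams)) {
    dz <- discretize(vol, roi, n_bins = n_bins)
    for (fam in matrix_fams) {
      f <- switch(fam,
                  glcm = glcm_features(dz$gray, dz$ng),
                  glszm = glszm_features(dz$gray, dz$ng),
                  gldm = gldm_features(dz$gray, dz$ng),
                  ngtdm = ngtdm_features(dz$gray, dz$ng))
      out <- c(out, stats::setNames(f, paste0(fam, "_", names(f))))
    }
  }
  out
}

#' Manifest of feature names for a transform x family configuration
#'
#' @param transforms transform labels (see [default_transform_labels()]).
#' @param families feature families.
#' @param sequences MR sequence labels.
#' @return character vector of encoded feature names, in extraction order.
#' @export
feature_manifest <- function(transforms = default_transform_labels(),
                             families = TEXTURE_FAMILIES,
                             sequences = c("T1pre", "T1post", "T2", "FLAIR")) {
  per_family <- list(
    firstorder = names(firstorder_features(array(stats::rnorm(27), c(3, 3, 3)),
                                           array(TRUE, c(3, 3, 3)))),
    glcm = names(glcm_features_one(diag(2) / 2, 2L)),
    glszm = names(glszm_features(array(1L, c(2, 2, 2)), 1L)),
    gldm = names(gldm_features(array(1L, c(2, 2, 2)), 1L)),
    ngtdm = names(ngtdm_features(array(1L, c(2, 2, 2)), 1L)))
  out <- character(0)
  for (sq in sequences) {
    for (tr in transforms) {
      for (fam in families) {
        out <- c(out, encode_feature_name(sq, tr, fam, per_family[[fam]]))
      }
    }
  }
  out
}

#' Extract the cohort feature table
#'
#' For every patient with all four sequences, applies the transform bank to
#' each sequence volume and extracts the enabled families from every derived
#' image, using the T1pre (T1W) ROI mask for all sequences. Patients with a
#' missing sequence are skipped with a logged reason.
#'
#' @param cohort_images named list: per patient, a list with elements
#'   `T1pre`, `T1post`, `T2`, `FLAIR` ([image_volume()]s) and `mask`.
#' @param transforms,families,n_bins extraction configuration.
#' @param verbose log per-patient progress via [message()].
#' @return numeric matrix (patients x features) with an `exclusions`
#'   attribute (data.frame patient/reason).
#' @export
extract_feature_table <- function(cohort_images,
                                  transforms = default_transform_labels(),
                                  families = TEXTURE_FAMILIES,
                                  n_bins = 16L, verbose = FALSE) {
  seqs <- c("T1pre", "T1post", "T2", "FLAIR")
  rows <- list()
  excl <- data.frame(patient = character(), reason = character(),
                     stringsAsFactors = FALSE)
  for (pid in names(cohort_images)) {
    pat <- cohort_images[[pid]]
    missing <- setdiff(c(seqs, "mask"), names(pat))
    if (length(missing)) {
      excl <- rbind(excl, data.frame(
        patient = pid, reason = paste("missing", paste(missing, collapse = "+")),
        stringsAsFactors = FALSE))
      next
    }
    vals <- numeric(0)
    for (sq in seqs) {
      bank <- transform_bank(pat[[sq]], transforms = transforms)
      for (tr in names(bank)) {
        f <- extract_image_features(bank[[tr]], pat$mask,
                                    families = families, n_bins = n_bins)
        names(f) <- paste0(sq, "-", tr, "_", names(f))
        vals <- c(vals, f)
      }
    }
    rows[[pid]] <- vals
    if (verbose) message("extracted ", length(vals), " features for ", pid)
  }
  if (!length(rows)) stop_data("no patient had a complete sequence set")
  X <- do.call(rbind, rows)
  attr(X, "exclusions") <- excl
  X
}
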