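test_that("first-order statistics match closed forms", {
  roi <- array(TRUE, c(3, 1, 1))
  f <- firstorder_features(array(c(1, 2, 3), c(3, 1, 1)), roi)
  expect_equal(unname(f["Median"]), 2)
  expect_equal(unname(f["Minimum"]), 1)
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Variance"]), 2 / 3)  # population variance
  # distributional limit: Pearson (non-excess) kurtosis of a normal is 3
  set.seed(21)
  n <- 1e5
  v <- array(rnorm(n), c(100, 100, 10))
  f2 <- firstorder_features(v, array(TRUE, dim(v)))
  expect_equal(unname(f2["Kurtosis"]), 3, tolerance = 0.1 / 3)
  expect_equal(unname(f2["Skewness"]), 0, tolerance = 0.05)
  # zero-variance sentinel
  f3 <- firstorder_features(array(4, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(unname(f3["Kurtosis"]), 0)
  expect_equal(unname(f3["Entropy"]), 0)
  expect_error(firstorder_features(v, array(FALSE, dim(v))),
               class = "cicr_data_error")
})

test_that("GLCM: degenerate and checkerboard conventions", {
  const <- array(1L, c(3, 3, 3))
  f <- glcm_features(const, 1L)
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["Imc2"]), 0)
  # strict 2-level checkerboard, single axis direction: Correlation = -1
  ck <- array(NA_integer_, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) ck[i, j, 1] <- 1L + (i + j) %% 2L
  f2 <- glcm_features(ck, 2L, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(f2["Correlation"]), -1)
  # hand 2x2 co-occurrence: all pairs are (1,2)/(2,1)
  P <- glcm_matrix(ck, 2L, c(1L, 0L, 0L))
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2))
})

test_that("GLCM matrices equal the exhaustive pair-enumeration oracle", {
  for (seed in 1:25) {
    g <- random_gray(seed)
    ng <- max(g, na.rm = TRUE)
    for (k in c(1, 5, 11)) {
      off <- cicradiomics:::GLCM_OFFSETS[k, ]
      expect_equal(glcm_matrix(g, ng, off), oracle_glcm(g, ng, off),
                   info = paste("seed", seed, "offset", k))
    }
  }
})

test_that("GLSZM: hand cases and flood-fill oracle equivalence", {
  # constant ROI: a single zone
  f <- glszm_features(array(2L, c(3, 3, 2)), 2L)
  expect_equal(unname(f["SizeZoneNonUniformityNormalized"]), 1)
  # two zones of sizes 1 and 2 at different levels: SZNN = 0.5
  g <- array(NA_integer_, c(3, 1, 1))
  g[1:3, 1, 1] <- c(1L, 2L, 2L)
  f2 <- glszm_features(g, 2L)
  expect_equal(unname(f2["SizeZoneNonUniformityNormalized"]), 0.5)
  expect_equal(unname(f2["LargeAreaLowGrayLevelEmphasis"]),
               (1 / 1 + 4 / 4) / 2)  # zones (g=1,s=1),(g=2,s=2)
  for (seed in 26:60) {
    g <- random_gray(seed)
    z <- glszm_zones(g, max(g, na.rm = TRUE))
    z <- z[order(z$level, z$size), ]
    o <- oracle_zones(g)
    expect_equal(unname(as.matrix(z)), unname(as.matrix(o)),
                 info = paste("seed", seed))
  }
})

test_that("GLDM: hand cases and neighbor-scan oracle equivalence", {
  # single-voxel ROI: dependence 0, DNN = 1
  g1 <- array(NA_integer_, c(3, 3, 1)); g1[2, 2, 1] <- 1L
  f1 <- gldm_features(g1, 1L)
  expect_equal(unname(f1["DependenceNonUniformityNormalized"]), 1)
  # constant 3x3x1: dependences {3 x4, 5 x4, 8 x1}, DNN = 33/81
  f2 <- gldm_features(array(1L, c(3, 3, 1)), 1L)
  expect_equal(unname(f2["DependenceNonUniformityNormalized"]), 33 / 81)
  for (seed in 61:95) {
    g <- random_gray(seed)
    dd <- gldm_dependence(g, max(g, na.rm = TRUE))
    o <- oracle_gldm(g)
    expect_equal(dd$level, o$level, info = paste("seed", seed))
    expect_equal(dd$dependence, o$dependence, info = paste("seed", seed))
  }
  # alpha tolerance widens dependence
  g <- array(c(1L, 2L), c(2, 1, 1))
  expect_equal(gldm_dependence(g, 2L, alpha = 0)$dependence, c(0L, 0L))
  expect_equal(gldm_dependence(g, 2L, alpha = 1)$dependence, c(1L, 1L))
})

test_that("NGTDM: hand cases and per-voxel oracle equivalence", {
  # constant ROI: all s = 0, Busyness = Strength = 0 by convention
  f <- ngtdm_features(array(3L, c(3, 3, 1)), 3L)
  expect_equal(unname(f["Busyness"]), 0)
  expect_equal(unname(f["Strength"]), 0)
  # hand case: 2 voxels, levels 1 and 2 -> s = (1, 1), busyness 1, strength 1
  g <- array(c(1L, 2L), c(2, 1, 1))
  f2 <- ngtdm_features(g, 2L)
  expect_equal(unname(f2["Busyness"]), 1)
  expect_equal(unname(f2["Strength"]), 1)
  for (seed in 96:130) {
    g <- random_gray(seed)
    tb <- ngtdm_table(g, max(g, na.rm = TRUE))
    o <- oracle_ngtdm(g)
    expect_equal(tb$level, o$level, info = paste("seed", seed))
    expect_equal(tb$n, o$n, info = paste("seed", seed))
    expect_equal(tb$s, o$s, tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(attr(tb, "nvp"), o$nvp[1], info = paste("seed", seed))
  }
})

test_that("SZNN and DNN live in (0, 1] and fall as structure diversifies", {
  for (seed in 131:150) {
    g <- random_gray(seed)
    ng <- max(g, na.rm = TRUE)
    sznn <- glszm_features(g, ng)["SizeZoneNonUniformityNormalized"]
    dnn <- gldm_features(g, ng)["DependenceNonUniformityNormalized"]
    expect_gt(sznn, 0); expect_lte(sznn, 1)
    expect_gt(dnn, 0); expect_lte(dnn, 1)
  }
  # diversifying zone sizes lowers SZNN (more heterogeneity)
  uniform_zones <- array(NA_integer_, c(6, 1, 1))
  uniform_zones[] <- c(1L, 2L, 1L, 2L, 1L, 2L)      # six size-1 zones
  varied_zones <- array(NA_integer_, c(6, 1, 1))
  varied_zones[] <- c(1L, 1L, 1L, 2L, 1L, 2L)       # sizes 3,1,1,1
  s_u <- glszm_features(uniform_zones, 2L)["SizeZoneNonUniformityNormalized"]
  s_v <- glszm_features(varied_zones, 2L)["SizeZoneNonUniformityNormalized"]
  expect_gt(s_u, s_v)
})

test_that("features ignore voxels outside the ROI (mask locality)", {
  set.seed(31)
  v <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  roi <- array(runif(prod(dim(v))) < 0.4, dim(v))
  roi[1, 1, 1] <- TRUE
  base <- extract_image_features(v, roi)
  for (rep in 1:5) {
    v2 <- v
    v2[!roi] <- rnorm(sum(!roi), sd = 50)
    expect_equal(extract_image_features(v2, roi), base)
  }
})

test_that("feature names encode and parse bidirectionally", {
  nm <- encode_feature_name("T2", "wavelet-LHL", "glszm",
                            "SizeZoneNonUniformityNormalized")
  expect_equal(nm, "T2-wavelet-LHL_glszm_SizeZoneNonUniformityNormalized")
  p <- parse_feature_name(nm)
  expect_equal(p$sequence, "T2")
  expect_equal(p$transform, "wavelet-LHL")
  expect_equal(p$family, "glszm")
  expect_equal(p$feature, "SizeZoneNonUniformityNormalized")
  for (nm2 in c("T1pre-lbp-3D-m1_glcm_Correlation",
                "T1post-original_firstorder_Median",
                "FLAIR-logarithm_ngtdm_Strength")) {
    q <- parse_feature_name(nm2)
    expect_equal(encode_feature_name(q$sequence, q$transform, q$family,
                                     q$feature), nm2)
  }
  expect_error(parse_feature_name("X1-original_glcm_Imc2"),
               class = "cicr_data_error")
})

test_that("extraction respects the manifest and is deterministic", {
  tc <- tiny_cohort()
  imgs <- tc$images[1:2]
  # original x firstorder Median only: 4 columns per patient
  X <- extract_feature_table(imgs, transforms = "original",
                             families = "firstorder")
  med <- grep("_firstorder_Median$", colnames(X))
  expect_equal(length(med), 4L)
  man <- feature_manifest(transforms = c("original", "gradient"),
                          families = c("firstorder", "glszm"))
  X2 <- extract_feature_table(imgs, transforms = c("original", "gradient"),
                              families = c("firstorder", "glszm"))
  expect_equal(colnames(X2), man)
  X3 <- extract_feature_table(imgs, transforms = c("original", "gradient"),
                              families = c("firstorder", "glszm"))
  expect_identical(X2, X3)
  # a patient with a missing sequence is excluded with a reason
  broken <- tc$images[1:3]
  broken[[2]]$T2 <- NULL
  X4 <- extract_feature_table(broken, transforms = "original",
                              families = "firstorder")
  expect_equal(nrow(X4), 2L)
  excl <- attr(X4, "exclusions")
  expect_equal(nrow(excl), 1L)
  expect_match(excl$reason, "T2")
})
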