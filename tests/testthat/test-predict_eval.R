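test_that("zscore_columns uses the population SD", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  Z <- zscore_columns(X)
  expect_equal(Z[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0))
  expect_equal(sqrt(colMeans(Z^2)), c(a = 1, b = 1))
  expect_equal(zscore_columns(Z), Z)
  X2 <- cbind(ok = 1:3, flat = c(2, 2, 2))
  expect_error(zscore_columns(X2), "flat", class = "cicr_data_error")
})

test_that("class_weights equalize the weighted class masses", {
  y <- rep(c(1, 0), c(4, 12))
  w <- class_weights(y)
  expect_equal(unname(w["1"]), 2.0)
  expect_equal(unname(w["0"]), 2 / 3, tolerance = 1e-12)
  expect_equal(w["1"] * 4, w["0"] * 12, ignore_attr = TRUE)
  expect_equal(unname(class_weights(rep(c(0, 1), 8))), c(1, 1))
  expect_error(class_weights(rep(1, 5)), class = "cicr_data_error")
})

test_that("weighted logistic fit: boundary, balance, recovery, equivalence", {
  # separable 1-D: probability crosses 0.5 inside the gap
  X <- matrix(c(seq(-3, -1, length.out = 20), seq(1, 3, length.out = 20)),
              ncol = 1, dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_weighted_logistic(X, y)
  expect_lt(predict_logistic(fit, matrix(-1, dimnames = list(NULL, "x"))), 0.5)
  expect_gt(predict_logistic(fit, matrix(1, dimnames = list(NULL, "x"))), 0.5)
  # balanced data: weighted fit == unweighted fit
  set.seed(51)
  Xb <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("u", "v")))
  yb <- rep(c(0, 1), 50)
  f1 <- fit_weighted_logistic(Xb, yb, weights = class_weights(yb))
  f2 <- fit_weighted_logistic(Xb, yb)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  # coefficient recovery within 15% at n = 2000
  set.seed(52)
  Xr <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("u", "v")))
  th <- c(1.2, -0.8)
  yr <- rbinom(2000, 1, plogis(drop(Xr %*% th)))
  fr <- fit_weighted_logistic(Xr, yr, ridge = 1e-4)
  expect_equal(unname(fr$coef), th, tolerance = 0.15)
  # weighting equivalence: weights on imbalanced data == physical duplication
  set.seed(53)
  Xi <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "x"))
  yi <- rep(c(0, 1), c(40, 20))
  Xi[yi == 1] <- Xi[yi == 1] + 1
  wfit <- fit_weighted_logistic(Xi, yi, weights = class_weights(yi))
  Xd <- rbind(Xi, Xi[yi == 1, , drop = FALSE])  # duplicate the minority class
  yd <- c(yi, rep(1, 20))
  dfit <- fit_weighted_logistic(Xd, yd,
                                weights = stats::setNames(c(0.75, 0.75),
                                                          c("0", "1")))
  expect_equal(wfit$coef, dfit$coef, tolerance = 1e-6)
})

test_that("curve averaging and corner cutoffs behave as specified", {
  curve1 <- data.frame(x = seq(0, 1, 0.01), y = seq(0, 1, 0.01),
                       threshold = seq(1, 0, -0.01))
  curve2 <- data.frame(x = seq(0, 1, 0.01), y = 1,
                       threshold = seq(1, 0, -0.01))
  # averaging N copies of one curve reproduces it
  same <- average_curves(list(curve1, curve1, curve1), "ROC")
  expect_equal(same$y, same$x, tolerance = 1e-9)
  # y = x and y = 1 average to (x + 1) / 2
  avg <- average_curves(list(curve1, curve2), "ROC")
  expect_equal(avg$y, (avg$x + 1) / 2, tolerance = 1e-9)
  expect_error(average_curves(list(), "ROC"), class = "cicr_data_error")
  # forced-arithmetic cutoff example
  cur <- structure(list(x = c(0, 0.2, 1), y = c(0, 0.9, 1),
                        threshold = c(0.9, 0.5, 0.1), kind = "ROC"),
                   class = "averaged_curve")
  oc <- optimal_cutoff(cur)
  expect_equal(oc$x, 0.2); expect_equal(oc$y, 0.9)
  expect_equal(oc$threshold, 0.5)
  expect_equal(oc$distance, sqrt(0.2^2 + 0.1^2))
  # brute-force distance scan agrees on random curves
  set.seed(54)
  for (k in 1:5) {
    xx <- sort(runif(20)); yy <- sort(runif(20))
    cr <- structure(list(x = xx, y = yy, threshold = seq(1, 0, length.out = 20),
                         kind = "PR"), class = "averaged_curve")
    oc2 <- optimal_cutoff(cr)
    d_all <- sqrt((xx - 1)^2 + (yy - 1)^2)
    expect_equal(oc2$distance, min(d_all))
  }
  # grid refinement changes the averaged-ROC AUC by < 0.005
  set.seed(55)
  curves <- lapply(1:20, function(i) {
    sc <- runif(40); lb <- rbinom(40, 1, 0.4)
    cicradiomics:::roc_points(sc, lb)
  })
  a101 <- average_curves(curves, "ROC", grid_size = 101L)$auc
  a1001 <- average_curves(curves, "ROC", grid_size = 1001L)$auc
  expect_lt(abs(a101 - a1001), 0.005)
})

test_that("repeated_split_evaluate: separable, permuted and deterministic", {
  set.seed(56)
  n <- 60
  X <- matrix(c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = n / 2)
  ev <- repeated_split_evaluate(X, y, repetitions = 50, master_seed = 1)
  expect_equal(unname(ev$summary["accuracy", "mean"]), 1.0)
  expect_equal(unname(ev$summary["roc_auc", "mean"]), 1.0)
  expect_equal(ev$roc_cutoff$distance, 0)
  # CI brackets the mean
  expect_true(all(ev$summary[, "ci_low"] <= ev$summary[, "mean"] + 1e-12 &
                    ev$summary[, "mean"] <= ev$summary[, "ci_high"] + 1e-12))
  # determinism
  ev2 <- repeated_split_evaluate(X, y, repetitions = 50, master_seed = 1)
  expect_identical(ev$summary, ev2$summary)
  expect_identical(ev$mean_probability, ev2$mean_probability)
  # label permutation: mean accuracy ~ majority rate, AUC ~ 0.5 when
  # averaged over permutations (a single fixed permutation retains
  # dataset-level chance association)
  set.seed(57)
  Xn <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("g", 1:4)))
  yn <- rep(c(0, 1), c(90, 30))
  aucs <- vapply(1:12, function(k) {
    yp <- sample(yn)
    evp <- repeated_split_evaluate(Xn, yp, repetitions = 40, master_seed = k)
    unname(evp$summary["roc_auc", "mean"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("U-test/top-third screen applies both gates with the right quota", {
  set.seed(58)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(NULL, sprintf("f%02d", 1:11)))
  X[y == 1, "f01"] <- X[y == 1, "f01"] + 3   # significant, high importance
  X[y == 1, "f05"] <- X[y == 1, "f05"] + 3   # significant, low importance
  imp <- stats::setNames(c(10, 8, -7, 6, 0.1, 5, rep(0.01, 5)),
                         sprintf("f%02d", 1:11))
  out <- u_test_and_top_third(X, y, imp)
  expect_equal(sum(rank(-abs(out$importance)) <= 3 & out$kept),
               sum(out$kept))           # quota floor(11/3) = 3
  expect_true(out$kept[out$feature == "f01"])
  expect_false(out$kept[out$feature == "f05"])  # significant but ranked low
  expect_false(out$kept[out$feature == "f02"])  # ranked high but null
  # k = 6 -> quota 2
  out6 <- u_test_and_top_third(X[, 1:6], y, imp[1:6])
  expect_lte(sum(out6$kept), 2L)
})

test_that("exemplar selection picks extreme patients and max-area slices", {
  tc <- tiny_cohort()
  masks <- lapply(tc$images, `[[`, "mask")
  X <- extract_feature_table(tc$images, transforms = "original",
                             families = "firstorder")
  f <- colnames(X)[1]
  mp <- stats::setNames(seq(0, 1, length.out = nrow(X)), rownames(X))
  ex <- select_exemplars(X, f, mp, masks)
  expect_equal(ex$features[[f]]$max$patient,
               rownames(X)[which.max(X[, f])])
  expect_equal(ex$model$max$patient, rownames(X)[nrow(X)])
  expect_equal(ex$model$min$patient, rownames(X)[1])
  # slice argmax agrees with an exhaustive per-slice count
  pid <- ex$model$max$patient
  areas <- vapply(seq_len(dim(masks[[pid]])[3]),
                  function(k) sum(masks[[pid]][, , k]), numeric(1))
  expect_equal(ex$model$max$slice, which(areas == max(areas))[1])
  # single-patient cohort: same patient is both extremes
  ex1 <- select_exemplars(X[1, , drop = FALSE], f, mp[1], masks[1])
  expect_equal(ex1$model$max$patient, ex1$model$min$patient)
  # all tumor in one slice
  m1 <- list(P = array(0L, c(4, 4, 3)))
  m1$P[2, 2, 2] <- 1L
  Xs <- matrix(1, 1, 1, dimnames = list("P", "f"))
  exs <- select_exemplars(Xs, "f", c(P = 0.5), m1)
  expect_equal(exs$model$max$slice, 2L)
})
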