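test_that("feature assembly has documented arity and no missing values", {
  ds <- generate_dataset(n = 3, seed = 5)
  fm <- assemble_features(ds, feature_spec("pbf"))
  expect_equal(dim(fm), c(12L, 3L))
  expect_named(as.data.frame(fm), c("CF_C", "CF_H", "CF_E"))
  fm2 <- assemble_features(ds, feature_spec("content+CF"))
  expect_equal(ncol(fm2), 6L)
  fm3 <- assemble_features(ds, feature_spec("pbf11cbf"))
  expect_equal(ncol(fm3), 14L)
  expect_equal(colnames(fm3)[12:14], c("CF_C", "CF_H", "CF_E"))
  expect_false(anyNA(fm3))
  expect_error(assemble_features(character(0), feature_spec("pbf")),
               "no sequences")
  expect_error(feature_spec("nonsense"), "unknown feature")
})

test_that("standardisation yields zero mean, unit variance, constant-safe", {
  ds <- generate_dataset(n = 5, seed = 2)
  fm <- assemble_features(ds, feature_spec("pbf11cbf"), scale = TRUE)
  expect_equal(unname(colMeans(fm)), rep(0, ncol(fm)), tolerance = 1e-12)
  sds <- apply(fm, 2, sd)
  expect_true(all(abs(sds - 1) < 1e-12 | sds == 0))
})

test_that("grid search separates Gaussian blobs and records the grid", {
  set.seed(1)
  x <- rbind(matrix(rnorm(30, mean = 0), ncol = 2),
             matrix(rnorm(30, mean = 6), ncol = 2))
  rownames(x) <- sprintf("p%02d", 1:30)
  y <- rep(c("all-alpha", "all-beta"), each = 15)
  fit <- psse_fit(x, stats::setNames(y, rownames(x)), folds = 5, seed = 3)
  expect_equal(fit$cv_accuracy, 1)
  expect_equal(dim(fit$grid), c(11L, 11L))  # 121 candidate pairs
  # ties break toward the smallest cost, then gamma, of the maximum
  amax <- which(fit$grid == max(fit$grid), arr.ind = TRUE)
  rmin <- min(amax[, 1])
  cmin <- min(amax[amax[, 1] == rmin, 2])
  expect_equal(which(2^(-5:5) == fit$cost), rmin)
  expect_equal(which(2^(-5:5) == fit$gamma), cmin)
  expect_error(psse_fit(x, rep("all-alpha", 30)), "at least two")
})

test_that("fitting is invariant to affine rescaling of a feature column", {
  set.seed(4)
  ds <- generate_dataset(n = 8, seed = 4)
  fm <- assemble_features(ds, feature_spec("content+CF"))
  fit1 <- psse_fit(fm, ds$labels, folds = 4, seed = 5)
  fm2 <- fm
  fm2[, 1] <- fm2[, 1] * 1000 + 7
  fit2 <- psse_fit(fm2, ds$labels, folds = 4, seed = 5)
  expect_equal(fit1$cost, fit2$cost)
  expect_equal(fit1$gamma, fit2$gamma)
  expect_equal(unname(fit1$features), unname(fit2$features),
               tolerance = 1e-12)
})

test_that("small classes reduce the fold count with a warning", {
  ds <- generate_dataset(n = 3, seed = 9)
  expect_warning(fit <- psse_fit(ds, features = "pbf", folds = 10, seed = 1),
                 "reduced to 3-fold")
  expect_equal(fit$folds, 3L)
})

test_that("evaluation reports obey the weighted-mean accuracy identity", {
  truth <- rep(c("all-alpha", "all-beta", "alpha/beta", "alpha+beta"),
               each = 4)
  pred <- truth
  pred[1] <- "all-beta"  # one miss in the first class
  rep_ <- evaluation_report(truth, pred)
  expect_equal(unname(rep_$per_class["all-alpha"]), 0.75)
  expect_equal(rep_$overall, 15 / 16)
  expect_equal(rep_$overall,
               sum(rep_$per_class * rep_$class_sizes) /
                 sum(rep_$class_sizes))
  tab <- accuracy_report(rep_)
  expect_equal(tab$accuracy_pct[tab$class == "Overall"], "93.75")
  expect_equal(as.numeric(tab$accuracy_pct[tab$class == "all-alpha"]), 75)
  # all-correct identity
  perfect <- evaluation_report(truth, truth)
  expect_true(all(perfect$per_class == 1))
  expect_equal(perfect$overall, 1)
})

test_that("jackknife is deterministic and beats chance on synthetic data", {
  ds <- generate_dataset(n = 12, seed = 6)
  for (feats in c("pbf", "content", "content+CF")) {
    fit <- psse_fit(ds, features = feats, folds = 5, seed = 11)
    rep_ <- jackknife(fit)
    expect_equal(rep_$overall,
                 sum(rep_$per_class * rep_$class_sizes) /
                   sum(rep_$class_sizes))
    # chance for 4 balanced classes is 0.25; demand > 0.25 + 3 binomial SE
    n <- length(ds$sequences)
    expect_gt(rep_$overall, 0.25 + 3 * sqrt(0.25 * 0.75 / n))
  }
  fit <- psse_fit(ds, features = "pbf", folds = 5, seed = 11)
  r1 <- jackknife(fit)
  r2 <- jackknife(fit)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("singleton classes are predicted without their label, warned", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20), ncol = 2),
             matrix(rnorm(20, mean = 5), ncol = 2),
             matrix(rnorm(2, mean = 10), ncol = 2))
  rownames(x) <- sprintf("q%02d", 1:21)
  y <- c(rep("all-alpha", 10), rep("all-beta", 10), "alpha/beta")
  suppressWarnings(fit <- psse_fit(x, stats::setNames(y, rownames(x)),
                                   folds = 3, seed = 2))
  expect_warning(rep_ <- jackknife(fit), "q21")
  expect_equal(unname(rep_$per_class["alpha/beta"]), 0)
})

test_that("predict recomputes features and replays the training scaling", {
  ds <- generate_dataset(n = 10, seed = 14)
  fit <- psse_fit(ds, features = "pbf11cbf", folds = 5, seed = 15)
  self <- predict(fit, ds$sequences)
  expect_named(self, names(ds$sequences))
  expect_gt(mean(as.character(self) == ds$labels), 0.8)
  fresh <- generate_dataset(n = 5, seed = 999)
  pred <- predict(fit, fresh)
  expect_length(pred, 20L)
  expect_true(all(as.character(pred) %in% SS_CLASSES))
})
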