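toy_data <- function(n = 60, gap = 3) {
  set.seed(10)
  X <- data.frame(x1 = c(rnorm(n), rnorm(n) + gap),
                  x2 = c(rnorm(n), rnorm(n) + gap))
  y <- factor(rep(c("fibroblast", "tumor"), each = n),
              levels = c("fibroblast", "tumor"))
  list(X = X, y = y)
}

test_that("all four families fit separable toy data perfectly", {
  d <- toy_data(gap = 6)
  for (fam in c("logistic", "random_forest", "svm_gaussian", "bundle")) {
    set.seed(1)
    m <- train_classifier(classifier_spec(fam), d$X, d$y)
    s <- predict_scores(m, d$X)
    expect_true(all(s >= 0 & s <= 1))
    pred <- ifelse(s >= 0.5, "tumor", "fibroblast")
    expect_gte(mean(pred == d$y), 0.99)
  }
  expect_error(train_classifier(classifier_spec("logistic"), d$X,
                                rep("tumor", nrow(d$X))), "both classes")
})

test_that("the SVM kernel width follows the pairwise-distance quantile heuristic", {
  d <- toy_data()
  set.seed(2)
  m <- train_classifier(classifier_spec("svm_gaussian"), d$X, d$y)
  M <- as.matrix(d$X)
  d2 <- as.vector(dist(M))^2
  q <- quantile(d2[d2 > 0], c(0.1, 0.9))
  sigma2 <- 1 / m$fit$gamma
  expect_gte(sigma2, q[1])
  expect_lte(sigma2, q[2])
})

test_that("bundling averages exactly 20 tree predictions", {
  d <- toy_data(40)
  set.seed(3)
  m <- train_classifier(classifier_spec("bundle"), d$X, d$y)
  expect_length(m$fit$rounds, 20)
  s <- predict_scores(m, d$X[1:5, ])
  # manual average over the stored rounds reproduces the score
  manual <- rowMeans(vapply(m$fit$rounds, function(rd) {
    M <- microscreen:::as_design_matrix(d$X[1:5, ])
    aug <- cbind(M,
      p_log = predict(rd$base_log, newdata = data.frame(M), type = "response"),
      p_knn5 = microscreen:::knn_score(m$fit$M_train[rd$oob, , drop = FALSE],
                                       m$fit$y_train[rd$oob], M, 5),
      p_knn10 = microscreen:::knn_score(m$fit$M_train[rd$oob, , drop = FALSE],
                                        m$fit$y_train[rd$oob], M, 10))
    predict(rd$tree, newdata = data.frame(aug), type = "prob")[, "tumor"]
  }, numeric(5)))
  expect_equal(s, manual)
})

test_that("equal-error threshold minimizes |sens - spec| over observed scores", {
  # perfectly separated scores: sens = spec = 1
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- rep(c("fibroblast", "tumor"), each = 3)
  t <- equal_error_threshold(s, y)
  expect_equal(attr(t, "sensitivity"), 1)
  expect_equal(attr(t, "specificity"), 1)

  # identical distributions: sens ~ spec ~ 0.5
  set.seed(6)
  s <- runif(400)
  y <- rep(c("fibroblast", "tumor"), 200)
  t <- equal_error_threshold(s, y)
  expect_lt(abs(attr(t, "sensitivity") - 0.5), 0.1)
  expect_lt(abs(attr(t, "specificity") - 0.5), 0.1)

  # exhaustive oracle over all observed scores
  set.seed(7)
  s <- c(rnorm(50, 0.4, 0.2), rnorm(50, 0.6, 0.2))
  y <- rep(c("fibroblast", "tumor"), each = 50)
  t <- equal_error_threshold(s, y)
  gaps <- vapply(sort(unique(s)), function(tt) {
    abs(mean(s[y == "tumor"] >= tt) - mean(s[y == "fibroblast"] < tt))
  }, numeric(1))
  expect_equal(abs(attr(t, "sensitivity") - attr(t, "specificity")), min(gaps))
})

test_that("cross-validation folds partition the data and runs are reproducible", {
  d <- toy_data(50, gap = 1.5)
  cv1 <- cross_validate(classifier_spec("logistic"), d$X, d$y, k = 10, seed = 5)
  cv2 <- cross_validate(classifier_spec("logistic"), d$X, d$y, k = 10, seed = 5)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_setequal(unique(cv1$fold), 1:10)
  expect_equal(length(cv1$fold), nrow(d$X))
  # stratification: each fold contains both classes
  for (f in 1:10) expect_equal(length(unique(d$y[cv1$fold == f])), 2)
})

test_that("permuted labels give chance-level AUC, separable textures near-perfect", {
  feats <- labeled_features(1:6)
  rd <- reduced_design(feats)
  cv <- cross_validate(classifier_spec("svm_gaussian"), rd$X, rd$y, seed = 2)
  expect_gte(cv$metrics["ACC"], 0.9)
  expect_gte(cv$metrics["AUC"], 0.95)

  aucs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    yp <- sample(rd$y)
    cross_validate(classifier_spec("logistic"), rd$X, yp,
                   seed = 100 + s)$metrics["AUC"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("majority voting labels regions and drops ties", {
  regions <- matrix(0L, 10, 12)
  regions[1:5, 1:6] <- 1L; regions[6:10, 1:6] <- 2L; regions[1:4, 7:12] <- 3L
  paint <- matrix(0L, 10, 12)
  paint[1:5, 1:6] <- 1L                       # region 1: pure tumor
  paint[6:10, 1:3] <- 1L; paint[6:8, 4] <- 1L   # region 2: 18 tumor px
  paint[9:10, 4] <- 2L; paint[6:10, 5:6] <- 2L   # region 2: 12 fibroblast px
  paint[1:2, 7:12] <- 1L; paint[3:4, 7:12] <- 2L # region 3: exact tie
  lab <- majority_vote_labels(regions, paint)
  expect_equal(nrow(lab), 2)
  expect_equal(lab$label[lab$region_id == 1], "tumor")
  expect_equal(lab$vote_fraction[lab$region_id == 1], 1.0)
  expect_equal(lab$label[lab$region_id == 2], "tumor")
  expect_equal(lab$vote_fraction[lab$region_id == 2], 0.6)
  expect_false(3 %in% lab$region_id)
})

test_that("well classification covers every foreground pixel exactly once", {
  feats <- labeled_features(1:5)
  rd <- reduced_design(feats)
  set.seed(8)
  cv <- cross_validate(classifier_spec("svm_gaussian"), rd$X, rd$y, seed = 8)
  model <- train_classifier(classifier_spec("svm_gaussian"), rd$X, rd$y)
  model$threshold <- cv$threshold
  w <- generate_well(small_well_params(55))
  m <- threshold_mask(w$image)
  cm <- classify_well(w$image, model, rd$reducer, mask = m)
  expect_true(all((cm$class > 0) == (m > 0)))
  classified <- cm$class %in% 1:2
  expect_true(all(cm$certainty[classified] >= 0.5 - 1e-9))
  expect_true(all(cm$certainty[classified] <= 1))

  # a well containing only isolated single cells classifies no region
  ws <- matrix(0.01, 100, 120)
  for (cc in list(c(20, 20), c(20, 60), c(60, 30), c(80, 100)))
    ws[disc_mask(100, 120, cc[1], cc[2], 5) == 1] <- 0.7
  ms <- threshold_mask(ws, threshold_config(use_entropy = FALSE))
  cms <- classify_well(ws, model, rd$reducer, mask = ms)
  expect_gt(sum(cms$class == 3), 0)
  expect_equal(sum(cms$class %in% 1:2), 0)
})
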