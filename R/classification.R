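# Supervised tumor-vs-fibroblast classification of foreground regions:
# four model families (logistic regression, random forest, Gaussian-kernel
# SVM, and a bundling ensemble), stratified 10-fold cross-validation, and an
# equal-sensitivity/specificity decision threshold.

CLASS_LEVELS <- c("fibroblast", "tumor") # higher score = tumor

#' Classifier specification
#'
#' @param family one of `"logistic"`, `"random_forest"`, `"svm_gaussian"`,
#'   `"bundle"`.
#' @param n_trees random forest trees (default 1000).
#' @param min_node_fraction minimum fraction of observations in terminal
#'   nodes, from the menu `{0.025, 0.05, 0.10}`.
#' @param cost SVM cost parameter, from the menu `{1, 10, 100}`.
#' @param n_bootstrap bundling bootstrap rounds (default 20).
#' @param knn_k neighbor counts of the bundled k-NN base learners.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("logistic", "random_forest",
                                       "svm_gaussian", "bundle"),
                            n_trees = 1000, min_node_fraction = 0.05,
                            cost = 10, n_bootstrap = 20, knn_k = c(5, 10)) {
  family <- match.arg(family)
  stopifnot(min_node_fraction %in% c(0.025, 0.05, 0.10),
            cost %in% c(1, 10, 100))
  structure(list(family = family, n_trees = n_trees,
                 min_node_fraction = min_node_fraction, cost = cost,
                 n_bootstrap = n_bootstrap, knn_k = knn_k),
            class = "classifier_spec")
}

# design matrix: numeric PCs plus dummy-coded culture method
as_design_matrix <- function(X) {
  X <- as.data.frame(X)
  num <- vapply(X, is.numeric, logical(1))
  M <- as.matrix(X[, num, drop = FALSE])
  for (cn in names(X)[!num]) {
    f <- factor(X[[cn]])
    if (nlevels(f) > 1)
      M <- cbind(M, stats::model.matrix(~ f - 1)[, -1, drop = FALSE])
  }
  M
}

# Gaussian-kernel width by the quantile heuristic: inverse of the median of
# pairwise squared distances between (subsampled) training points
estimate_svm_gamma <- function(M, max_points = 300) {
  n <- nrow(M)
  idx <- if (n > max_points) sample(n, max_points) else seq_len(n)
  d2 <- as.vector(dist(M[idx, , drop = FALSE]))^2
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) return(1)
  1 / median(d2)
}

# k-NN tumor-probability scorer via class::knn (vote share of the winner)
knn_score <- function(train_M, train_y, test_M, k) {
  k <- min(k, nrow(train_M))
  pred <- class::knn(train_M, test_M, train_y, k = k, prob = TRUE)
  p <- attr(pred, "prob")
  ifelse(pred == "tumor", p, 1 - p)
}

#' Train a region classifier
#'
#' All families expose a common `score` on \[0, 1\] for the tumor class.
#' The SVM kernel width is auto-estimated by the pairwise-distance quantile
#' heuristic; bundling draws `n_bootstrap` bootstrap samples, trains the
#' base learners (logistic regression, 5-NN, 10-NN) on the out-of-bag
#' pixels, feeds their predictions to a decision tree fitted on the in-bag
#' sample, and averages the trees' probability predictions.
#'
#' @param spec a [classifier_spec()].
#' @param X data.frame/matrix of predictors (principal components and the
#'   culture-method covariate).
#' @param y factor or character with levels `fibroblast`/`tumor`; both must
#'   be present.
#' @return a `region_classifier` with a `score_fn`-style predict method;
#'   use [predict_scores()].
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- factor(y, levels = CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present in y")
  X <- as.data.frame(X)
  M <- as_design_matrix(X)
  fit <- switch(spec$family,
    logistic = {
      d <- data.frame(y = y, M)
      list(model = suppressWarnings(glm(y ~ ., data = d, family = binomial())))
    },
    random_forest = {
      nodesize <- max(1, ceiling(spec$min_node_fraction * nrow(M)))
      list(model = randomForest::randomForest(
        x = M, y = y, ntree = spec$n_trees,
        mtry = max(1, floor(sqrt(ncol(M)))), nodesize = nodesize))
    },
    svm_gaussian = {
      gamma <- estimate_svm_gamma(M)
      # scores come from the decision values (deterministic), mapped to
      # [0, 1] by the logistic function
      list(model = e1071::svm(x = M, y = y, kernel = "radial", gamma = gamma,
                              cost = spec$cost),
           gamma = gamma)
    },
    bundle = {
      rounds <- vector("list", spec$n_bootstrap)
      n <- nrow(M)
      for (b in seq_len(spec$n_bootstrap)) {
        inbag <- sample(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(inbag))
        if (length(oob) < 5 || nlevels(droplevels(y[oob])) < 2 ||
            nlevels(droplevels(y[inbag])) < 2) {
          oob <- seq_len(n) # degenerate resample: fall back to full data
        }
        dlog <- data.frame(y = y[oob], M[oob, , drop = FALSE])
        base_log <- suppressWarnings(glm(y ~ ., data = dlog, family = binomial()))
        aug <- function(idx) {
          nd <- data.frame(M[idx, , drop = FALSE])
          cbind(M[idx, , drop = FALSE],
                p_log = predict(base_log, newdata = nd, type = "response"),
                p_knn5 = knn_score(M[oob, , drop = FALSE], y[oob],
                                   M[idx, , drop = FALSE], spec$knn_k[1]),
                p_knn10 = knn_score(M[oob, , drop = FALSE], y[oob],
                                    M[idx, , drop = FALSE], spec$knn_k[2]))
        }
        dtree <- data.frame(y = y[inbag], aug(inbag))
        tree <- rpart::rpart(y ~ ., data = dtree, method = "class",
                             control = rpart::rpart.control(cp = 0.01))
        rounds[[b]] <- list(base_log = base_log, oob = oob, tree = tree)
      }
      list(rounds = rounds, M_train = M, y_train = y)
    }
  )
  structure(list(spec = spec, fit = fit, columns = colnames(M),
                 threshold = 0.5),
            class = "region_classifier")
}

#' Tumor scores for new observations
#'
#' @param model a [train_classifier()] result.
#' @param X predictors with the training columns.
#' @return numeric vector of tumor-class scores on \[0, 1\].
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "region_classifier"))
  M <- as_design_matrix(as.data.frame(X))
  missing <- setdiff(model$columns, colnames(M))
  for (cn in missing) M <- cbind(M, setNames(data.frame(0), cn))
  M <- as.matrix(as.data.frame(M)[, model$columns, drop = FALSE])
  spec <- model$spec
  switch(spec$family,
    logistic = as.numeric(predict(model$fit$model,
                                  newdata = data.frame(M), type = "response")),
    random_forest = predict(model$fit$model, newdata = M,
                            type = "prob")[, "tumor"],
    svm_gaussian = {
      pr <- predict(model$fit$model, newdata = M, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      tumor_first <- startsWith(colnames(dv)[1], "tumor")
      as.numeric(stats::plogis(if (tumor_first) dv[, 1] else -dv[, 1]))
    },
    bundle = {
      preds <- vapply(model$fit$rounds, function(rd) {
        nd <- data.frame(M)
        aug <- cbind(M,
          p_log = predict(rd$base_log, newdata = nd, type = "response"),
          p_knn5 = knn_score(model$fit$M_train[rd$oob, , drop = FALSE],
                             model$fit$y_train[rd$oob], M, spec$knn_k[1]),
          p_knn10 = knn_score(model$fit$M_train[rd$oob, , drop = FALSE],
                              model$fit$y_train[rd$oob], M, spec$knn_k[2]))
        predict(rd$tree, newdata = data.frame(aug), type = "prob")[, "tumor"]
      }, numeric(nrow(M)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
      rowMeans(preds)
    }
  )
}

#' Equal-sensitivity/specificity decision threshold
#'
#' Scans the observed scores as candidate thresholds (classification rule:
#' tumor iff `score >= t`) and returns the one minimizing
#' `|sensitivity - specificity|`; ties resolve to the lowest threshold.
#'
#' @param scores tumor scores.
#' @param labels true labels (`fibroblast`/`tumor`).
#' @return threshold, with attributes `sensitivity` and `specificity`.
#' @export
equal_error_threshold <- function(scores, labels) {
  y <- factor(labels, levels = CLASS_LEVELS)
  stopifnot(all(table(y) > 0))
  cand <- sort(unique(scores))
  npos <- sum(y == "tumor"); nneg <- sum(y == "fibroblast")
  sens <- vapply(cand, function(t) sum(scores >= t & y == "tumor") / npos,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(scores < t & y == "fibroblast") / nneg,
                 numeric(1))
  k <- which.min(abs(sens - spec)) # which.min takes the first (lowest) tie
  structure(cand[k], sensitivity = sens[k], specificity = spec[k])
}

# threshold-free AUC via the rank-sum statistic
rank_auc <- function(scores, y) {
  y <- factor(y, levels = CLASS_LEVELS)
  r <- rank(scores)
  n1 <- sum(y == "tumor"); n0 <- sum(y == "fibroblast")
  (sum(r[y == "tumor"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by class; out-of-fold tumor scores are pooled, the
#' equal-sensitivity/specificity threshold is calibrated on the pooled
#' scores, and accuracy, F1 (tumor as the reference class) and the common
#' sensitivity/specificity value are computed at that threshold.  AUC is
#' threshold-free.
#'
#' @param spec a [classifier_spec()].
#' @param X,y as in [train_classifier()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and any training
#'   randomness.
#' @return list with `metrics` (`AUC`, `ACC`, `F1`, `SensSpec`), pooled
#'   `scores`, `labels`, fold assignment and the calibrated `threshold`.
#' @export
cross_validate <- function(spec, X, y, k = 10, seed = 1L) {
  y <- factor(y, levels = CLASS_LEVELS)
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(n >= k)
  set.seed(seed)
  fold <- integer(n)
  for (cl in CLASS_LEVELS) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    ytr <- droplevels(y[!test])
    if (nlevels(ytr) < 2) stop("a class is absent from a training fold")
    model <- train_classifier(spec, X[!test, , drop = FALSE], y[!test])
    scores[test] <- predict_scores(model, X[test, , drop = FALSE])
  }
  thr <- equal_error_threshold(scores, y)
  pred <- factor(ifelse(scores >= thr, "tumor", "fibroblast"),
                 levels = CLASS_LEVELS)
  tp <- sum(pred == "tumor" & y == "tumor")
  fp <- sum(pred == "tumor" & y == "fibroblast")
  fn <- sum(pred == "fibroblast" & y == "tumor")
  acc <- mean(pred == y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  metrics <- c(AUC = rank_auc(scores, y), ACC = acc, F1 = f1,
               SensSpec = mean(c(attr(thr, "sensitivity"),
                                 attr(thr, "specificity"))))
  list(metrics = metrics, scores = scores, labels = y, fold = fold,
       threshold = as.numeric(thr))
}

#' Compare classifier families by cross-validation
#'
#' Runs [cross_validate()] for each supplied specification and returns one
#' row of metrics per family variant; the best variant per family (by AUC)
#' mirrors the model-selection protocol of the screening pipeline.
#'
#' @param specs list of [classifier_spec()] objects.
#' @param X,y,k,seed as in [cross_validate()].
#' @return data.frame with columns `family`, `AUC`, `ACC`, `F1`, `SensSpec`.
#' @export
compare_classifiers <- function(specs, X, y, k = 10, seed = 1L) {
  rows <- lapply(specs, function(s) {
    cv <- cross_validate(s, X, y, k = k, seed = seed)
    data.frame(family = s$family, t(cv$metrics))
  })
  do.call(rbind, rows)
}

#' Region labels from expert class paintings by majority vote
#'
#' Sums tumor and fibroblast pixel votes over all paintings within each
#' region; the label is the larger total and the vote fraction its share.
#' Regions with zero painted pixels or an exact tie are excluded.
#'
#' @param regions integer region label matrix.
#' @param paintings list of integer matrices with 1 = tumor, 2 = fibroblast,
#'   0 = unpainted (a ground-truth map is a valid single painting).
#' @return data.frame with `region_id`, `label`, `vote_fraction`
#'   (in (0.5, 1\]).
#' @export
majority_vote_labels <- function(regions, paintings) {
  if (!is.list(paintings)) paintings <- list(paintings)
  px <- split_labels(regions)
  rows <- lapply(names(px), function(id) {
    idx <- px[[id]]
    tumor <- sum(vapply(paintings, function(p) sum(p[idx] == TRUTH_TUMOR),
                        numeric(1)))
    fibro <- sum(vapply(paintings, function(p) sum(p[idx] == TRUTH_FIBROBLAST),
                        numeric(1)))
    if (tumor + fibro == 0 || tumor == fibro) return(NULL)
    data.frame(region_id = as.integer(id),
               label = if (tumor > fibro) "tumor" else "fibroblast",
               vote_fraction = max(tumor, fibro) / (tumor + fibro))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = integer(), label = character(),
                      vote_fraction = numeric())
  out
}

#' Classify a well into a per-pixel class map
#'
#' Thresholds the image (unless a mask is supplied), sets rounded single
#' cells aside without classification, partitions the remaining foreground
#' into seeded regions, extracts and reduces texture features, scores each
#' region with the trained model, and paints each region tumor or fibroblast
#' by the model's decision threshold.  Per-pixel certainty is
#' `max(score, 1 - score)` of the pixel's region.
#'
#' @param image grayscale matrix.
#' @param model a [train_classifier()] result whose `threshold` has been
#'   calibrated (e.g. set to [cross_validate()]'s threshold).
#' @param reducer the [fit_reducer()] fitted on the training features.
#' @param mask optional precomputed foreground mask.
#' @param rule a [single_cell_rule()].
#' @param cfg a [threshold_config()] (used when `mask` is missing).
#' @param target_area region seed target area.
#' @param culture_method covariate value for this well.
#' @return list with `class` (integer matrix: 0 background, 1 tumor,
#'   2 fibroblast, 3 rounded single) and `certainty` (numeric matrix; 1 for
#'   single cells, `max(score, 1-score)` for classified regions, 0 on
#'   background), plus the `regions` and region `scores`.
#' @export
classify_well <- function(image, model, reducer, mask = NULL,
                          rule = single_cell_rule(),
                          cfg = threshold_config(), target_area = 350,
                          culture_method = "freezer") {
  if (is.null(mask)) mask <- threshold_mask(image, cfg)
  split <- extract_rounded_single_cells(mask, rule)
  classmap <- matrix(0L, nrow(image), ncol(image))
  certainty <- matrix(0, nrow(image), ncol(image))
  classmap[split$single_cells > 0] <- TRUTH_SINGLE
  certainty[split$single_cells > 0] <- 1
  scores <- numeric(0)
  regions <- matrix(0L, nrow(image), ncol(image))
  if (any(split$remaining > 0)) {
    seeds <- hex_seeds(split$remaining, target_area)
    regions <- propagate_regions(split$remaining, seeds)
    feats <- region_features(image, regions, culture_method)
    Z <- apply_reducer(reducer, feats[, feature_columns(feats), drop = FALSE])
    Xn <- data.frame(Z, culture_method = feats$culture_method)
    scores <- predict_scores(model, Xn)
    names(scores) <- feats$region_id
    for (i in seq_len(nrow(feats))) {
      idx <- which(regions == feats$region_id[i])
      cls <- if (scores[i] >= model$threshold) TRUTH_TUMOR else TRUTH_FIBROBLAST
      classmap[idx] <- cls
      certainty[idx] <- max(scores[i], 1 - scores[i])
    }
  }
  list(class = classmap, certainty = certainty, regions = regions,
       scores = scores)
}
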