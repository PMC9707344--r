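# Normal-vs-abnormal classification harness, PCA projection, feature
# importance, and the intra/inter-class distance analysis.

meta_cols <- c("recording_id", "subject", "label", "device", "test")

# Split a feature table into metadata and numeric feature matrix.
split_table <- function(table) {
  feats <- setdiff(names(table), meta_cols)
  x <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na))
    nk_stop(paste("all-missing feature columns:",
                  paste(feats[all_na], collapse = ", ")), "neurokin_format_error")
  list(meta = table[, intersect(meta_cols, names(table)), drop = FALSE], x = x)
}

# Imputation + standardization fitted on training rows only.
preproc_fit <- function(x) {
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  xi <- x
  for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- med[j]
  ctr <- colMeans(xi)
  scl <- apply(xi, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(medians = med, centers = ctr, scales = scl)
}

preproc_apply <- function(pp, x) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pp$medians[j]
  scale(x, center = pp$centers, scale = pp$scales)[, , drop = FALSE]
}

#' Cross-validation fold assignments
#'
#' `"video"` splitting stratifies recordings by label into `n_folds` folds;
#' `"subject"` splitting assigns whole subjects to folds, so no subject's
#' recordings span the train/test boundary (with 20 subjects and 5 folds,
#' each test fold holds exactly 4 subjects).
#'
#' @param table a feature table from [features_to_table()].
#' @param scheme `"video"` or `"subject"`.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..n_folds), one per row.
#' @export
make_splits <- function(table, scheme = c("video", "subject"), n_folds = 5L,
                        seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(derive_seed(seed, 11L))
  n <- nrow(table)
  fold <- integer(n)
  if (scheme == "video") {
    for (lab in unique(table$label)) {
      idx <- sample(which(table$label == lab))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    subjects <- unique(table$subject)
    if (length(subjects) < n_folds)
      nk_stop("subject-wise splitting needs at least n_folds subjects",
              "neurokin_format_error")
    sf <- rep_len(seq_len(n_folds), length(subjects))[sample(length(subjects))]
    fold <- sf[match(table$subject, subjects)]
  }
  fold
}

# One model fit + probability prediction. x matrices are standardized.
fit_predict <- function(model, x_train, y_train, x_test, seed) {
  set.seed(seed)
  y_fac <- factor(y_train, levels = c("normal", "abnormal"))
  y01 <- as.integer(y_fac == "abnormal")
  switch(model,
    rf = {
      fit <- randomForest::randomForest(x_train, y_fac, ntree = 500)
      stats::predict(fit, x_test, type = "prob")[, "abnormal"]
    },
    gbm = {
      fit <- xgboost::xgboost(data = x_train, label = y01, nrounds = 200,
                              params = list(objective = "binary:logistic",
                                            max_depth = 3, eta = 0.1,
                                            nthread = 1),
                              verbose = 0)
      stats::predict(fit, x_test)
    },
    xgb = {
      fit <- xgboost::xgboost(data = x_train, label = y01, nrounds = 200,
                              params = list(objective = "binary:logistic",
                                            max_depth = 3, eta = 0.1,
                                            subsample = 0.8,
                                            colsample_bytree = 0.8,
                                            nthread = 1),
                              verbose = 0)
      stats::predict(fit, x_test)
    },
    lr = {
      fit <- glmnet::glmnet(x_train, y_fac, family = "binomial", alpha = 0,
                            lambda = 1 / nrow(x_train))
      as.numeric(stats::predict(fit, x_test, type = "response"))
    },
    rsvm = {
      fit <- e1071::svm(x_train, y_fac, kernel = "radial", cost = 1,
                        probability = TRUE)
      pr <- stats::predict(fit, x_test, probability = TRUE)
      attr(pr, "probabilities")[, "abnormal"]
    },
    mlp = {
      fit <- nnet::nnet(x_train, y01, size = 64, decay = 1e-3, maxit = 500,
                        MaxNWts = 100000, trace = FALSE, entropy = TRUE)
      as.numeric(stats::predict(fit, x_test))
    },
    nk_stop(sprintf("unknown model '%s'", model), "neurokin_format_error"))
}

# Average precision (area under the precision-recall curve by the standard
# step interpolation at each positive).
average_precision <- function(y01, p) {
  o <- order(p, decreasing = TRUE)
  y <- y01[o]
  if (sum(y) == 0L) return(NA_real_)
  cum_tp <- cumsum(y)
  prec_at <- cum_tp / seq_along(y)
  mean(prec_at[y == 1L])
}

binary_metrics <- function(y_true, p, threshold = 0.5) {
  y01 <- as.integer(y_true == "abnormal")
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y01 == 1L); fp <- sum(pred == 1L & y01 == 0L)
  tn <- sum(pred == 0L & y01 == 0L); fn <- sum(pred == 0L & y01 == 1L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  auc <- if (length(unique(y01)) == 2L)
    as.numeric(pROC::auc(pROC::roc(y01, p, levels = c(0, 1), direction = "<",
                                   quiet = TRUE))) else NA_real_
  c(accuracy = (tp + tn) / length(y01), precision = prec, recall = rec,
    specificity = spec, f1 = f1, auc = auc,
    ap = average_precision(y01, p))
}

#' Train and evaluate classifiers under cross-validation
#'
#' For every fold: median imputation and z-score standardization are fitted
#' on the training rows only and applied to both sides (no information
#' leakage); each requested model is trained on the standardized training
#' fold and scored on the held-out fold; metrics (accuracy, precision,
#' recall, specificity, F1, AUC, average precision; positive class =
#' abnormal) are averaged across folds. Deterministic given (table, splits,
#' seed). Folds whose training side is single-class are skipped with a
#' warning recorded in the report.
#'
#' @param table a feature table from [features_to_table()].
#' @param models subset of `c("rf", "gbm", "xgb", "lr", "rsvm", "mlp")`.
#' @param splits fold assignment from [make_splits()].
#' @param seed RNG seed.
#' @return An `eval_report`: `metrics` (one row per model, fold-averaged),
#'   `per_fold`, `n_folds`, `seed`, `skipped_folds`.
#' @export
train_eval <- function(table, models = c("rf", "gbm", "xgb", "lr", "rsvm", "mlp"),
                       splits = make_splits(table, "subject", seed = seed),
                       seed = 1L) {
  st <- split_table(table)
  y <- st$meta$label
  folds <- sort(unique(splits))
  per_fold <- list()
  skipped <- integer()
  for (k in folds) {
    tr <- splits != k; te <- splits == k
    if (length(unique(y[tr])) < 2L || sum(te) == 0L) {
      skipped <- c(skipped, k)
      warning(sprintf("fold %d skipped: degenerate training labels", k))
      next
    }
    pp <- preproc_fit(st$x[tr, , drop = FALSE])
    xtr <- preproc_apply(pp, st$x[tr, , drop = FALSE])
    xte <- preproc_apply(pp, st$x[te, , drop = FALSE])
    for (mi in seq_along(models)) {
      p <- fit_predict(models[mi], xtr, y[tr], xte,
                       seed = derive_seed(seed, k, mi))
      m <- binary_metrics(y[te], p)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(model = models[mi], fold = k, t(m))
    }
  }
  pf <- do.call(rbind, per_fold)
  metric_names <- c("accuracy", "precision", "recall", "specificity", "f1",
                    "auc", "ap")
  agg <- stats::aggregate(pf[metric_names], by = list(model = pf$model),
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg <- agg[match(models, agg$model), ]
  rownames(agg) <- NULL
  structure(list(metrics = agg, per_fold = pf, n_folds = length(folds),
                 seed = seed, skipped_folds = skipped),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds (seed %d)\n", x$n_folds, x$seed))
  print(cbind(x$metrics[1L], round(x$metrics[-1L], 4)))
  invisible(x)
}

#' Project recordings on principal components
#'
#' Features are median-imputed, z-scored and projected on the top `k`
#' principal components. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param table a feature table from [features_to_table()].
#' @param k number of components (default 2).
#' @return list with `scores` (n x k), `explained_variance` (full proportion
#'   vector), `loadings`, and `labels`.
#' @export
pca_project <- function(table, k = 2L) {
  st <- split_table(table)
  pp <- preproc_fit(st$x)
  xs <- preproc_apply(pp, st$x)
  keep <- apply(xs, 2L, function(v) stats::sd(v) > 0)
  if (!any(keep)) nk_stop("all features constant", "neurokin_degenerate")
  xs <- xs[, keep, drop = FALSE]
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2L, flip, "*")
  scores <- xs %*% rot[, seq_len(min(k, ncol(rot))), drop = FALSE]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained_variance = ev,
       loadings = rot[, seq_len(min(k, ncol(rot))), drop = FALSE],
       labels = st$meta$label)
}

#' Random-forest feature importance
#'
#' Impurity-based (mean decrease in Gini) importances of a random forest fit
#' on the full table, normalized to sum to one and sorted descending.
#'
#' @param table a feature table from [features_to_table()].
#' @param seed RNG seed.
#' @param ntree forest size (default 500).
#' @return named numeric vector of weights summing to 1.
#' @export
feature_importance <- function(table, seed = 1L, ntree = 500L) {
  st <- split_table(table)
  pp <- preproc_fit(st$x)
  xs <- preproc_apply(pp, st$x)
  set.seed(derive_seed(seed, 7L))
  fit <- randomForest::randomForest(xs, factor(st$meta$label,
                                               levels = c("normal", "abnormal")),
                                    ntree = ntree)
  imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  w <- imp / sum(imp)
  sort(w, decreasing = TRUE)
}

#' Intra- and inter-class feature distances across devices
#'
#' Each subject contributes four recordings: normal and abnormal on each of
#' two devices. Per feature and subject: A-A is the distance between the two
#' abnormal recordings' feature values (across devices), N-N between the two
#' normal ones, and N-A the average of the two cross-label, cross-device
#' pairs. Distances are normalized per feature by the maximum N-A across
#' subjects, so N-A spans (0, 1] and device robustness shows as A-A and N-N
#' concentrating near zero.
#'
#' @param table a feature table from [features_to_table()] with `subject`,
#'   `label` and `device` columns (exactly two devices).
#' @param features optional feature-name subset.
#' @return data.frame with columns `feature`, `subject`, `pair` (A-A, N-N,
#'   N-A) and `distance` (normalized).
#' @export
pairwise_distance_analysis <- function(table, features = NULL) {
  devs <- sort(unique(table$device))
  if (length(devs) != 2L)
    nk_stop("distance analysis requires exactly two devices", "neurokin_format_error")
  feats <- features %||% setdiff(names(table), meta_cols)
  rows <- list()
  for (f in feats) {
    vals <- list()
    for (s in unique(table$subject)) {
      pick <- function(lab, dev) {
        v <- table[table$subject == s & table$label == lab & table$device == dev, f]
        if (length(v) != 1L || is.na(v)) NA_real_ else v
      }
      a1 <- pick("abnormal", devs[1L]); a2 <- pick("abnormal", devs[2L])
      n1 <- pick("normal", devs[1L]); n2 <- pick("normal", devs[2L])
      if (anyNA(c(a1, a2, n1, n2))) next   # subject skipped for this feature
      vals[[s]] <- c(`A-A` = abs(a1 - a2), `N-N` = abs(n1 - n2),
                     `N-A` = mean(c(abs(a1 - n2), abs(n1 - a2))))
    }
    if (length(vals) == 0L) next
    m <- do.call(rbind, vals)
    mx <- max(m[, "N-A"])
    if (mx == 0) next
    m <- m / mx
    for (s in rownames(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, subject = s, pair = colnames(m),
        distance = as.numeric(m[s, ]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
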