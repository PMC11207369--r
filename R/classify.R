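#' Balanced class weights
#'
#' The window dataset is heavily imbalanced (respiring dominates), which
#' drags a plain classifier toward the majority class.  Balanced weighting
#' assigns each class the weight `N / (k * n_c)` (total count over classes
#' times class count), so minority classes get proportionally larger
#' weights.
#'
#' @param labels Factor or character vector of training labels.
#' @return Named numeric weight per class.
#' @examples
#' round(make_class_weights(rep(c("resp", "hold", "swal"),
#'                              c(5272, 950, 611))), 2)
#' @export
make_class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 1L || any(tab == 0)) {
    stop("every class must have at least one instance", call. = FALSE)
  }
  w <- sum(tab) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Training configuration
#'
#' @param model_kind `"tree-ensemble"` (random forest), `"margin-linear"`
#'   or `"margin-rbf"` (support vector machine with the given kernel).
#' @param grid Data frame of hyperparameter combinations to search, or
#'   `NULL` for the built-in default grid: cost `C` in `{0.1, 1, 10, 100}`
#'   and `gamma` multipliers `{0.1, 1, 10}` of the scale heuristic
#'   `1 / (p * var(X))` for margin models; `trees` in `{100, 300}`, `depth`
#'   in `{0 (unlimited), 5, 10}` and `mtry_rule` in `{"sqrt", "log2"}` for
#'   the tree ensemble.
#' @param class_weight `"balanced"` applies [make_class_weights()] during
#'   training; `"none"` trains unweighted.
#' @param cv `"loso"` for leave-one-subject-out grouped cross-validation,
#'   or an integer number of grouped folds (subjects assigned whole to
#'   folds).
#' @param seed Seed for the tree ensemble and fold assignment.
#' @return An object of class `train_config`.
#' @export
train_config <- function(model_kind = c("tree-ensemble", "margin-linear",
                                        "margin-rbf"),
                         grid = NULL,
                         class_weight = c("balanced", "none"),
                         cv = "loso",
                         seed = 1) {
  model_kind <- match.arg(model_kind)
  class_weight <- match.arg(class_weight)
  if (is.null(grid)) {
    grid <- switch(model_kind,
      "tree-ensemble" = expand.grid(trees = c(100, 300),
                                    depth = c(0, 5, 10),
                                    mtry_rule = c("sqrt", "log2"),
                                    stringsAsFactors = FALSE),
      "margin-linear" = data.frame(C = c(0.1, 1, 10, 100)),
      "margin-rbf" = expand.grid(C = c(0.1, 1, 10, 100),
                                 gamma_mult = c(0.1, 1, 10)))
  }
  if (!nrow(grid)) stop("hyperparameter grid must be nonempty", call. = FALSE)
  structure(list(model_kind = model_kind, grid = grid,
                 class_weight = class_weight, cv = cv, seed = seed),
            class = "train_config")
}

# fit one model on (x, y) with one grid row
fit_one <- function(x, y, params, config, weights) {
  x <- as.data.frame(x)
  weights <- weights[levels(y)] # a fold may lack a class entirely
  if (config$model_kind == "tree-ensemble") {
    p <- ncol(x)
    mtry <- switch(as.character(params$mtry_rule),
                   sqrt = max(1L, floor(sqrt(p))),
                   log2 = max(1L, floor(log2(p))))
    ranger::ranger(x = x, y = y,
                   num.trees = params$trees,
                   max.depth = params$depth,
                   mtry = min(mtry, p),
                   class.weights = as.numeric(weights),
                   seed = config$seed, num.threads = 1L)
  } else {
    scale_cols <- apply(x, 2L, stats::sd) > 0
    if (config$model_kind == "margin-linear") {
      e1071::svm(x = x, y = y, kernel = "linear", cost = params$C,
                 class.weights = weights, scale = scale_cols)
    } else {
      g0 <- 1 / (ncol(x) * max(stats::var(as.vector(as.matrix(x))), 1e-12))
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$C,
                 gamma = g0 * params$gamma_mult,
                 class.weights = weights, scale = scale_cols)
    }
  }
}

predict_one <- function(model, x) {
  x <- as.data.frame(x)
  if (inherits(model, "ranger")) {
    # fixed predict seed: majority-vote ties must break reproducibly
    stats::predict(model, data = x, num.threads = 1L,
                   seed = 1L)$predictions
  } else {
    stats::predict(model, newdata = x)
  }
}

#' Tune and train a swallowing/respiration classifier
#'
#' Grid search over the configuration's hyperparameter grid, scored by
#' macro-averaged F1 under grouped cross-validation (groups are subjects,
#' so no subject contributes to both sides of a fold).  Held-out
#' predictions of all folds are pooled into one confusion matrix per grid
#' point; the best combination is refit on all data.
#'
#' @param features Numeric feature matrix or data frame (rows = windows).
#' @param labels Class labels (factor or character).
#' @param groups Subject identifier per row.
#' @param config A [train_config()].
#' @return An object of class `swallow_classifier` with elements `model`,
#'   `config`, `best_params`, `cv_macro_f1`, `cv_report` (a
#'   [evaluate()] report of the pooled held-out predictions at the best
#'   grid point), `class_weights`, and `levels`.
#' @export
tune_and_train <- function(features, labels, groups, config = train_config()) {
  features <- as.data.frame(features)
  y <- factor(labels)
  groups <- as.character(groups)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  if (length(unique(groups)) < 2L) stop("need at least two groups", call. = FALSE)
  if (nrow(features) != length(y) || length(y) != length(groups)) {
    stop("features, labels and groups must align", call. = FALSE)
  }
  weights <- if (config$class_weight == "balanced") {
    make_class_weights(y)
  } else {
    stats::setNames(rep(1, nlevels(y)), levels(y))
  }

  ug <- unique(groups)
  fold_of <- if (identical(config$cv, "loso")) {
    stats::setNames(seq_along(ug), ug)
  } else {
    k <- as.integer(config$cv)
    if (is.na(k) || k < 2L) stop("`cv` must be \"loso\" or an integer >= 2", call. = FALSE)
    perm <- with_seed(config$seed, sample(length(ug)))
    stats::setNames(((perm - 1L) %% k) + 1L, ug)
  }
  folds <- fold_of[groups]
  for (cl in levels(y)) {
    present_in_training <- vapply(unique(folds), function(f) {
      any(y[folds != f] == cl)
    }, logical(1))
    if (!any(present_in_training)) {
      stop(sprintf("class '%s' is absent from every training fold", cl),
           call. = FALSE)
    }
  }
  for (f in unique(folds)) {
    if (length(unique(y[folds != f])) < 2L) {
      stop(sprintf(
        "degenerate fold: all but one class absent from the training data when fold '%s' is held out",
        f), call. = FALSE)
    }
  }

  grid <- config$grid
  scores <- numeric(nrow(grid))
  reports <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in unique(folds)) {
      tr <- folds != f
      model <- fit_one(features[tr, , drop = FALSE], droplevels(y[tr]),
                       grid[gi, , drop = FALSE], config, weights)
      ph <- predict_one(model, features[!tr, , drop = FALSE])
      pred[!tr] <- factor(as.character(ph), levels = levels(y))
    }
    rep_gi <- evaluate(y, pred)
    scores[gi] <- rep_gi$macro_f1
    reports[[gi]] <- rep_gi
  }
  best <- which.max(scores)
  final <- fit_one(features, y, grid[best, , drop = FALSE], config, weights)
  structure(list(model = final,
                 config = config,
                 best_params = grid[best, , drop = FALSE],
                 cv_macro_f1 = scores[best],
                 cv_report = reports[[best]],
                 cv_scores = cbind(grid, macro_f1 = scores),
                 class_weights = weights,
                 levels = levels(y),
                 feature_names = colnames(features)),
            class = "swallow_classifier")
}

#' @export
print.swallow_classifier <- function(x, ...) {
  cat(sprintf("<swallow_classifier> %s, classes: %s\n",
              x$config$model_kind, paste(x$levels, collapse = "/")))
  cat("  best hyperparameters: ",
      paste(names(x$best_params), unlist(x$best_params),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  grouped-CV macro-F1: %.3f\n", x$cv_macro_f1))
  invisible(x)
}

#' @rdname tune_and_train
#' @param object A `swallow_classifier`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @export
predict.swallow_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  factor(as.character(predict_one(object$model,
                                  newdata[, object$feature_names,
                                          drop = FALSE])),
         levels = object$levels)
}

#' Confusion matrix and per-class metrics
#'
#' Builds the k-by-k confusion matrix (rows = true class, columns =
#' predicted) and computes per-class precision, recall and F1 plus the
#' macro-averaged F1 (the unweighted mean over classes, which weights the
#' rare swallow class equally with respiring).  A class never predicted
#' gets precision 0 by convention; an undefined F1 is 0.
#'
#' @param y_true,y_pred Equal-length label vectors over a shared label set.
#' @param labels Optional class ordering; defaults to the union of observed
#'   labels in factor order.
#' @return An object of class `class_report`.
#' @export
evaluate <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (is.factor(y_true)) levels(y_true) else
      sort(unique(c(as.character(y_true), as.character(y_pred))))
    labels <- union(labels, unique(as.character(y_pred)))
  }
  conf <- table(true = factor(y_true, levels = labels),
                pred = factor(y_pred, levels = labels))
  conf <- unclass(conf)
  report_from_confusion(conf)
}

report_from_confusion <- function(conf) {
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = conf,
                 precision = prec, recall = rec, f1 = f1,
                 support = rowSums(conf),
                 macro_f1 = mean(f1)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, digits = 3, ...) {
  k <- nrow(x$confusion)
  cat("Confusion matrix (Ans. rows, Pred. columns):\n")
  print(x$confusion)
  tab <- data.frame(precision = round(x$precision, digits),
                    recall = round(x$recall, digits),
                    f1 = round(x$f1, digits),
                    support = x$support)
  print(tab)
  cat(sprintf("macro-averaged F1: %.*f\n", digits, x$macro_f1))
  invisible(x)
}

#' Macro-averaged F1 from a confusion matrix
#'
#' @param confusion Square nonnegative count matrix, rows = true class,
#'   columns = predicted class.
#' @return The unweighted mean of per-class F1 scores, in `[0, 1]`.
#' @examples
#' macro_f1(matrix(c(9, 1, 2, 8), 2, byrow = TRUE))
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("`confusion` must be square", call. = FALSE)
  }
  if (any(confusion < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(confusion) == 0) stop("`confusion` is all zero", call. = FALSE)
  report_from_confusion(confusion)$macro_f1
}

#' Window-size sweep
#'
#' Rebuilds the dataset, designed features and tuned classifier for each
#' candidate window size and reports the grouped-CV macro-F1 per size.
#' Windows much shorter than one respiratory cycle cannot show the cycle's
#' periodicity, so performance is expected to drop below about 4 s.
#'
#' @param recordings Recordings as for [build_dataset()].
#' @param sizes Window sizes to try, seconds.
#' @param config A [train_config()].
#' @param stride_s Window stride, seconds.
#' @return Data frame with columns `window_s`, `macro_f1`, `n_windows`.
#' @export
window_size_sweep <- function(recordings, sizes = c(2, 3, 4, 5, 6),
                              config = train_config(), stride_s = 1) {
  if (!length(sizes)) stop("`sizes` must be nonempty", call. = FALSE)
  res <- lapply(sizes, function(s) {
    ds <- build_dataset(recordings, window_s = s, stride_s = stride_s)
    ft <- designed_feature_table(ds)
    fit <- tune_and_train(ft[, -(1:3)], ft$label, ft$subject, config)
    data.frame(window_s = s, macro_f1 = fit$cv_macro_f1,
               n_windows = nrow(ft))
  })
  do.call(rbind, res)
}
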