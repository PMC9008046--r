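#' Assemble a feature matrix from graph measures and covariates
#'
#' Selects named features for every subject: `"<measure>_<band>"`
#' entries are taken from the long metrics table, anything else
#' (e.g. `sex`, `mmse`) from the covariate table. No scaling is applied
#' here — standardization is fitted on training folds inside
#' [evaluate_classifiers()] to avoid leakage; [standardize_features()]
#' exposes that transform.
#'
#' @param metrics Long metrics table from [cohort_metrics()].
#' @param covariates Covariate table with `subject_id` and `group`.
#' @param selected Character vector of feature names, e.g.
#'   `c("modularity_beta", "radius_gamma", "sex", "mmse")`.
#' @return List with `X` (numeric matrix, subjects x features),
#'   `labels` (factor with two levels, second level = positive class)
#'   and `subject_id`.
#' @export
build_features <- function(metrics, covariates, selected) {
  ids <- covariates$subject_id
  cols <- lapply(selected, function(f) {
    if (f %in% names(covariates)) {
      v <- covariates[[f]]
      if (!is.numeric(v)) stop("feature '", f, "' is not numeric")
      return(v)
    }
    # measure_band features: band is the suffix after the last "_"
    us <- gregexpr("_", f)[[1]]
    if (us[1] == -1) stop("feature not found: ", f)
    split <- max(us)
    meas <- substr(f, 1, split - 1)
    band <- substr(f, split + 1, nchar(f))
    sel <- metrics$measure == meas & metrics$band == band
    if (!any(sel)) stop("feature not found: ", f)
    v <- metrics$value[sel][match(ids, metrics$subject_id[sel])]
    if (anyNA(v)) stop("feature '", f, "' missing for some subjects")
    v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- selected
  if (anyDuplicated(selected)) stop("duplicate feature names")
  if (!all(is.finite(X))) stop("non-finite feature values")
  labels <- factor(covariates$group)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  list(X = X, labels = labels, subject_id = ids)
}

#' Standardize features on a training fold
#'
#' Centers and scales columns by training-fold mean and SD and applies
#' the same transform to the test fold (constant columns are left
#' centered only).
#'
#' @param X Feature matrix.
#' @param train Integer indices of the training rows.
#' @return List with `train` and `test` matrices.
#' @export
standardize_features <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- apply(X[train, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  scale_it <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
  list(train = scale_it(X[train, , drop = FALSE]),
       test = scale_it(X[-train, , drop = FALSE]))
}

# class-proportion-preserving train indices for one split
stratified_split <- function(labels, train_frac) {
  idx <- unlist(lapply(levels(labels), function(l) {
    pool <- which(labels == l)
    sample(pool, round(train_frac * length(pool)))
  }))
  sort(idx)
}

#' Confusion-matrix metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), accuracy
#' (TP+TN)/(TP+TN+FP+FN) and F1 = 2*precision*recall /
#' (precision+recall). Ratios with a zero denominator are reported as 0
#' with a warning.
#'
#' @param tp,fp,tn,fn Non-negative counts (not all zero).
#' @return Named list: `precision`, `recall`, `accuracy`, `f1`.
#' @examples
#' metric_from_confusion(8, 2, 8, 2)
#' @export
metric_from_confusion <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be >= 0")
  if (tp + fp + tn + fn == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (precision + recall = 0); reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall,
       accuracy = (tp + tn) / (tp + tn + fp + fn), f1 = f1)
}

# ---- the six classifiers ---------------------------------------------
# each fit function returns a closure scoring P(positive class) on new
# standardized data; hyperparameters are fixed, documented defaults
classifier_fits <- function(hyper) {
  list(
    logistic = function(X, y01) {
      df <- data.frame(X, y = y01)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      function(Xt) suppressWarnings(
        predict(fit, newdata = data.frame(Xt), type = "response"))
    },
    svm = function(X, y01) {
      fit <- e1071::svm(X, factor(y01), kernel = "linear",
                        probability = TRUE)
      function(Xt) {
        pr <- attr(predict(fit, Xt, probability = TRUE), "probabilities")
        pr[, "1"]
      }
    },
    random_forest = function(X, y01) {
      fit <- randomForest::randomForest(X, factor(y01),
                                        ntree = hyper$rf_trees)
      function(Xt) predict(fit, Xt, type = "prob")[, "1"]
    },
    gradient_boosting = function(X, y01) {
      dtr <- xgboost::xgb.DMatrix(data = X, label = y01, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1),
        data = dtr, nrounds = hyper$gb_rounds, verbose = 0)
      function(Xt)
        predict(fit, xgboost::xgb.DMatrix(data = Xt, nthread = 1))
    },
    neural_network = function(X, y01) {
      fit <- nnet::nnet(X, y01, size = min(2 * ncol(X), 20),
                        decay = hyper$nn_decay, maxit = hyper$nn_maxit,
                        entropy = TRUE, trace = FALSE)
      function(Xt) as.numeric(predict(fit, Xt))
    },
    naive_bayes = function(X, y01) {
      fit <- e1071::naiveBayes(data.frame(X), factor(y01))
      function(Xt) predict(fit, data.frame(Xt), type = "raw")[, "1"]
    }
  )
}

#' Benchmark six classifiers under repeated stratified splits
#'
#' Evaluates logistic regression, linear-kernel SVM, random forest,
#' gradient boosting, a single-hidden-layer neural network and Gaussian
#' naive Bayes on the given features: `n_repeats` stratified
#' `train_frac`/(1-train_frac) splits under a fixed master seed,
#' feature standardization fitted on each training fold only,
#' confusion counts pooled over repeats (micro-average), the four
#' confusion metrics computed from the pooled counts, and AUC from the
#' pooled test-fold scores. Per-repeat metrics are also returned since
#' aggregation conventions differ between studies.
#'
#' @param features Result of [build_features()].
#' @param config Pipeline configuration (`train_frac`, `n_repeats`,
#'   `seed`).
#' @param hyper Hyperparameters: `rf_trees` (100), `gb_rounds` (100),
#'   `nn_decay` (0.01), `nn_maxit` (500).
#' @param positive Positive-class label (default: second factor level).
#' @return Data.frame, one row per classifier: pooled `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `recall`, `accuracy`, `f1`, `auc`; attribute
#'   `"per_repeat"` holds the per-repeat table.
#' @export
evaluate_classifiers <- function(features, config = default_config(),
                                 hyper = list(rf_trees = 100,
                                              gb_rounds = 100,
                                              nn_decay = 0.01,
                                              nn_maxit = 500),
                                 positive = NULL) {
  X <- features$X
  labels <- features$labels
  if (min(table(labels)) < 10)
    stop("need at least 10 subjects per class")
  positive <- positive %||% levels(labels)[2]
  negative <- setdiff(levels(labels), positive)
  y01 <- as.integer(labels == positive)
  fits <- classifier_fits(hyper)
  n_rep <- config$n_repeats %||% 10
  frac <- config$train_frac %||% 0.7
  master <- config$seed %||% 1

  counts <- matrix(0L, length(fits), 4,
                   dimnames = list(names(fits),
                                   c("tp", "fp", "tn", "fn")))
  scores <- stats::setNames(
    lapply(names(fits), function(i) numeric(0)), names(fits))
  truth <- integer(0)
  per_rep <- list()

  for (rep_i in seq_len(n_rep)) {
    set.seed(derive_seed(master, rep_i))
    tr <- stratified_split(labels, frac)
    std <- standardize_features(X, tr)
    y_tr <- y01[tr]; y_te <- y01[-tr]
    truth <- c(truth, y_te)
    for (cl in names(fits)) {
      set.seed(derive_seed(master, rep_i * 100L +
                             match(cl, names(fits))))
      scorer <- fits[[cl]](std$train, y_tr)
      s <- as.numeric(scorer(std$test))
      pred <- as.integer(s > 0.5)
      tp <- sum(pred == 1 & y_te == 1); fp <- sum(pred == 1 & y_te == 0)
      tn <- sum(pred == 0 & y_te == 0); fn <- sum(pred == 0 & y_te == 1)
      counts[cl, ] <- counts[cl, ] + c(tp, fp, tn, fn)
      scores[[cl]] <- c(scores[[cl]], s)
      m <- suppressWarnings(metric_from_confusion(tp, fp, tn, fn))
      per_rep[[length(per_rep) + 1]] <-
        data.frame(repeat_i = rep_i, classifier = cl,
                   tp = tp, fp = fp, tn = tn, fn = fn,
                   precision = m$precision, recall = m$recall,
                   accuracy = m$accuracy, f1 = m$f1,
                   stringsAsFactors = FALSE)
    }
  }

  rows <- lapply(names(fits), function(cl) {
    cc <- counts[cl, ]
    m <- suppressWarnings(
      metric_from_confusion(cc["tp"], cc["fp"], cc["tn"], cc["fn"]))
    auc <- auc_score(truth, scores[[cl]])
    data.frame(classifier = cl, tp = cc["tp"], fp = cc["fp"],
               tn = cc["tn"], fn = cc["fn"],
               precision = m$precision, recall = m$recall,
               accuracy = m$accuracy, f1 = m$f1, auc = auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_repeat") <- do.call(rbind, per_rep)
  attr(out, "positive") <- positive
  attr(out, "negative") <- negative
  out
}

#' Area under the ROC curve
#'
#' AUC with a fixed score orientation (higher score = positive class),
#' so that the anti-symmetry `auc(-s) = 1 - auc(s)` holds exactly and a
#' random score gives values on both sides of 0.5.
#'
#' @param truth01 0/1 vector of true classes.
#' @param score Numeric classifier scores.
#' @return Scalar AUC.
#' @export
auc_score <- function(truth01, score) {
  r <- pROC::roc(response = truth01, predictor = score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Default feature sets for the two clinical contrasts
#'
#' The amnestic-vs-non-amnestic contrast uses the two discriminant
#' graph measures (beta-band modularity, gamma-band radius) plus the
#' two always-available clinical covariates (sex, MMSE); the
#' early-vs-late amnestic contrast uses the six gamma-band measures
#' that separate those groups.
#'
#' @param task `"amnestic_vs_nonamnestic"` or `"early_vs_late"`.
#' @return Character vector of feature names for [build_features()].
#' @export
selected_features <- function(task = c("amnestic_vs_nonamnestic",
                                       "early_vs_late")) {
  switch(match.arg(task),
    amnestic_vs_nonamnestic =
      c("modularity_beta", "radius_gamma", "sex", "mmse"),
    early_vs_late =
      c("degree_gamma", "strength_gamma", "global_efficiency_gamma",
        "local_efficiency_gamma", "clustering_coefficient_gamma",
        "transitivity_gamma"))
}
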