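# faPEA/unPEA classifiers. The primary model is a random forest of B = 500
# trees, each grown on an independent 10% bootstrap replica (with
# replacement), floor(sqrt(D)) candidate predictors per node, terminal
# nodes of at least 5 observations, and uniform class priors (implemented
# as balanced class weights). Baselines: logistic regression and
# polynomial-kernel SVMs (degree 2 and 3) with the positive class (faPEA)
# weighted by 1.5 and features z-scored with training statistics.

#' Random-forest configuration
#'
#' @param n_trees Number of trees.
#' @param bootstrap_fraction Fraction of the training set drawn (with
#'   replacement) for each tree.
#' @param predictors_per_node Candidate predictors per split; `NULL` means
#'   `floor(sqrt(D))`.
#' @param min_leaf Minimum observations per terminal node.
#' @param priors `"uniform"` (balanced class weights) or `"empirical"`.
#' @return A list of class `"rf_config"`.
#' @export
rf_config <- function(n_trees = 500, bootstrap_fraction = 0.10,
                      predictors_per_node = NULL, min_leaf = 5,
                      priors = c("uniform", "empirical")) {
  stopifnot(n_trees >= 1, bootstrap_fraction > 0, bootstrap_fraction <= 1,
            min_leaf >= 1)
  structure(list(n_trees = n_trees, bootstrap_fraction = bootstrap_fraction,
                 predictors_per_node = predictors_per_node,
                 min_leaf = min_leaf, priors = match.arg(priors)),
            class = "rf_config")
}

#' Baseline-classifier configuration
#'
#' @param positive_class_weight Weight of the minority (faPEA) class.
#' @param standardize Z-score features with training-fold statistics.
#' @param cost SVM regularization constant.
#' @param coef0 SVM polynomial-kernel offset.
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(positive_class_weight = 1.5, standardize = TRUE,
                            cost = 1, coef0 = 1) {
  stopifnot(positive_class_weight > 0)
  structure(list(positive_class_weight = positive_class_weight,
                 standardize = standardize, cost = cost, coef0 = coef0),
            class = "baseline_config")
}

.pea_levels <- c("unPEA", "faPEA")  # positive class last

.check_training_input <- function(x, y) {
  if (anyNA(x)) stop("validation error: missing feature values")
  y <- factor(as.character(y), levels = .pea_levels)
  if (anyNA(y)) stop("labels must be faPEA or unPEA")
  if (nlevels(droplevels(y)) < 2)
    stop("validation error: training data contains a single class")
  y
}

#' Fit a faPEA/unPEA classifier
#'
#' The formula interface of the pipeline's classification stage:
#' `pea_model(label ~ ., data)` fits the random forest on every numeric
#' feature column; `method` selects the baselines. Metadata columns
#' (`patient_id`, `t_onset_s`, `icc_available`) are never used as
#' predictors even under `~ .`.
#'
#' @param formula Model formula; the response must be the class label.
#' @param data A data.frame (typically a [pea_features()] table).
#' @param method `"rf"`, `"lr"`, `"svm2"` or `"svm3"`.
#' @param rf A [rf_config()].
#' @param baseline A [baseline_config()].
#' @param seed Integer seed; fits are deterministic given (data, config,
#'   seed).
#' @return An object of class `"pea_model"`.
#' @export
pea_model <- function(formula, data, method = c("rf", "lr", "svm2", "svm3"),
                      rf = rf_config(), baseline = baseline_config(),
                      seed = 1) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data = .drop_meta(data))
  y <- .check_training_input(mf[-1], mf[[1]])
  x <- mf[-1]
  num <- vapply(x, is.numeric, logical(1))
  x <- as.data.frame(x[num])
  if (!ncol(x)) stop("no numeric predictors in formula")
  fit <- switch(method,
                rf = .fit_rf(x, y, rf, seed),
                lr = .fit_lr(x, y, baseline),
                svm2 = .fit_svm(x, y, baseline, degree = 2, seed),
                svm3 = .fit_svm(x, y, baseline, degree = 3, seed))
  structure(list(method = method, fit = fit$fit, extra = fit$extra,
                 feature_names = colnames(x), n = nrow(x),
                 class_counts = table(y), seed = seed,
                 config = if (method == "rf") rf else baseline),
            class = "pea_model")
}

.drop_meta <- function(data) {
  drop <- intersect(c("patient_id", "t_onset_s", "icc_available"),
                    names(data))
  data[setdiff(names(data), drop)]
}

.fit_rf <- function(x, y, cfg, seed) {
  D <- ncol(x)
  mtry <- if (is.null(cfg$predictors_per_node)) max(1L, floor(sqrt(D)))
          else min(D, cfg$predictors_per_node)
  cw <- if (cfg$priors == "uniform") {
    tb <- table(y)
    w <- length(y) / (length(tb) * as.numeric(tb))
    stats::setNames(w, names(tb))
  } else NULL
  # uniform priors act twice: balanced case weights make every bootstrap
  # replica class-balanced in expectation, and balanced class weights keep
  # the split criterion prior-free
  fit <- ranger::ranger(x = x, y = y, num.trees = cfg$n_trees,
                        sample.fraction = cfg$bootstrap_fraction,
                        replace = TRUE, mtry = mtry,
                        min.node.size = cfg$min_leaf,
                        class.weights = cw,
                        case.weights = if (!is.null(cw))
                          unname(cw[as.character(y)]),
                        importance = "impurity",
                        seed = seed, num.threads = 1)
  list(fit = fit, extra = NULL)
}

.fit_lr <- function(x, y, cfg) {
  sc <- if (cfg$standardize) .train_scaler(x) else NULL
  xs <- .apply_scaler(x, sc)
  w <- ifelse(y == "faPEA", cfg$positive_class_weight, 1)
  df <- cbind(..y = as.integer(y == "faPEA"), xs)
  fit <- suppressWarnings(
    stats::glm(..y ~ ., data = df, family = stats::binomial(),
               weights = w))
  list(fit = fit, extra = list(scaler = sc))
}

.fit_svm <- function(x, y, cfg, degree, seed) {
  sc <- if (cfg$standardize) .train_scaler(x) else NULL
  xs <- .apply_scaler(x, sc)
  set.seed(seed)  # Platt calibration uses internal cross-validation
  fit <- e1071::svm(x = as.matrix(xs), y = y, kernel = "polynomial",
                    degree = degree, coef0 = cfg$coef0, cost = cfg$cost,
                    gamma = 1 / ncol(xs),
                    class.weights = c(unPEA = 1,
                                      faPEA = cfg$positive_class_weight),
                    probability = TRUE, scale = FALSE)
  list(fit = fit, extra = list(scaler = sc))
}

.train_scaler <- function(x) {
  mu <- vapply(x, mean, 0)
  sd <- vapply(x, stats::sd, 0)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

.apply_scaler <- function(x, sc) {
  if (is.null(sc)) return(as.data.frame(x))
  as.data.frame(Map(function(v, m, s) (v - m) / s, x, sc$mu, sc$sd))
}

#' Predict faPEA probability or class
#'
#' For the random forest the probability is the fraction of trees voting
#' faPEA; for the baselines it is the calibrated model probability. The
#' `newdata` columns must contain the training features.
#'
#' @param object A [pea_model()].
#' @param newdata Data.frame with the training feature columns.
#' @param type `"prob"` (P(faPEA)) or `"class"` (labels at threshold 0.5).
#' @param ... Unused.
#' @return Numeric probability vector or factor of labels.
#' @export
predict.pea_model <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("validation error: newdata lacks feature columns: ",
         paste(miss, collapse = ", "))
  x <- as.data.frame(newdata[object$feature_names])
  if (anyNA(x)) stop("validation error: missing feature values in newdata")
  p <- switch(object$method,
    rf = {
      pr <- stats::predict(object$fit, data = x, predict.all = TRUE,
                           num.threads = 1)$predictions
      pos <- which(.pea_levels == "faPEA")
      rowMeans(pr == pos)
    },
    lr = {
      xs <- .apply_scaler(x, object$extra$scaler)
      as.numeric(stats::predict(object$fit, newdata = xs,
                                type = "response"))
    },
    {
      xs <- as.matrix(.apply_scaler(x, object$extra$scaler))
      pr <- stats::predict(object$fit, xs, probability = TRUE)
      attr(pr, "probabilities")[, "faPEA"]
    })
  p <- unname(pmin(1, pmax(0, p)))
  if (type == "prob") p else
    factor(ifelse(p >= 0.5, "faPEA", "unPEA"), levels = .pea_levels)
}

#' Random-forest feature importance
#'
#' Split-gain (Gini impurity decrease) importance of the fitted forest;
#' non-negative, one value per training feature.
#'
#' @param model A [pea_model()] with `method = "rf"`.
#' @return Named numeric vector of importances.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "pea_model"))
  if (model$method != "rf")
    stop("unsupported operation: feature importance requires the RF model")
  imp <- ranger::importance(model$fit)
  imp[model$feature_names]
}

#' @export
print.pea_model <- function(x, ...) {
  cat(sprintf("faPEA/unPEA classifier (%s): %d features, n = %d\n",
              toupper(x$method), length(x$feature_names), x$n))
  print(x$class_counts)
  invisible(x)
}

#' @export
summary.pea_model <- function(object, ...) {
  print(object)
  if (object$method == "rf") {
    cat("\nFeature importance (impurity decrease):\n")
    imp <- sort(feature_importance(object), decreasing = TRUE)
    print(round(imp, 4))
  } else if (object$method == "lr") {
    cat("\nCoefficients (z-scored features):\n")
    print(round(stats::coef(object$fit), 4))
  }
  invisible(object)
}

#' @export
coef.pea_model <- function(object, ...) {
  if (object$method != "lr")
    stop("coefficients are only defined for the logistic-regression baseline")
  stats::coef(object$fit)
}

#' @export
plot.pea_model <- function(x, ...) {
  if (x$method != "rf")
    stop("plot is implemented for the RF model (feature importance)")
  imp <- sort(feature_importance(x))
  graphics::barplot(imp, horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "impurity-decrease importance",
                    main = "RF feature importance", ...)
  invisible(x)
}
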