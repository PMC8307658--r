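# Patientwise stratified repeated cross-validation and downstream
# analyses. All segments of a patient share a fold (no train/test leakage)
# and the per-fold class mixture tracks the global one as closely as the
# grouping constraint allows.

#' Patientwise stratified fold assignment
#'
#' Greedy bin packing: patients are sorted by segment count (descending,
#' seeded random tie-break) and each is assigned to the fold where it best
#' preserves, in order of priority, the fold's class balance and its size.
#' Deterministic given `seed`.
#'
#' @param meta Data.frame with one row per segment: `patient_id`, `label`.
#'   (A [pea_dataset()] or [pea_features()] table works directly.)
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A list of class `"fold_plan"`: `assignments` (named integer
#'   vector patient -> fold), `fold` (integer per segment row), `k`, `seed`.
#' @export
make_folds <- function(meta, k = 10, seed = 1) {
  if (inherits(meta, "pea_dataset")) meta <- as.data.frame(meta)
  stopifnot(all(c("patient_id", "label") %in% names(meta)))
  pats <- unique(meta$patient_id)
  if (length(pats) < k)
    stop("validation error: fewer patients (", length(pats),
         ") than folds (", k, ")")
  pt <- stats::aggregate(rep(1, nrow(meta)),
                         by = list(patient_id = meta$patient_id,
                                   label = meta$label), FUN = sum)
  names(pt)[3] <- "n"
  set.seed(as.integer(seed %% 2^31))
  pt <- pt[order(-pt$n, stats::runif(nrow(pt))), ]

  # deal each class separately: a patient goes to the fold currently
  # holding the fewest segments of that class (total size breaks ties),
  # which spreads both classes as evenly as the grouping allows
  fold_n <- numeric(k)
  fold_cls <- matrix(0, k, 2, dimnames = list(NULL, c("faPEA", "unPEA")))
  assign <- stats::setNames(integer(nrow(pt)), pt$patient_id)
  for (i in seq_len(nrow(pt))) {
    cl <- if (pt$label[i] == "faPEA") "faPEA" else "unPEA"
    cost <- fold_cls[, cl] + 1e-3 * fold_n + stats::runif(k) * 1e-9
    f <- which.min(cost)
    assign[i] <- f
    fold_n[f] <- fold_n[f] + pt$n[i]
    fold_cls[f, cl] <- fold_cls[f, cl] + pt$n[i]
  }
  structure(list(assignments = assign,
                 fold = unname(assign[meta$patient_id]),
                 k = k, seed = seed),
            class = "fold_plan")
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic: the probability that a random positive (faPEA)
#' score exceeds a random negative one, ties counted half.
#'
#' @param scores Numeric scores (higher = more faPEA-like).
#' @param labels Labels with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "faPEA"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop(structure(class = c("pea_auc_undefined", "error", "condition"),
                   list(message = "AUC undefined: a single class present",
                        call = sys.call(-1))))
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fold_metrics <- function(p, y) {
  pred_pos <- p >= 0.5
  is_pos <- y == "faPEA"
  se <- if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_
  sp <- if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_
  auc <- tryCatch(roc_auc(p, y),
                  pea_auc_undefined = function(e) NA_real_)
  c(se = se, sp = sp, bac = (se + sp) / 2, auc = auc)
}

#' Patientwise stratified repeated cross-validation
#'
#' For each repeat a fresh patientwise stratified fold plan is drawn; for
#' each fold the model is fitted on the remaining folds and evaluated on
#' the held-out fold. Sensitivity/specificity use the 0.5 probability
#' threshold (the majority-vote point under uniform priors); AUC is
#' rank-based on the predicted probabilities. Folds whose test part holds
#' a single class get `NA` AUC and are excluded from the summaries.
#'
#' @param data A [pea_features()] table (or any data.frame with
#'   `patient_id`, `label` and feature columns), or a [pea_dataset()]
#'   (featurized first with `config`).
#' @param method Classifier passed to [pea_model()].
#' @param features Character vector of feature columns to use; default all
#'   17.
#' @param k Folds per repeat.
#' @param repeats Number of CV repetitions.
#' @param seed Master seed; repeat r uses `seed + r - 1` for its fold plan
#'   and model fits.
#' @param config Pipeline configuration (only used to featurize a dataset).
#' @param rf,baseline Model configurations.
#' @return An object of class `"pea_cv"`: `metrics` (data.frame with one
#'   row per repeat x fold: `repeat_id`, `fold`, `n_test`, `se`, `sp`,
#'   `bac`, `auc`) and `summary` (median and IQR per metric).
#' @export
cross_validate <- function(data, method = "rf",
                           features = pea_feature_names(),
                           k = 10, repeats = 10, seed = 1,
                           config = pea_config(),
                           rf = rf_config(), baseline = baseline_config()) {
  if (inherits(data, "pea_dataset")) data <- pea_features(data, config)
  features <- intersect(features, names(data))
  if (!length(features)) stop("no feature columns found in data")
  fml <- stats::as.formula(paste("label ~",
                                 paste(features, collapse = " + ")))
  rows <- list()
  for (r in seq_len(repeats)) {
    rseed <- seed + r - 1
    plan <- make_folds(data, k = k, seed = rseed)
    for (f in seq_len(k)) {
      test <- plan$fold == f
      if (!any(test) || all(test)) next
      if (length(unique(data$label[!test])) < 2) {
        message("repeat ", r, " fold ", f,
                ": single-class training set; fold skipped")
        next
      }
      fit <- pea_model(fml, data[!test, , drop = FALSE], method = method,
                       rf = rf, baseline = baseline, seed = rseed * 1000 + f)
      p <- predict(fit, data[test, , drop = FALSE], type = "prob")
      m <- .fold_metrics(p, data$label[test])
      rows[[length(rows) + 1]] <-
        data.frame(repeat_id = r, fold = f, n_test = sum(test), t(m))
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- t(vapply(c("se", "sp", "bac", "auc"), function(mm) {
    v <- metrics[[mm]]
    v <- v[!is.na(v)]
    c(median = stats::median(v), iqr = stats::IQR(v), n_folds = length(v))
  }, numeric(3)))
  structure(list(metrics = metrics, summary = summ, method = method,
                 features = features, k = k, repeats = repeats, seed = seed),
            class = "pea_cv")
}

#' @export
print.pea_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold patientwise CV, %s model, %d features\n",
              x$repeats, x$k, toupper(x$method), length(x$features)))
  s <- x$summary
  for (mm in rownames(s))
    cat(sprintf("  %-4s median (IQR): %5.1f (%4.1f) %%  [%d folds]\n",
                toupper(mm), 100 * s[mm, "median"], 100 * s[mm, "iqr"],
                as.integer(s[mm, "n_folds"])))
  invisible(x)
}

#' @export
plot.pea_cv <- function(x, ...) {
  m <- x$metrics
  graphics::boxplot(list(Se = m$se, Sp = m$sp, BAC = m$bac,
                         AUC = m$auc[!is.na(m$auc)]),
                    ylab = "per-fold value", ylim = c(0, 1),
                    main = sprintf("%s, %dx%d-fold patientwise CV",
                                   toupper(x$method), x$repeats, x$k), ...)
  invisible(x)
}

#' Recursive importance-based feature selection
#'
#' For every CV partition the RF is trained on all `D` features, the
#' feature with the lowest importance is discarded, and the model is
#' retrained on the remainder — one feature per step until one is left.
#' The selection probability of a feature at size `Nf` is the fraction of
#' partitions whose retained set of size `Nf` contains it.
#'
#' @param data Feature table as in [cross_validate()].
#' @param features Feature columns to rank.
#' @param k,repeats CV partitions: `repeats` plans of `k` folds each; each
#'   (repeat, fold) training set is one partition.
#' @param seed Master seed.
#' @param config,rf As in [cross_validate()].
#' @return An object of class `"pea_selection"`: `prob` (matrix feature x
#'   Nf of selection probabilities), `n_partitions`.
#' @export
recursive_feature_selection <- function(data,
                                        features = pea_feature_names(),
                                        k = 10, repeats = 1, seed = 1,
                                        config = pea_config(),
                                        rf = rf_config()) {
  if (inherits(data, "pea_dataset")) data <- pea_features(data, config)
  features <- intersect(features, names(data))
  D <- length(features)
  if (D < 2) stop("need at least 2 features")
  counts <- matrix(0, D, D, dimnames = list(features, as.character(seq_len(D))))
  n_part <- 0L
  for (r in seq_len(repeats)) {
    rseed <- seed + r - 1
    plan <- make_folds(data, k = k, seed = rseed)
    for (f in seq_len(k)) {
      train <- data[plan$fold != f, , drop = FALSE]
      if (length(unique(train$label)) < 2) next
      n_part <- n_part + 1L
      kept <- features
      while (length(kept) >= 1) {
        counts[kept, as.character(length(kept))] <-
          counts[kept, as.character(length(kept))] + 1
        if (length(kept) == 1) break
        fml <- stats::as.formula(paste("label ~",
                                       paste(kept, collapse = " + ")))
        fit <- pea_model(fml, train, method = "rf", rf = rf,
                         seed = rseed * 1000 + f + length(kept))
        imp <- feature_importance(fit)
        kept <- setdiff(kept, names(which.min(imp)))
      }
    }
  }
  structure(list(prob = counts / n_part, n_partitions = n_part,
                 features = features, seed = seed),
            class = "pea_selection")
}

#' @export
print.pea_selection <- function(x, ...) {
  cat(sprintf("Recursive RF feature selection over %d partitions\n",
              x$n_partitions))
  cat("Selection probability at Nf = 1, 3, 7:\n")
  nf <- intersect(c("1", "3", "7"), colnames(x$prob))
  print(round(x$prob[order(-x$prob[, "1"]), nf, drop = FALSE], 2))
  invisible(x)
}

#' Classification performance versus time from PEA onset
#'
#' Restricts the cohort to segments recorded within `tw` minutes of PEA
#' onset and cross-validates on each restriction.
#'
#' @param data Feature table with a `t_onset_s` column (or a
#'   [pea_dataset()]).
#' @param windows Analysis windows in minutes.
#' @param ... Passed to [cross_validate()].
#' @param config Pipeline configuration (to featurize a dataset).
#' @return A list of class `"pea_tw"`: `reports` (one [cross_validate()]
#'   result or `NULL` per window) and `summary` (data.frame `tw_min`,
#'   `n_segments`, `auc_median`, `bac_median`).
#' @export
time_window_analysis <- function(data, windows = 1:10, ...,
                                 config = pea_config()) {
  if (inherits(data, "pea_dataset")) data <- pea_features(data, config)
  stopifnot("t_onset_s" %in% names(data))
  reports <- vector("list", length(windows))
  names(reports) <- paste0("tw_", windows)
  summ <- data.frame(tw_min = windows, n_segments = NA_integer_,
                     auc_median = NA_real_, bac_median = NA_real_)
  for (i in seq_along(windows)) {
    sub <- data[data$t_onset_s <= windows[i] * 60, , drop = FALSE]
    summ$n_segments[i] <- nrow(sub)
    if (!nrow(sub) || length(unique(sub$label)) < 2 ||
        length(unique(sub$patient_id)) < list(...)$k %||% 10) {
      message("tw = ", windows[i], " min: too few segments/patients; skipped")
      next
    }
    rep_i <- tryCatch(cross_validate(sub, ...),
                      error = function(e) {
                        message("tw = ", windows[i], " min: ",
                                conditionMessage(e)); NULL
                      })
    reports[[i]] <- rep_i
    if (!is.null(rep_i)) {
      summ$auc_median[i] <- rep_i$summary["auc", "median"]
      summ$bac_median[i] <- rep_i$summary["bac", "median"]
    }
  }
  structure(list(reports = reports, summary = summ), class = "pea_tw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pea_tw <- function(x, ...) {
  cat("Performance vs time from PEA onset\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
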