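test_that("fold plans are patientwise, balanced and deterministic", {
  df <- planted_feature_table(n_patients = 20, seg_per_patient = 3)
  plan <- make_folds(df, k = 10, seed = 1)
  # every patient in exactly one fold, 2 patients per fold
  per_pat <- tapply(plan$fold, df$patient_id, function(f) length(unique(f)))
  expect_true(all(per_pat == 1))
  expect_true(all(table(plan$assignments) == 2))
  # same seed, same plan; plans are seed-sensitive
  expect_identical(plan$assignments, make_folds(df, 10, seed = 1)$assignments)
  # a heavy patient stays together
  df2 <- rbind(df, data.frame(patient_id = "P999", label = "faPEA",
                              t_onset_s = 1:50, oracle = 0,
                              noise1 = 0, noise2 = 0))
  plan2 <- make_folds(df2, k = 10, seed = 2)
  expect_length(unique(plan2$fold[df2$patient_id == "P999"]), 1)
  expect_error(make_folds(df[df$patient_id %in% c("P001", "P002"), ], k = 10),
               "fewer patients")
})

test_that("fold class mixtures track the global proportion", {
  df <- planted_feature_table(n_patients = 40, seg_per_patient = 5, seed = 3)
  plan <- make_folds(df, k = 10, seed = 3)
  global <- mean(df$label == "faPEA")
  for (f in 1:10) {
    prop <- mean(df$label[plan$fold == f] == "faPEA")
    expect_lt(abs(prop - global), 0.10 + 1e-9)
  }
})

test_that("rank AUC agrees with hand cases and brute force", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                           c("faPEA", "faPEA", "unPEA", "unPEA")), 1)
  expect_identical(roc_auc(rep(0.5, 6), rep(c("faPEA", "unPEA"), 3)), 0.5)
  expect_identical(roc_auc(c(0.7, 0.4, 0.5),
                           c("faPEA", "faPEA", "unPEA")), 0.5)
  expect_error(roc_auc(1:3, rep("faPEA", 3)), class = "pea_auc_undefined")
  brute <- function(s, l) {
    pos <- s[l == "faPEA"]; neg <- s[l != "faPEA"]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(30)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    l <- sample(c("faPEA", "unPEA"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    s <- round(runif(n), 2)  # force some ties
    expect_equal(roc_auc(s, l), brute(s, l), tolerance = 1e-12)
  }
  # third route: an established ROC implementation
  set.seed(31)
  l <- sample(c("faPEA", "unPEA"), 60, replace = TRUE)
  s <- runif(60)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("unPEA", "faPEA"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a perfect feature yields perfect cross-validated scores", {
  df <- planted_feature_table(n_patients = 30, seg_per_patient = 3, seed = 5)
  cv <- cross_validate(df, method = "rf", features = "oracle",
                       k = 5, repeats = 2, seed = 1)
  expect_identical(cv$summary["auc", "median"], 1)
  expect_identical(cv$summary["bac", "median"], 1)
  # BAC is (Se+Sp)/2 on every fold
  ok <- !is.na(cv$metrics$bac)
  expect_equal(cv$metrics$bac[ok],
               (cv$metrics$se[ok] + cv$metrics$sp[ok]) / 2,
               tolerance = 1e-9)
})

test_that("no patient ever spans a train/test split", {
  df <- planted_feature_table(n_patients = 24, seg_per_patient = 4, seed = 6)
  for (r in 1:5) {
    plan <- make_folds(df, k = 6, seed = r)
    for (f in 1:6) {
      train_p <- unique(df$patient_id[plan$fold != f])
      test_p <- unique(df$patient_id[plan$fold == f])
      expect_length(intersect(train_p, test_p), 0)
    }
  }
})

test_that("recursive selection retains a planted feature to the end", {
  df <- planted_feature_table(n_patients = 30, seg_per_patient = 4, seed = 7)
  tr <- recursive_feature_selection(df,
                                    features = c("oracle", "noise1", "noise2"),
                                    k = 5, repeats = 1, seed = 2,
                                    rf = rf_config(n_trees = 100,
                                                   bootstrap_fraction = 0.3))
  expect_identical(dim(tr$prob), c(3L, 3L))
  expect_identical(unname(tr$prob["oracle", "1"]), 1)
  expect_true(all(tr$prob[, "3"] == 1))  # full set always retained
  expect_identical(tr$n_partitions, 5L)
})

test_that("time-window restriction is a no-op when all segments are early", {
  df <- planted_feature_table(n_patients = 20, seg_per_patient = 3, seed = 8)
  df$t_onset_s <- 30
  tw <- time_window_analysis(df, windows = c(1, 5, 10), method = "rf",
                             features = c("oracle", "noise1", "noise2"),
                             k = 5, repeats = 1, seed = 1)
  expect_length(tw$reports, 3)
  expect_identical(tw$summary$n_segments, rep(60L, 3))
  expect_identical(tw$summary$auc_median[1], tw$summary$auc_median[3])
  expect_identical(tw$summary$bac_median[1], tw$summary$bac_median[2])
})

test_that("single-class test folds are excluded from summaries, not imputed", {
  # 8 patients of which 2 unPEA, k = 4: stratified dealing puts the two
  # unPEA patients in different folds, so two test folds are pure faPEA
  df <- planted_feature_table(n_patients = 8, seg_per_patient = 3, seed = 9)
  df$label <- ifelse(df$patient_id %in% c("P001", "P002"), "unPEA", "faPEA")
  df$oracle <- as.integer(df$label == "faPEA") + rnorm(nrow(df), 0, 0.05)
  cv <- cross_validate(df, method = "rf", features = "oracle",
                       k = 4, repeats = 1, seed = 1,
                       rf = rf_config(bootstrap_fraction = 0.5))
  expect_true(anyNA(cv$metrics$auc))
  expect_false(anyNA(cv$summary["auc", "median"]))
  expect_lt(cv$summary["auc", "n_folds"], nrow(cv$metrics))
})
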