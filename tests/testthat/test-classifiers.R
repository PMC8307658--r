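sep_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  lab <- rep(c("faPEA", "unPEA"), each = n / 2)
  data.frame(label = lab,
             f1 = ifelse(lab == "faPEA", 2, -2) + rnorm(n, 0, 0.3),
             f2 = rnorm(n))
}

test_that("the forest separates linearly separable data", {
  df <- sep_table()
  fit <- pea_model(label ~ f1 + f2, df, method = "rf", seed = 3)
  p <- predict(fit, df)
  m <- table(pred = p >= 0.5, truth = df$label == "faPEA")
  se <- m["TRUE", "TRUE"] / sum(df$label == "faPEA")
  sp <- m["FALSE", "FALSE"] / sum(df$label == "unPEA")
  expect_gt((se + sp) / 2, 0.95)
})

test_that("forest probabilities are tree-vote fractions", {
  df <- sep_table()
  fit <- pea_model(label ~ f1 + f2, df, method = "rf", seed = 3)
  # the probability is exactly the per-tree faPEA vote fraction
  votes <- predict(fit$fit, data = df[c("f1", "f2")], predict.all = TRUE,
                   num.threads = 1)$predictions
  frac <- rowMeans(votes == 2L)  # level 2 = faPEA
  expect_identical(predict(fit, df, type = "prob"), unname(frac))
  expect_true(all(frac >= 0 & frac <= 1))
  # thresholding the vote fraction reproduces the class prediction
  cls <- predict(fit, df, type = "class")
  expect_identical(cls == "faPEA", frac >= 0.5)
})

test_that("fits are deterministic under a fixed seed", {
  df <- sep_table()
  p1 <- predict(pea_model(label ~ ., df, method = "rf", seed = 7), df)
  p2 <- predict(pea_model(label ~ ., df, method = "rf", seed = 7), df)
  expect_identical(p1, p2)
})

test_that("uniform priors absorb class imbalance", {
  set.seed(8)
  df <- sep_table(n = 300, seed = 8)
  # make it imbalanced 1:4 and noisy enough that priors matter
  df <- df[c(which(df$label == "faPEA")[1:30], which(df$label == "unPEA")), ]
  df$f1 <- df$f1 + rnorm(nrow(df), 0, 1)
  hold <- sep_table(n = 100, seed = 9)
  fit1 <- pea_model(label ~ f1 + f2, df, method = "rf", seed = 1)
  dup <- rbind(df, df[df$label == "faPEA", ], df[df$label == "faPEA", ])
  fit2 <- pea_model(label ~ f1 + f2, dup, method = "rf", seed = 1)
  d <- abs(predict(fit1, hold) - predict(fit2, hold))
  expect_lt(mean(d), 0.05)
})

test_that("single-class or incomplete inputs are rejected", {
  df <- sep_table()
  expect_error(pea_model(label ~ ., df[df$label == "faPEA", ], method = "rf"),
               "single class")
  fit <- pea_model(label ~ f1 + f2, df, method = "rf")
  expect_error(predict(fit, df["f1"]), "lacks feature columns")
})

test_that("logistic regression handles separable and constant features", {
  set.seed(10)
  n <- 200
  lab <- sample(c("faPEA", "unPEA"), n, replace = TRUE)
  df <- data.frame(label = lab,
                   f1 = as.integer(lab == "faPEA") + rnorm(n, 0, 0.3),
                   cst = 1)
  fit <- pea_model(label ~ f1 + cst, df, method = "lr")
  expect_gt(roc_auc(predict(fit, df), df$label), 0.95)
  b_cst <- coef(fit)[["cst"]]
  expect_true(is.na(b_cst) || abs(b_cst) < 1e-6)
})

test_that("a quadratic kernel solves the XOR pattern", {
  set.seed(11)
  n <- 200
  a <- sample(0:1, n, TRUE); b <- sample(0:1, n, TRUE)
  df <- data.frame(label = ifelse(xor(a, b), "faPEA", "unPEA"),
                   f1 = a + rnorm(n, 0, 0.1), f2 = b + rnorm(n, 0, 0.1))
  fit <- pea_model(label ~ f1 + f2, df, method = "svm2", seed = 2)
  acc <- mean(predict(fit, df, type = "class") == df$label)
  expect_gt(acc, 0.9)
})

test_that("importance finds a planted feature and is flat on noise", {
  set.seed(12)
  n <- 200
  lab <- sample(c("faPEA", "unPEA"), n, replace = TRUE)
  df <- data.frame(label = lab,
                   planted = as.integer(lab == "faPEA"),
                   n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  fit <- pea_model(label ~ ., df, method = "rf", seed = 1)
  imp <- feature_importance(fit)
  expect_length(imp, 4)
  expect_identical(names(which.max(imp)), "planted")
  expect_true(all(imp >= 0))
  # all-noise importances are statistically indistinguishable over seeds
  set.seed(13)
  nulldf <- data.frame(label = sample(c("faPEA", "unPEA"), n, TRUE),
                       n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  acc <- rowMeans(vapply(1:20, function(s)
    feature_importance(pea_model(label ~ ., nulldf, method = "rf",
                                 seed = s)), numeric(3)))
  expect_lt(max(acc) / min(acc), 5)
  # importance is an RF-only notion
  lr <- pea_model(label ~ n1 + n2 + n3, nulldf, method = "lr")
  expect_error(feature_importance(lr), "unsupported|RF")
})
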