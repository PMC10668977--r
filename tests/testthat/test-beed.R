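test_that("equalized down-sampling yields floor(m/n) balanced subsets", {
  maj <- sprintf("maj%03d", 1:160)
  mino <- sprintf("min%02d", 1:30)
  expect_message(subs <- equalized_downsample(maj, mino, seed = 3L),
                 "10 majority ids discarded")
  expect_length(subs, 5)
  for (s in subs) {
    expect_length(s, 60)
    expect_equal(sum(s %in% maj), 30)
    expect_equal(sum(s %in% mino), 30)
  }
  expect_length(attr(subs, "discarded"), 10)
  # the majority blocks are disjoint and do not include discarded ids
  used <- unlist(lapply(subs, function(s) s[s %in% maj]))
  expect_false(any(duplicated(used)))
  expect_length(intersect(used, attr(subs, "discarded")), 0)

  expect_length(equalized_downsample(1:4, 5:6, seed = 1L), 2)
  expect_length(equalized_downsample(1:3, 4:6, seed = 1L), 1)
  expect_warning(one <- equalized_downsample(1:2, 3:6, seed = 1L), "smaller")
  expect_length(one, 1)
  expect_error(equalized_downsample(integer(0), 1:3), "non-empty")
})

test_that("subset balance holds on random class sizes", {
  set.seed(14)
  for (i in 1:20) {
    m <- sample(20:200, 1); n <- sample(5:20, 1)
    subs <- suppressMessages(equalized_downsample(seq_len(m), m + seq_len(n),
                                                  seed = i))
    expect_length(subs, m %/% n)
    for (s in subs) {
      expect_equal(sum(s <= m), n)
      expect_equal(sum(s > m), n)
    }
  }
})

test_that("min-max weighting matches the published normalization", {
  expect_equal(compute_weights(c(0.6, 0.7, 0.8)), c(0, 0.5, 1))
  expect_equal(compute_weights(c(0.5, 0.9)), c(0, 1))
  expect_equal(compute_weights(c(0.7, 0.7, 0.7)), c(1, 1, 1))
  expect_equal(compute_weights(0.83), 1)
})

test_that("AUC equals the brute-force pairwise concordance oracle", {
  set.seed(41)
  truth <- rep(c(0L, 1L), 100)
  expect_equal(auc_score(truth, as.numeric(truth)), 1)
  expect_equal(auc_score(truth, rep(0.3, 200)), 0.5)
  for (i in 1:10) {
    score <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)  # many ties
    expect_equal(auc_score(truth, score), auc_oracle(truth, score))
  }
  expect_error(auc_score(rep(1L, 5), runif(5)), "both classes")
})

test_that("confusion metrics follow the count formulas", {
  perfect <- confusion_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)

  truth <- c(rep(1, 3), rep(0, 7))
  est <- c(1, 1, 0, 1, rep(0, 6))
  m <- confusion_metrics(truth, est)
  expect_equal(unlist(m[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("mask metrics follow the overlap formulas", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_equal(mask_metrics(a, a)$dice, 1)

  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  m <- mask_metrics(a, b)  # disjoint
  expect_equal(m$dice, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f_measure, 0)

  half <- a; half[2:5, 2:3] <- FALSE  # half of a
  m2 <- mask_metrics(half, a)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$dice, 2 * 8 / (8 + 16))
})

test_that("weighted voting combines hard votes with the 0.5 criterion", {
  cv <- noduleclick:::combine_votes
  expect_equal(cv(matrix(c(1, 1, 1), 1), c(0.2, 0.5, 1))$.score, 1)
  expect_equal(cv(matrix(c(1, 1, 1), 1), c(0.2, 0.5, 1))$.label, 1L)

  got <- cv(matrix(c(1, 0, 1), 1), c(0, 0.5, 1))
  expect_equal(got$.score, (0 + 0 + 1) / 1.5)
  expect_equal(got$.label, 1L)

  # a score of exactly the criterion is negative (strict inequality)
  tie <- cv(matrix(c(1, 0), 1), c(1, 1))
  expect_equal(tie$.score, 0.5)
  expect_equal(tie$.label, 0L)

  # all-zero weights fall back to an unweighted majority
  mv <- cv(matrix(c(1, 1, 0), 1), c(0, 0, 0))
  expect_equal(mv$.score, 2 / 3)
})

test_that("training on the reference class sizes yields five weighted members", {
  tbl <- make_feature_table(table_spec(seed = 100L))
  fit <- suppressMessages(train_beed(tbl, base_kind = "RF",
                                     feature_method = "info_gain", k = 10,
                                     seed = 7L))
  expect_length(fit$members, 5)
  expect_length(fit$features, 10)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_equal(max(fit$weights), 1)
  expect_equal(order(fit$aucs), order(fit$weights))
  # every subset is balanced
  for (s in fit$subsets) {
    expect_equal(sum(tbl$label[match(s, tbl$id)] == 1), 30)
    expect_equal(sum(tbl$label[match(s, tbl$id)] == 0), 30)
  }

  # determinism: same seed, same subsets and weights
  fit2 <- suppressMessages(train_beed(tbl, base_kind = "RF",
                                      feature_method = "info_gain", k = 10,
                                      seed = 7L))
  expect_identical(fit$subsets, fit2$subsets)
  expect_equal(fit$aucs, fit2$aucs)

  pr <- predict(fit, tbl)
  expect_true(all(pr$.score >= 0 & pr$.score <= 1))
  expect_true(all(pr$.label %in% 0:1))
  expect_error(predict(fit, tbl[, 1:4]), "lacks feature")
})

test_that("a linearly separable table drives every member AUC to 1", {
  tbl <- make_feature_table(table_spec(n_majority = 40, n_minority = 10,
                                       n_features = 5, n_informative = 3,
                                       delta = 10, sigma = 0.5, seed = 11L))
  fit <- train_beed(tbl, base_kind = "LDA", feature_method = "none", seed = 2L)
  expect_true(all(fit$aucs == 1))
  expect_true(all(fit$weights == 1))
  pr <- predict(fit, tbl)
  expect_equal(pr$.label, tbl$label)
})

test_that("every base-learner kind trains and predicts on a small table", {
  tbl <- make_feature_table(table_spec(n_majority = 40, n_minority = 20,
                                       n_features = 6, n_informative = 3,
                                       delta = 3, sigma = 1, seed = 12L))
  holdout <- make_feature_table(table_spec(n_majority = 20, n_minority = 10,
                                           n_features = 6, n_informative = 3,
                                           delta = 3, sigma = 1, seed = 13L))
  for (kind in c("LDA", "RF", "NN", "AdaBoost", "XGBoost", "SVM")) {
    fit <- train_beed(tbl, base_kind = kind, feature_method = "none", seed = 3L)
    pr <- predict(fit, holdout)
    acc <- mean(pr$.label == holdout$label)
    expect_gt(acc, 0.7, label = kind)
  }
})

test_that("BEED models serialize to a directory and back", {
  tbl <- make_feature_table(table_spec(n_majority = 40, n_minority = 20,
                                       n_features = 6, n_informative = 3,
                                       delta = 3, seed = 15L))
  fit <- train_beed(tbl, base_kind = "LDA", feature_method = "pearson",
                    k = 4, seed = 5L)
  dir <- file.path(tempdir(), "beed_model")
  write_beed(fit, dir)
  back <- read_beed(dir)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$features, fit$features)
  expect_equal(predict(back, tbl), predict(fit, tbl))
})
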