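test_that("phantom tissues land at their specified HU levels", {
  ph <- small_phantom(seed = 31L)
  hu <- to_hounsfield(ph$slice)
  spec <- ph$spec

  nod <- spec$nodules[[1]]
  v <- hu[ph$truth]
  # CLT bound (plus <=0.5 HU quantisation from integer stored values)
  expect_lt(abs(mean(v) - nod$mean_hu),
            3 * nod$sd_hu / sqrt(length(v)) + 0.5)

  parench <- ph$lung & !ph$truth
  expect_lt(abs(mean(hu[parench]) - spec$lung_hu[1]), 2)
  expect_lt(abs(mean(hu[!ph$lung & hu < -950]) - spec$air_hu[1]), 2)

  # click sits at the truth centroid
  expect_true(ph$truth[ph$click$row, ph$click$col])
  expect_equal(ph$click$start_hu, hu[ph$click$row, ph$click$col])
})

test_that("phantoms are bit-reproducible from their seed", {
  a <- small_phantom(seed = 55L)
  b <- small_phantom(seed = 55L)
  expect_identical(a$slice$stored_values, b$slice$stored_values)
  expect_identical(a$truth, b$truth)
  c_ <- small_phantom(seed = 56L)
  expect_false(identical(a$slice$stored_values, c_$slice$stored_values))
})

test_that("degenerate phantom specs behave as documented", {
  none <- make_phantom(phantom_spec(image_size = c(96, 96), nodules = list()))
  expect_false(any(none$truth))
  expect_null(none$click)

  jp <- small_phantom(seed = 57L, juxtapleural = TRUE)
  expect_gt(sum(jp$truth & !jp$lung), 0)   # part of the nodule leaves the lung
  expect_gt(sum(jp$truth & jp$lung), 0)    # and part stays inside

  expect_error(
    make_phantom(phantom_spec(image_size = c(96, 96),
                              nodules = list(phantom_nodule(c(2, 2), 10)))),
    "outside")
  expect_error(phantom_nodule(c(10, 10), radius = 1), "radius")
  expect_error(phantom_spec(nodules = list(
    phantom_nodule(c(100, 100), 5, mean_hu = -900))), "exceed")
})

test_that("click jitter moves the click but keeps it reproducible", {
  a <- make_phantom(phantom_spec(image_size = c(128, 128), seed = 3L),
                    click_jitter = 3L)
  b <- make_phantom(phantom_spec(image_size = c(128, 128), seed = 3L),
                    click_jitter = 3L)
  expect_identical(a$click, b$click)
})

test_that("calibration samples come from the declared linear model", {
  noiseless <- make_calibration_set(50, seed = 8L, sigma_avg = 0, sigma_std = 0)
  co <- fit_mean_model(noiseless)
  expect_equal(as.numeric(co), attr(noiseless, "mean_coefs"), tolerance = 1e-10)
  # a noiseless avg makes (start, avg) collinear, which the spread fit rejects
  expect_error(fit_std_model(noiseless), "collinear")
  # spread recovery needs avg scatter: noiseless std, noisy avg
  exact_std <- make_calibration_set(50, seed = 8L, sigma_avg = 5, sigma_std = 0)
  sco <- fit_std_model(exact_std)
  expect_equal(as.numeric(sco), attr(exact_std, "std_coefs"), tolerance = 1e-8)

  # with noise: recovery within 3 standard errors at n = 500
  noisy <- make_calibration_set(500, seed = 8L, sigma_avg = 5)
  fit <- attr(fit_mean_model(noisy), "fit")
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)[1] - (-173.34)), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - 0.71), 3 * se[2])

  expect_identical(make_calibration_set(20, seed = 4L),
                   make_calibration_set(20, seed = 4L),
                   "same seed, same samples")
})

test_that("feature tables honour the class sizes and separation", {
  tbl <- make_feature_table(table_spec(seed = 19L))
  expect_equal(sum(tbl$label == 1), 160)
  expect_equal(sum(tbl$label == 0), 30)
  expect_equal(ncol(tbl), 22)  # id + label + 20 features

  # informative features separate by delta, the rest do not
  gap <- sapply(sprintf("f%02d", 1:20), function(f) {
    mean(tbl[[f]][tbl$label == 1]) - mean(tbl[[f]][tbl$label == 0])
  })
  expect_true(all(gap[1:5] > 0.3))
  expect_true(all(abs(gap[6:20]) < 0.8))
})

test_that("a zero-shift table is uninformative end to end", {
  null_spec <- table_spec(delta = 0, seed = 23L)
  tbl <- make_feature_table(null_spec)
  rr <- rank_features(tbl[, -1], "pearson")
  expect_lt(max(rr$score), 0.35)

  test <- make_feature_table(table_spec(delta = 0, seed = 24L))
  fit <- suppressMessages(train_beed(tbl, base_kind = "LDA",
                                     feature_method = "none", seed = 1L))
  pr <- predict(fit, test)
  expect_lt(abs(auc_score(test$label, pr$.score) - 0.5), 0.12)
})

test_that("a widely separated table is classified almost perfectly", {
  tbl <- make_feature_table(table_spec(delta = 6, seed = 25L))
  test <- make_feature_table(table_spec(delta = 6, seed = 26L))
  fit <- suppressMessages(train_beed(tbl, base_kind = "RF",
                                     feature_method = "info_gain", k = 5,
                                     seed = 1L))
  pr <- predict(fit, test)
  expect_gte(mean(pr$.label == test$label), 0.95)
})
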