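test_that("seeded growth returns exactly the seed's thresholded component", {
  shape <- c(40, 40)
  lung <- matrix(TRUE, shape[1], shape[2])
  hu <- matrix(-800, shape[1], shape[2])
  d <- disc(shape, c(20, 20), 6)
  hu[d] <- -300
  grown <- grow_region(hu, lung, click_seed(20, 20), threshold = -344.34)
  expect_identical(grown, d)

  # seed below the threshold -> empty
  expect_false(any(grow_region(hu, lung, click_seed(3, 3), -344.34)))

  # two blobs separated by background: only the seeded one
  hu2 <- matrix(-800, 30, 30)
  b1 <- disc(c(30, 30), c(10, 10), 4); b2 <- disc(c(30, 30), c(22, 22), 4)
  hu2[b1 | b2] <- -200
  grown2 <- grow_region(hu2, matrix(TRUE, 30, 30), click_seed(10, 10), -300)
  expect_identical(grown2, b1)

  expect_error(grow_region(hu, matrix(TRUE, 2, 2), click_seed(1, 1), 0),
               "shape")
})

test_that("growth matches the brute-force BFS oracle on random grids", {
  set.seed(202)
  for (i in 1:200) {
    eligible <- matrix(runif(24 * 24) < 0.55, 24, 24)
    seed_r <- sample(24, 1); seed_c <- sample(24, 1)
    hu <- ifelse(eligible, 1, -1)
    got <- grow_region(hu, matrix(TRUE, 24, 24),
                       click_seed(seed_r, seed_c), threshold = 0)
    expect_identical(got, bfs_oracle(eligible, seed_r, seed_c))
  }
})

test_that("morphology follows set arithmetic with background borders", {
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_false(any(erode_mask(single)))

  sq5 <- matrix(FALSE, 9, 9); sq5[3:7, 3:7] <- TRUE
  exp3 <- matrix(FALSE, 9, 9); exp3[4:6, 4:6] <- TRUE
  expect_identical(erode_mask(sq5), exp3)
  expect_identical(dilate_mask(exp3), sq5)

  # a solid block touching the border erodes at the border too
  solid <- matrix(TRUE, 5, 5)
  expect_equal(sum(erode_mask(solid)), 9)

  expect_error(erode_mask(sq5, kernel_size = 4), "odd")
  expect_error(dilate_mask(sq5, kernel_size = 2), "odd")
})

test_that("morphology equals the direct-definition oracle on random masks", {
  set.seed(88)
  for (i in 1:25) {
    m <- matrix(runif(18 * 15) < 0.5, 18, 15)
    expect_identical(erode_mask(m), erode_oracle(m))
    expect_identical(dilate_mask(m), dilate_oracle(m))
    # opening never enlarges
    opened <- dilate_mask(erode_mask(m))
    expect_true(all(!opened | m))
  }
})

test_that("noise removal keeps only the clicked component", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE     # clicked component
  m[12:14, 12:18] <- TRUE # noise
  out <- remove_noise(m, click_seed(3, 3))
  expect_true(all(which(out) %in% which(m)))
  expect_equal(sum(out), 16)
  expect_false(out[13, 13])

  expect_identical(remove_noise(matrix(FALSE, 5, 5), click_seed(2, 2)),
                   matrix(FALSE, 5, 5))

  # seed outside every component -> nearest component is kept
  lone <- matrix(FALSE, 20, 20); lone[15:17, 15:17] <- TRUE
  kept <- remove_noise(lone, click_seed(2, 2))
  expect_identical(kept, lone)
})

test_that("diagonal-only connections count as one 8-connected component", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE
  out <- remove_noise(m, click_seed(2, 2))
  expect_equal(sum(out), 3)
})

test_that("the TM pipeline segments a phantom nodule accurately", {
  ph <- small_phantom(seed = 4L)
  hu <- to_hounsfield(ph$slice)
  seg <- tm_segment(hu, ph$lung, ph$click, default_calibration())
  expect_s3_class(seg, "nodule_segmentation")
  expect_equal(seg$provenance, "TM")
  expect_false(seg$is_null)
  expect_gte(mask_metrics(seg$mask, ph$truth)$dice, 0.8)
  # the TM mask never leaves the lung
  expect_true(all(!seg$mask | ph$lung))
})

test_that("clicks in parenchyma or outside the lung yield a null result", {
  ph <- small_phantom(seed = 4L)
  hu <- to_hounsfield(ph$slice)
  cal <- default_calibration()

  # parenchyma click below its own estimated threshold -> excluded at growth.
  # At alpha = 0 the threshold is the estimated mean (about -740 HU for a
  # -800 HU click), so ordinary parenchyma falls below it.
  cand <- which(ph$lung & hu < -780 & !ph$truth, arr.ind = TRUE)[1, ]
  parench <- click_seed(cand[1], cand[2])
  expect_true(tm_segment(hu, ph$lung, parench, cal, alpha = 0)$is_null)

  # juxtapleural phantom: the click (nodule centroid) is outside the lung
  jp <- small_phantom(seed = 5L, juxtapleural = TRUE)
  expect_false(jp$lung[jp$click$row, jp$click$col])
  expect_true(tm_segment(to_hounsfield(jp$slice), jp$lung, jp$click, cal)$is_null)
})

test_that("TM mask area is non-decreasing in alpha", {
  ph <- small_phantom(seed = 6L)
  hu <- to_hounsfield(ph$slice)
  cal <- default_calibration()
  areas <- sapply(c(0.5, 1, 2, 3), function(a) {
    sum(tm_segment(hu, ph$lung, ph$click, cal, alpha = a)$mask)
  })
  expect_true(all(diff(areas) >= 0))
})

test_that("the classical lung masker recovers phantom lungs", {
  ph <- small_phantom(seed = 7L)
  est <- lung_mask_classical(to_hounsfield(ph$slice))
  expect_gte(mask_metrics(est, ph$lung)$dice, 0.9)
})
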