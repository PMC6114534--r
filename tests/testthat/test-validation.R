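test_that("perfect detections give ideal rates", {
  truth <- boxDf(c(0, 0, 20, 20,
                   50, 50, 70, 75))
  rep <- matchDetections(truth, truth)
  expect_equal(unname(rep@rates["correct_positive_rate"]), 1)
  expect_equal(unname(rep@rates["false_negative_rate"]), 0)
  expect_equal(unname(rep@rates["false_positive_rate"]), 0)
  expect_equal(unname(rep@rates["double_detection_rate"]), 0)
  expect_equal(unname(rep@rates["precision"]), 1)
  expect_equal(rep@pairs$iou, c(1, 1))
  expect_true(all(rep@pairs$type == "correct"))
})

test_that("rates are counted per truth or per detection as documented", {
  truth <- boxDf(c(0, 0, 20, 20,
                   100, 100, 120, 120))
  det <- boxDf(c(0, 0, 20, 20,        # correct for truth 1
                 2, 2, 22, 22,        # double on truth 1
                 300, 300, 320, 320)) # false positive
  rep <- matchDetections(det, truth)
  r <- rep@rates
  expect_equal(unname(r["correct_positive_rate"]), 1 / 2)   # per truth
  expect_equal(unname(r["false_negative_rate"]), 1 / 2)     # truth 2 missed
  expect_equal(unname(r["double_detection_rate"]), 1 / 2)   # per truth
  expect_equal(unname(r["false_positive_rate"]), 1 / 3)     # per detection
  expect_equal(unname(r["precision"]), 1 / 3)
  expect_equal(unname(r["correct_positive_rate"] + r["false_negative_rate"]),
               1)
  cnt <- rep@counts
  expect_equal(unname(cnt[c("n_truth", "n_detections", "n_matched",
                            "n_false_positive", "n_double")]),
               c(2, 3, 1, 1, 1))
})

test_that("greedy matching takes the highest IoU first", {
  truth <- boxDf(c(0, 0, 10, 10))
  det <- boxDf(c(0, 0, 10, 12,        # IoU 10/12
                 0, 0, 10, 10))       # IoU 1 -> must win the truth box
  rep <- matchDetections(det, truth)
  correct <- rep@pairs[rep@pairs$type == "correct", ]
  expect_equal(correct$detection, 2L)
  expect_equal(correct$iou, 1)
  expect_equal(rep@pairs$type[rep@pairs$detection == 1L], "double")
})

test_that("the IoU threshold gates the matches", {
  truth <- boxDf(c(0, 0, 10, 10))
  ## half-overlapping box: intersection 50, union 150 -> IoU = 1/3
  det <- boxDf(c(5, 0, 15, 10))
  expect_equal(budquant:::boxIoU(as.numeric(det[1, ]),
                                 as.numeric(truth[1, ])), 1 / 3)
  hit <- matchDetections(det, truth, minOverlap = 0.25)
  expect_equal(unname(hit@rates["correct_positive_rate"]), 1)
  miss <- matchDetections(det, truth, minOverlap = 0.5)
  expect_equal(unname(miss@rates["correct_positive_rate"]), 0)
  expect_equal(unname(miss@rates["false_positive_rate"]), 1)
})

test_that("empty edge cases are reported honestly", {
  b <- boxDf(c(0, 0, 10, 10))
  e <- b[0, ]
  ## nothing at all: degenerate, precision 1 by convention
  both <- matchDetections(e, e)
  expect_true(both@degenerate)
  expect_equal(unname(both@rates["precision"]), 1)
  expect_equal(unname(both@rates["correct_positive_rate"]), 0)
  ## truth but no detections: pure false negatives
  fn <- matchDetections(e, b)
  expect_false(fn@degenerate)
  expect_equal(unname(fn@rates["false_negative_rate"]), 1)
  expect_equal(unname(fn@rates["precision"]), 1)  # no detections, none wrong
  ## detections but no truth: pure false positives
  fp <- matchDetections(b, e)
  expect_equal(unname(fp@rates["false_positive_rate"]), 1)
  expect_equal(unname(fp@rates["precision"]), 0)
})

test_that("count concordance equals the closed-form OLS R-squared", {
  set.seed(12)
  truth <- rpois(20, 8)
  detected <- truth + rnorm(20, 0, 1.5)
  cc <- countConcordance(detected, truth)
  expect_equal(cc$r_squared, oracleR2(detected, truth), tolerance = 1e-12)
  expect_false(cc$flagged)
  ## exact linear relation: R^2 = 1, slope and intercept recovered
  exact <- suppressWarnings(countConcordance(2 * truth + 3, truth))
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 3)
  ## zero-variance truth is flagged, not silently fit
  expect_warning(flat <- countConcordance(detected[1:5], rep(4, 5)),
                 "zero variance")
  expect_true(flat$flagged)
  expect_true(is.na(flat$r_squared))
  expect_error(countConcordance(1:2, 1:2), "three cores")
})

test_that("grade concordance reports exact agreement and R-squared", {
  g <- c(0L, 1L, 2L, 3L, 4L, 2L)
  perfect <- suppressWarnings(gradeConcordance(g, g))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$r_squared, 1)
  off <- gradeConcordance(c(g[-6], 3L), g)
  expect_equal(off$accuracy, 5 / 6)
  expect_true(is.na(gradeConcordance(c(1L, 1L), c(2L, 2L))$r_squared))
})
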