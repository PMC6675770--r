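test_that("the train/test split reproduces the standard design counts", {
  s <- gaussian_samples(2000, distance = 2, seed = 1)
  split <- split_train_test(s, n_train_per_class = 100, seed = 9)
  tab <- table(split$label, split$set)
  expect_identical(unname(tab["cancer", "train"]), 100L)
  expect_identical(unname(tab["noncancer", "train"]), 100L)
  expect_identical(unname(tab["cancer", "test"]), 1900L)
  expect_identical(unname(tab["noncancer", "test"]), 1900L)
  expect_identical(sum(split$set == "test"), 3800L)

  # deterministic under the seed
  again <- split_train_test(s, n_train_per_class = 100, seed = 9)
  expect_identical(split, again)
  other <- split_train_test(s, n_train_per_class = 100, seed = 10)
  expect_false(identical(split$set, other$set))
})

test_that("oversized training requests are rejected", {
  s <- gaussian_samples(200, distance = 2, seed = 1)
  expect_error(split_train_test(s, n_train_per_class = 200),
               class = "chromsep_split_error")
  expect_error(split_train_test(s, n_train_per_class = 500),
               class = "chromsep_split_error")
})

test_that("evaluation implements the confusion-matrix formulas", {
  # all correct
  truths <- rep(c("cancer", "noncancer"), each = 1900)
  r <- evaluate_predictions(truths, truths)
  expect_equal(r[, c("sensitivity", "ppv", "f1")],
               tibble::tibble(sensitivity = 1, ppv = 1, f1 = 1))

  # everything positive on a balanced test set
  r <- evaluate_predictions(rep("cancer", 3800), truths)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$ppv, 0.5)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-12)

  # direct formula evaluation for a printed case
  preds <- c(rep("cancer", 1500), rep("noncancer", 400), # truth: cancer
             rep("cancer", 300), rep("noncancer", 1600)) # truth: noncancer
  r <- evaluate_predictions(preds, truths)
  expect_identical(c(r$tp, r$fn, r$fp, r$tn), c(1500L, 400L, 300L, 1600L))
  expect_equal(r$sensitivity, 1500 / 1900, tolerance = 1e-12)
  expect_equal(r$ppv, 1500 / 1800, tolerance = 1e-12)
  expect_equal(r$f1, 2 * (1500 / 1900) * (1500 / 1800) /
                 (1500 / 1900 + 1500 / 1800), tolerance = 1e-12)
  expect_equal(round(c(r$sensitivity, r$ppv, r$f1), 5),
               c(0.78947, 0.83333, 0.81081))

  # zero-division policy: no true positives scores 0 across the board
  r0 <- evaluate_predictions(rep("noncancer", 3800), truths)
  expect_identical(c(r0$sensitivity, r0$ppv, r0$f1), c(0, 0, 0))

  expect_error(evaluate_predictions(rep("cancer", 3), rep("cancer", 4)),
               class = "chromsep_evaluation_error")
})

test_that("confusion counts are conserved and margins match class sizes", {
  s <- gaussian_samples(600, distance = 1.5, seed = 3)
  r <- svm_diagnosis(s, n_train_per_class = 100, seed = 3)
  expect_identical(r$tp + r$fp + r$tn + r$fn, r$n_test)
  expect_identical(r$tp + r$fn, 500L) # cancer test margin
  expect_identical(r$tn + r$fp, 500L)
  # F1 lies between sensitivity and PPV when both are positive
  expect_gte(r$f1, min(r$sensitivity, r$ppv))
  expect_lte(r$f1, max(r$sensitivity, r$ppv))
})

test_that("widely separated classes are learned perfectly", {
  s <- gaussian_samples(300, distance = 30, seed = 11, sigma = 4)
  split <- split_train_test(s, 50, seed = 1)
  clf <- train_pixel_classifier(split[split$set == "train", ])
  expect_identical(predict(clf, split[split$set == "train", ]),
                   split$label[split$set == "train"])
  r <- svm_diagnosis(s, n_train_per_class = 50, seed = 1)
  expect_identical(r$f1, 1)
})

test_that("identical class distributions score at chance level", {
  scores <- purrr::map_dbl(1:10, function(seed) {
    s <- gaussian_samples(800, distance = 0, seed = 100 + seed)
    r <- svm_diagnosis(s, n_train_per_class = 100, seed = seed)
    (r$sensitivity + (1 - r$fp / (r$fp + r$tn))) / 2 # balanced accuracy
  })
  expect_lt(abs(mean(scores) - 0.5), 0.05)
})

test_that("test error at distance 2 approaches the Gaussian Bayes error", {
  errs <- purrr::map_dbl(1:10, function(seed) {
    s <- gaussian_samples(2000, distance = 2, seed = 200 + seed)
    r <- svm_diagnosis(s, n_train_per_class = 100, seed = seed)
    (r$fp + r$fn) / r$n_test
  })
  expect_lt(abs(mean(errs) - stats::pnorm(-1)), 0.05)
})

test_that("degenerate training data raise a training error", {
  s <- tibble::tibble(label = rep(c("cancer", "noncancer"), each = 10),
                      R = 100, G = 100, B = 100)
  expect_error(train_pixel_classifier(s),
               class = "chromsep_training_error")
})

test_that("mean F1 increases with the class separation", {
  mean_f1 <- purrr::map_dbl(c(0.5, 1, 2, 3), function(d) {
    mean(purrr::map_dbl(1:5, function(seed) {
      s <- gaussian_samples(700, distance = d, seed = 300 + 10 * d + seed)
      svm_diagnosis(s, n_train_per_class = 100, seed = seed)$f1
    }))
  })
  expect_true(all(diff(mean_f1) > 0))
})
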