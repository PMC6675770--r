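test_that("class statistics match a direct-summation oracle", {
  # identical samples: zero covariance
  same <- matrix(rep(c(10, 20, 30), each = 5), 5, 3)
  st <- estimate_class_stats(same)
  expect_equal(st$mean, c(10, 20, 30), ignore_attr = TRUE)
  expect_true(all(st$covariance == 0))

  # four hand-listed vectors vs pairwise-deviation summation
  x <- matrix(c(1, 2, 3,
                4, 6, 8,
                0, 0, 1,
                5, 2, 0), 4, 3, byrow = TRUE)
  st <- estimate_class_stats(x)
  mu <- colSums(x) / 4
  s <- matrix(0, 3, 3)
  for (i in 1:4) s <- s + tcrossprod(x[i, ] - mu)
  s <- s / 3
  expect_equal(st$mean, mu, ignore_attr = TRUE)
  expect_equal(st$covariance, s, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(st$n, 4L)

  expect_error(estimate_class_stats(x[1:3, ]),
               class = "chromsep_insufficient_sample_error")
})

test_that("estimated means obey the sampling-theory bound at n = 2000", {
  sigma <- 10
  s <- gaussian_samples(2000, distance = 2, seed = 31, sigma = sigma)
  st <- estimate_class_stats(s[s$label == "noncancer", ])
  expect_true(all(abs(st$mean - c(120, 100, 90)) < 3 * sigma / sqrt(2000)))
})

test_that("Mahalanobis separation matches analytic cases", {
  a <- estimate_class_stats(gaussian_samples(200, 1, seed = 1)[1:200, ])
  expect_equal(mahalanobis_separation(a, a)$distance, 0)

  mk <- function(mean, cov) {
    structure(list(mean = mean, covariance = cov, n = 2000),
              class = "class_stats")
  }
  r <- mahalanobis_separation(mk(c(103, 50, 50), diag(3)),
                              mk(c(100, 50, 50), diag(3)))
  expect_equal(r$distance, 3, tolerance = 1e-12)
  expect_false(r$regularized)
})

test_that("separation agrees with the closed-form oracle on random statistics", {
  mk <- function(mean, cov) {
    structure(list(mean = mean, covariance = cov, n = 2000),
              class = "class_stats")
  }
  withr::with_seed(23, {
    for (i in 1:25) {
      m1 <- runif(3, 30, 220); m2 <- runif(3, 30, 220)
      s1 <- random_spd(); s2 <- random_spd()
      got <- mahalanobis_separation(mk(m1, s1), mk(m2, s2))$distance
      expect_equal(got,
                   closed_form_separation(region_color_model(m1, s1),
                                          region_color_model(m2, s2)),
                   tolerance = 1e-9)
      expect_equal(got, sqrt(stats::mahalanobis(m1, m2, (s1 + s2) / 2)),
                   tolerance = 1e-9)
    }
  })
})

test_that("separation is exactly symmetric and linear in the mean difference", {
  mk <- function(mean, cov) {
    structure(list(mean = mean, covariance = cov, n = 2000),
              class = "class_stats")
  }
  withr::with_seed(41, {
    for (i in 1:10) {
      m1 <- runif(3, 30, 220); m2 <- runif(3, 30, 220)
      s1 <- random_spd(); s2 <- random_spd()
      d_ab <- mahalanobis_separation(mk(m1, s1), mk(m2, s2))$distance
      d_ba <- mahalanobis_separation(mk(m2, s2), mk(m1, s1))$distance
      expect_identical(d_ab, d_ba)
      # doubling the mean difference doubles the distance
      m3 <- m2 + 2 * (m1 - m2)
      d2 <- mahalanobis_separation(mk(m3, s1), mk(m2, s2))$distance
      expect_equal(d2, 2 * d_ab, tolerance = 1e-9)
    }
  })
})

test_that("separation is invariant under affine maps of the feature space", {
  s <- gaussian_samples(800, distance = 2, seed = 77)
  base <- color_separation(s)$mahalanobis_distance
  withr::with_seed(78, {
    a <- matrix(rnorm(9), 3, 3) + diag(3)
    offset <- rnorm(3, 0, 10)
  })
  x <- as.matrix(s[, c("R", "G", "B")]) %*% t(a) +
    matrix(offset, nrow(s), 3, byrow = TRUE)
  mapped <- s
  mapped[, c("R", "G", "B")] <- as.data.frame(x)
  expect_equal(color_separation(mapped)$mahalanobis_distance, base,
               tolerance = 1e-6)
})

test_that("degenerate covariances are regularized or rejected, never silent", {
  mk <- function(mean, cov, n = 2000) {
    structure(list(mean = mean, covariance = cov, n = n),
              class = "class_stats")
  }
  # ill-conditioned: ridge applied and flagged
  ill <- diag(c(100, 1e-8, 100))
  r <- mahalanobis_separation(mk(c(110, 50, 50), ill), mk(c(100, 50, 50), ill))
  expect_true(r$regularized)
  expect_true(is.finite(r$distance))

  # identically zero covariance with equal means: distance 0, no error
  z <- matrix(0, 3, 3)
  r0 <- mahalanobis_separation(mk(c(10, 10, 10), z), mk(c(10, 10, 10), z))
  expect_identical(r0$distance, 0)

  # identically zero covariance with unequal means: impossible to normalize
  expect_error(
    mahalanobis_separation(mk(c(10, 10, 10), z), mk(c(20, 10, 10), z)),
    class = "chromsep_degenerate_covariance_error")
})

test_that("weighted and unweighted pooling coincide for equal class sizes", {
  s <- gaussian_samples(500, distance = 1.5, seed = 55)
  expect_equal(color_separation(s, pooling = "weighted")$mahalanobis_distance,
               color_separation(s, pooling = "unweighted")$mahalanobis_distance,
               tolerance = 1e-12)
})
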