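# Shared fixture builders. Everything is generated in code under fixed seeds;
# no fixture files are stored.

# A compact study spec for fast tests: smaller rasters, otherwise default
# study conditions.
small_study_spec <- function(n_lesions = 2, seed = 1L, ...) {
  study_spec(n_lesions = n_lesions, image_size = c(96, 96), seed = seed, ...)
}

# Labeled sample tibble drawn from two trivariate Gaussians with equal
# covariance sigma^2 * I whose means differ by `distance` Mahalanobis units
# along a luminance-neutral chromatic direction. Used as the analytic
# benchmark input for the estimator and classifier stages.
gaussian_samples <- function(n_per_class, distance, seed,
                             sigma = 10, base_mean = c(120, 100, 90)) {
  u <- c(0.587, -0.299, 0)
  u <- u / sqrt(sum(u^2))
  withr::with_seed(seed, {
    xc <- MASS::mvrnorm(n_per_class, base_mean + distance * sigma * u,
                        diag(sigma^2, 3))
    xn <- MASS::mvrnorm(n_per_class, base_mean, diag(sigma^2, 3))
    tibble::tibble(
      label = rep(c("cancer", "noncancer"), each = n_per_class),
      R = c(xc[, 1], xn[, 1]),
      G = c(xc[, 2], xn[, 2]),
      B = c(xc[, 3], xn[, 3])
    )
  })
}

# Random positive-definite 3x3 covariance with moderate conditioning.
random_spd <- function(scale = 25) {
  a <- matrix(rnorm(9), 3, 3)
  scale * (crossprod(a) / 3 + diag(0.5, 3))
}

# A quick deterministic labeled image with well-separated Gaussian regions.
quick_labeled_image <- function(seed = 1L, separation = 2,
                                gradient = 0, sigma = 12) {
  u <- c(0.587, -0.299, 0) / sqrt(0.587^2 + 0.299^2)
  base <- c(150, 95, 85)
  generate_lesion_image(lesion_spec(
    "Lq", "WL",
    cancer_model = region_color_model(base + separation * sigma * u,
                                      diag(sigma^2, 3)),
    noncancer_model = region_color_model(base, diag(sigma^2, 3)),
    image_size = c(96, 96),
    luminance_gradient_amplitude = gradient,
    seed = seed
  ))
}
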