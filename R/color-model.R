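#' Ground-truth color model for one image region
#'
#' A region color model is a trivariate Gaussian over 8-bit RGB space: the
#' simulator draws every pixel of a region (cancerous or non-cancerous) from
#' it. Because the model parameters are known exactly, every downstream
#' estimate — sample means, covariances, Mahalanobis distances — has a
#' closed-form oracle.
#'
#' @param mean_rgb Numeric length-3 vector of channel means, each in
#'   \[0, 255\].
#' @param cov_rgb 3x3 symmetric positive semi-definite covariance matrix in
#'   squared intensity units. A scalar is promoted to `scalar * I`.
#' @return An object of class `region_color_model`.
#' @export
#' @examples
#' region_color_model(c(150, 90, 80), 144)
region_color_model <- function(mean_rgb, cov_rgb) {
  mean_rgb <- as.numeric(mean_rgb)
  if (length(mean_rgb) != 3 || anyNA(mean_rgb) ||
      any(mean_rgb < 0) || any(mean_rgb > 255)) {
    abort("`mean_rgb` must be 3 finite values within [0, 255].",
          class = "chromsep_config_error")
  }
  if (is.numeric(cov_rgb) && length(cov_rgb) == 1) {
    cov_rgb <- diag(as.numeric(cov_rgb), 3)
  }
  cov_rgb <- as.matrix(cov_rgb)
  if (!is_symmetric_psd(cov_rgb)) {
    abort("`cov_rgb` must be a 3x3 symmetric positive semi-definite matrix.",
          class = "chromsep_config_error")
  }
  structure(
    list(mean_rgb = mean_rgb, cov_rgb = (cov_rgb + t(cov_rgb)) / 2),
    class = "region_color_model"
  )
}

#' @export
print.region_color_model <- function(x, ...) {
  cat("<region_color_model>\n")
  cat("  mean RGB:", paste(format(x$mean_rgb, digits = 4), collapse = ", "), "\n")
  cat("  covariance diag:",
      paste(format(diag(x$cov_rgb), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form Mahalanobis separation between two color models
#'
#' Analytic oracle for the pipeline's estimated color-separation distance:
#' `sqrt(t(dmu) %*% solve(S_pooled) %*% dmu)` with
#' `S_pooled = (S_a + S_b) / 2`, computed from the true model parameters
#' rather than from sampled pixels. Estimates from generated images converge
#' to this value as the pixel count grows.
#'
#' @param cancer,noncancer `region_color_model` objects.
#' @return Non-negative numeric distance.
#' @export
#' @examples
#' a <- region_color_model(c(120, 90, 80), diag(3))
#' b <- region_color_model(c(123, 90, 80), diag(3))
#' closed_form_separation(a, b) # 3
closed_form_separation <- function(cancer, noncancer) {
  stopifnot(inherits(cancer, "region_color_model"),
            inherits(noncancer, "region_color_model"))
  dmu <- cancer$mean_rgb - noncancer$mean_rgb
  pooled <- (cancer$cov_rgb + noncancer$cov_rgb) / 2
  if (all(dmu == 0)) return(0)
  pooled <- regularize_covariance(pooled)$sigma
  qf <- tryCatch(
    drop(crossprod(dmu, solve(pooled, dmu))),
    error = function(e) abort(
      "Pooled covariance is singular even after regularization.",
      class = "chromsep_numerical_error")
  )
  sqrt(max(qf, 0))
}

# Ridge-regularize a covariance matrix whose condition number exceeds
# `threshold`: add eps * I with eps = 1e-6 * mean diagonal variance. Returns
# the (possibly modified) matrix, its condition number, and whether the ridge
# was applied.
regularize_covariance <- function(sigma, threshold = 1e8) {
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  regularized <- FALSE
  if (!is.finite(cond) || cond > threshold) {
    eps <- 1e-6 * sum(diag(sigma)) / 3
    if (eps > 0) {
      sigma <- sigma + diag(eps, nrow(sigma))
      regularized <- TRUE
      ev <- ev + eps
      cond <- max(ev) / min(ev)
    }
  }
  list(sigma = sigma, condition_number = cond, regularized = regularized)
}
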