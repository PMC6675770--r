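#' Estimate class-conditional RGB statistics
#'
#' Arithmetic sample mean and unbiased (n - 1 denominator) sample covariance
#' of one class's RGB pixel samples — the per-class mean vector and
#' covariance matrix that enter the Mahalanobis color-separation distance.
#'
#' @param samples A tibble with `R`, `G`, `B` columns, or an n x 3 numeric
#'   matrix. At least 4 samples are required for a usable 3 x 3 covariance.
#' @return An object of class `class_stats` with fields `mean` (length-3),
#'   `covariance` (3 x 3), `n`.
#' @export
estimate_class_stats <- function(samples) {
  x <- if (is.matrix(samples)) samples else
    as.matrix(samples[, c("R", "G", "B")])
  if (nrow(x) < 4) {
    abort(sprintf("At least 4 samples are required; got %d.", nrow(x)),
          class = "chromsep_insufficient_sample_error")
  }
  structure(
    list(mean = colMeans(x), covariance = stats::cov(x), n = nrow(x)),
    class = "class_stats"
  )
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("<class_stats> n = %d, mean RGB = (%s)\n", x$n,
              paste(format(x$mean, digits = 5), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.class_stats <- function(x, ...) {
  tibble(channel = c("R", "G", "B"), mean = unname(x$mean),
         variance = unname(diag(x$covariance)), n = x$n)
}

#' Mahalanobis color-separation distance between two classes
#'
#' The covariance-normalized distance between the two class mean vectors,
#' `sqrt(t(dmu) %*% solve(S) %*% dmu)` with `S` the pooled covariance. The
#' default pooling is the unweighted average `(S_a + S_b) / 2`, symmetric in
#' the classes; `pooling = "weighted"` weights by sample counts instead
#' (identical when the class sizes are equal, as in the standard
#' 2000-per-class design). If the pooled covariance has condition number
#' above `cond_threshold` it is ridge-regularized by `eps * I` with
#' `eps = 1e-6 * mean diagonal variance`, and the result is flagged —
#' degenerate inputs are handled, never silently.
#'
#' @param a,b `class_stats` objects (order does not affect the result).
#' @param pooling `"unweighted"` (default) or `"weighted"`.
#' @param cond_threshold Condition-number threshold that triggers the ridge.
#' @return An object of class `separation_result`: `distance`,
#'   `condition_number`, `regularized`.
#' @export
#' @examples
#' a <- estimate_class_stats(matrix(rnorm(300, 100, 5), ncol = 3))
#' b <- estimate_class_stats(matrix(rnorm(300, 110, 5), ncol = 3))
#' mahalanobis_separation(a, b)
mahalanobis_separation <- function(a, b,
                                   pooling = c("unweighted", "weighted"),
                                   cond_threshold = 1e8) {
  stopifnot(inherits(a, "class_stats"), inherits(b, "class_stats"))
  pooling <- match.arg(pooling)
  pooled <- switch(pooling,
    unweighted = (a$covariance + b$covariance) / 2,
    weighted = ((a$n - 1) * a$covariance + (b$n - 1) * b$covariance) /
      (a$n + b$n - 2)
  )
  dmu <- a$mean - b$mean
  reg <- regularize_covariance(pooled, threshold = cond_threshold)
  if (all(dmu == 0)) {
    distance <- 0
  } else {
    qf <- tryCatch(
      drop(crossprod(dmu, solve(reg$sigma, dmu))),
      error = function(e) abort(
        "Pooled covariance is singular even after regularization but the class means differ.",
        class = "chromsep_degenerate_covariance_error")
    )
    if (!is.finite(qf)) {
      abort("Pooled covariance is singular even after regularization but the class means differ.",
            class = "chromsep_degenerate_covariance_error")
    }
    distance <- sqrt(max(qf, 0))
  }
  structure(
    list(distance = distance, condition_number = reg$condition_number,
         regularized = reg$regularized),
    class = "separation_result"
  )
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> distance = %.4f%s\n", x$distance,
              if (x$regularized) " (covariance regularized)" else ""))
  invisible(x)
}

#' @export
tidy.separation_result <- function(x, ...) {
  tibble(mahalanobis_distance = x$distance,
         condition_number = x$condition_number,
         regularized = x$regularized)
}

#' Color separation of a labeled sample table
#'
#' Data-frame front end to the distance: estimates per-class statistics from
#' a labeled pixel sample (cancer vs non-cancer) and returns the Mahalanobis
#' separation as a one-row tibble, ready to bind into a per-image results
#' table.
#'
#' @param samples A tibble with `label` (`"cancer"`/`"noncancer"`), `R`,
#'   `G`, `B` columns, e.g. from [luminance_matched_sample()].
#' @inheritParams mahalanobis_separation
#' @return A one-row tibble: `mahalanobis_distance`, `condition_number`,
#'   `regularized`.
#' @export
color_separation <- function(samples, pooling = c("unweighted", "weighted"),
                             cond_threshold = 1e8) {
  stats_c <- estimate_class_stats(samples[samples$label == "cancer", ])
  stats_n <- estimate_class_stats(samples[samples$label == "noncancer", ])
  tidy(mahalanobis_separation(stats_c, stats_n, pooling = pooling,
                              cond_threshold = cond_threshold))
}
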