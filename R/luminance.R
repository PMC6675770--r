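#' Per-pixel luminance from RGB
#'
#' Scalar brightness as the weighted channel sum `w_R*R + w_G*G + w_B*B`.
#' The default weights are the ITU-R BT.601 luma coefficients
#' (0.299, 0.587, 0.114); BT.709 weights may be supplied instead via
#' `luma_weights("bt709")`. Weights sum to 1, so gray pixels map to their
#' own intensity and the result stays in \[0, 255\].
#'
#' @param R,G,B Numeric vectors of channel intensities in \[0, 255\]. `R`
#'   may instead be an n x 3 matrix (columns R, G, B).
#' @param weights Length-3 luma weights.
#' @return Numeric vector of luminance values in \[0, 255\].
#' @export
#' @examples
#' luminance(255, 0, 0) # 76.245
#' luminance(80, 80, 80) # 80
luminance <- function(R, G = NULL, B = NULL, weights = luma_weights()) {
  if (is.matrix(R) && is.null(G)) {
    G <- R[, 2]; B <- R[, 3]; R <- R[, 1]
  }
  if (any(c(R, G, B) < 0) || any(c(R, G, B) > 255)) {
    abort("RGB components must lie in [0, 255].",
          class = "chromsep_domain_error")
  }
  weights[1] * R + weights[2] * G + weights[3] * B
}

#' @rdname luminance
#' @param standard `"bt601"` (default) or `"bt709"`.
#' @export
luma_weights <- function(standard = c("bt601", "bt709")) {
  switch(match.arg(standard),
         bt601 = c(0.299, 0.587, 0.114),
         bt709 = c(0.2126, 0.7152, 0.0722))
}

#' Add a luminance column to a pixel table
#'
#' @param pixels A tibble with `R`, `G`, `B` columns (e.g. from
#'   [region_pixels()]).
#' @param weights Length-3 luma weights, see [luma_weights()].
#' @return The input tibble with a `luminance` column appended.
#' @export
add_luminance <- function(pixels, weights = luma_weights()) {
  dplyr::mutate(pixels,
                luminance = luminance(.data$R, .data$G, .data$B,
                                      weights = weights))
}

#' Luminance-matched random pixel sampling
#'
#' Draws `n_per_class` pixels from each region such that the two samples
#' have identical luminance histograms, removing brightness as a confounder
#' so downstream color statistics reflect chromatic differences only. The
#' luminance range \[0, 255\] is partitioned into `n_bins` equal-width bins;
#' each bin's joint capacity is the smaller of the two class counts in it;
#' `n_per_class` is allocated across bins proportionally to joint capacity
#' by largest-remainder rounding (ties broken toward the lower bin index);
#' and the allocation is drawn uniformly without replacement from each class
#' within each bin. Both returned classes therefore have exactly equal
#' per-bin counts.
#'
#' @param pixels A tibble of labeled pixels with columns `label`, `R`, `G`,
#'   `B` (and any others, carried through), e.g. from [region_pixels()].
#' @param n_per_class Samples to draw from each class (default 2000, i.e.
#'   4000 pixels in total per image).
#' @param n_bins Number of equal-width luminance bins (default 32).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param weights Luma weights used to compute luminance.
#' @return A tibble of `2 * n_per_class` rows with columns of `pixels` plus
#'   `luminance` and `bin` (1-based bin index), of class
#'   `chromsep_samples`.
#' @export
luminance_matched_sample <- function(pixels, n_per_class = 2000,
                                     n_bins = 32, seed = 1L,
                                     weights = luma_weights()) {
  n_per_class <- stopifnot_scalar_count(n_per_class, "n_per_class")
  n_bins <- stopifnot_scalar_count(n_bins, "n_bins")
  labels <- c("cancer", "noncancer")
  if (!all(labels %in% pixels$label)) {
    abort("`pixels` must contain both 'cancer' and 'noncancer' labels.",
          class = "chromsep_empty_region_error")
  }
  pixels <- add_luminance(pixels, weights = weights)
  breaks <- seq(0, 255, length.out = n_bins + 1)
  pixels$bin <- pmin(findInterval(pixels$luminance, breaks,
                                  rightmost.closed = TRUE), n_bins)

  counts <- vapply(labels, function(lb) {
    tabulate(pixels$bin[pixels$label == lb], nbins = n_bins)
  }, integer(n_bins))
  capacity <- pmin(counts[, 1], counts[, 2])
  total <- sum(capacity)
  if (total < n_per_class) {
    abort(sprintf(
      "Luminance-matched sampling infeasible: joint bin capacity is %d but %d samples per class were requested.",
      total, n_per_class), class = "chromsep_infeasible_sampling_error")
  }

  alloc <- largest_remainder_alloc(n_per_class, capacity)

  drawn <- with_seed(seed, {
    purrr::map(labels, function(lb) {
      cls <- pixels[pixels$label == lb, ]
      picked <- purrr::map(which(alloc > 0), function(b) {
        in_bin <- which(cls$bin == b)
        in_bin[sample.int(length(in_bin), alloc[b])]
      })
      cls[sort(unlist(picked)), ]
    })
  })
  out <- dplyr::bind_rows(drawn)
  class(out) <- c("chromsep_samples", class(out))
  out
}

# Allocate n across bins proportionally to capacity, largest-remainder
# rounding, ties broken toward the lower bin index. Guarantees
# alloc <= capacity element-wise whenever n <= sum(capacity).
largest_remainder_alloc <- function(n, capacity) {
  quota <- n * capacity / sum(capacity)
  alloc <- floor(quota)
  short <- n - sum(alloc)
  if (short > 0) {
    frac <- quota - alloc
    ord <- order(-frac, seq_along(frac)) # largest remainder, then lower bin
    alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1
  }
  as.integer(alloc)
}

#' Diagnostic plot of luminance matching
#'
#' Overlaid per-class luminance histograms of a matched sample; matched
#' classes produce identical bar heights bin by bin.
#'
#' @param samples Output of [luminance_matched_sample()].
#' @param n_bins Bins for display.
#' @return A ggplot object.
#' @export
plot_luminance_match <- function(samples, n_bins = 32) {
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$luminance, fill = .data$label)) +
    ggplot2::geom_histogram(position = "dodge", bins = n_bins,
                            boundary = 0) +
    ggplot2::labs(x = "Luminance", y = "Pixels", fill = "Region") +
    ggplot2::theme_minimal()
}
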