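#' Pipeline configuration
#'
#' Collects every tunable of the per-image analysis: sample sizes, the
#' luminance-matching bin count, luma convention, covariance pooling, SVM
#' hyperparameters, and optional boundary erosion. Defaults are the standard
#' study design: 2000 luminance-matched pixels per class per image, 32
#' luminance bins, 100 training samples per class.
#'
#' @param n_per_class Pixels sampled per class per image.
#' @param n_bins Equal-width luminance bins for matching.
#' @param n_train_per_class Training samples per class for the SVM test.
#' @param luma `"bt601"` or `"bt709"` luminance weights.
#' @param pooling Covariance pooling for the distance, see
#'   [mahalanobis_separation()].
#' @param boundary_erode Pixels of mask erosion at the tumor boundary
#'   (default 0, see [region_pixels()]).
#' @param svm An [svm_params()] object.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class = 2000, n_bins = 32,
                            n_train_per_class = 100,
                            luma = c("bt601", "bt709"),
                            pooling = c("unweighted", "weighted"),
                            boundary_erode = 0,
                            svm = svm_params()) {
  structure(
    list(n_per_class = stopifnot_scalar_count(n_per_class, "n_per_class"),
         n_bins = stopifnot_scalar_count(n_bins, "n_bins"),
         n_train_per_class = stopifnot_scalar_count(n_train_per_class,
                                                    "n_train_per_class"),
         luma = match.arg(luma),
         pooling = match.arg(pooling),
         boundary_erode = boundary_erode,
         svm = svm),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; recognised keys are the arguments of
#' [pipeline_config()] plus `svm_cost`, `svm_gamma`, `svm_kernel`. Missing
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  svm <- svm_params(cost = raw$svm_cost %||% 1,
                    gamma = raw$svm_gamma,
                    kernel = raw$svm_kernel %||% "radial")
  args <- raw[intersect(names(raw),
                        c("n_per_class", "n_bins", "n_train_per_class",
                          "luma", "pooling", "boundary_erode"))]
  do.call(pipeline_config, c(args, list(svm = svm)))
}

#' Analyze one labeled image
#'
#' Runs the complete per-image assessment: extract region pixels, draw the
#' luminance-matched per-class samples, compute the Mahalanobis
#' color-separation distance, and run the SVM diagnosis test on a
#' train/test split of the same samples. The sampling and split seeds are
#' derived deterministically from `seed` and the image's lesion id and
#' modality, so a study run is exactly replayable image by image.
#'
#' @param labeled A `labeled_image` (from [load_labeled_image()] or
#'   [generate_lesion_image()]).
#' @param config A [pipeline_config()].
#' @param seed Integer study-level seed.
#' @return A one-row tibble: `lesion_id`, `modality`, `n_sampled` (total
#'   pixels sampled), `mahalanobis_distance`, `regularized`, `n_train`,
#'   `n_test`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `ppv`, `f1`.
#' @export
analyze_image <- function(labeled, config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(labeled, "labeled_image"),
            inherits(config, "pipeline_config"))
  weights <- luma_weights(config$luma)
  pixels <- region_pixels(labeled, boundary_erode = config$boundary_erode)
  samples <- luminance_matched_sample(
    pixels, n_per_class = config$n_per_class, n_bins = config$n_bins,
    seed = derive_seed(seed, "sample", labeled$lesion_id, labeled$modality),
    weights = weights)
  sep <- color_separation(samples, pooling = config$pooling)
  diag <- svm_diagnosis(
    samples, n_train_per_class = config$n_train_per_class,
    seed = derive_seed(seed, "split", labeled$lesion_id, labeled$modality),
    params = config$svm)
  dplyr::bind_cols(
    tibble(lesion_id = labeled$lesion_id, modality = labeled$modality,
           n_sampled = nrow(samples)),
    sep[, c("mahalanobis_distance", "regularized")],
    diag
  )
}

#' Run the full pipeline over a study
#'
#' Applies [analyze_image()] to every image of a study and returns the
#' per-image records table that [aggregate_study()] summarizes.
#'
#' @param study Either the tibble returned by [generate_study()] (with a
#'   `labeled` list-column) or a plain list of `labeled_image` objects.
#' @param config A [pipeline_config()].
#' @param seed Study-level seed for sampling and splits.
#' @param verbose Log one line per image (lesion, modality, derived seeds).
#' @return A tibble with one row per image (see [analyze_image()]).
#' @export
run_study <- function(study, config = pipeline_config(), seed = 1L,
                      verbose = FALSE) {
  images <- if (is.data.frame(study)) study$labeled else study
  records <- purrr::map(images, function(labeled) {
    if (verbose) {
      message(sprintf(
        "analyze %s/%s (sample seed %d, split seed %d)",
        labeled$lesion_id, labeled$modality,
        derive_seed(seed, "sample", labeled$lesion_id, labeled$modality),
        derive_seed(seed, "split", labeled$lesion_id, labeled$modality)))
    }
    analyze_image(labeled, config = config, seed = seed)
  })
  dplyr::bind_rows(records)
}

#' Run the pipeline from a manifest of image files
#'
#' Loads every image/mask pair listed in a manifest CSV (the format written
#' by [write_study()]) and runs the per-image pipeline on each.
#'
#' @param manifest_path Path to the manifest CSV.
#' @inheritParams run_study
#' @return A per-image records tibble.
#' @export
run_study_files <- function(manifest_path, config = pipeline_config(),
                            seed = 1L, verbose = FALSE) {
  manifest <- read_manifest(manifest_path)
  images <- purrr::pmap(
    manifest[, c("lesion_id", "modality", "image", "mask")],
    function(lesion_id, modality, image, mask) {
      load_labeled_image(image, mask, lesion_id, modality)
    })
  run_study(images, config = config, seed = seed, verbose = verbose)
}
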