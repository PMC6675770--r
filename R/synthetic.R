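#' Specification of one synthetic lesion image
#'
#' Bundles everything needed to render one image/mask pair: the two
#' ground-truth region color models, the raster size, the mask geometry (a
#' star-convex blob: an ellipse whose radius is perturbed by a radial
#' sinusoid), an optional radial luminance gradient, and a seed. The cancer
#' and non-cancer regions must each contain at least 2000 pixels so that the
#' standard per-class sample size is always feasible.
#'
#' @param lesion_id Character id of the lesion.
#' @param modality One of `"WL"`, `"Indigo"`, `"AIM"`.
#' @param cancer_model,noncancer_model [region_color_model()] objects.
#' @param image_size Integer `(height, width)`, each at least 64.
#' @param mask_center Blob center `(row, col)`; defaults to the image center.
#' @param mask_radii Ellipse radii `(row, col)` in pixels; default 28% of the
#'   image size.
#' @param mask_irregularity Relative amplitude of the sinusoidal boundary
#'   perturbation (0 = smooth ellipse).
#' @param mask_lobes Integer number of sinusoid periods around the boundary.
#' @param mask_phase Phase of the boundary sinusoid in radians.
#' @param luminance_gradient_amplitude Peak additive brightness (intensity
#'   units) of a radial gradient applied equally to all channels, brightest
#'   at the image center; 0 disables it.
#' @param seed Integer seed; identical specs render bit-identical rasters.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(lesion_id, modality, cancer_model, noncancer_model,
                        image_size = c(160, 160),
                        mask_center = NULL,
                        mask_radii = NULL,
                        mask_irregularity = 0.15,
                        mask_lobes = 5,
                        mask_phase = 0,
                        luminance_gradient_amplitude = 0,
                        seed = 1L) {
  stopifnot(inherits(cancer_model, "region_color_model"),
            inherits(noncancer_model, "region_color_model"))
  image_size <- vapply(image_size, stopifnot_scalar_count,
                       integer(1), name = "image_size", min = 64)
  if (length(image_size) != 2) {
    abort("`image_size` must be (height, width).",
          class = "chromsep_config_error")
  }
  if (is.null(mask_center)) mask_center <- (image_size + 1) / 2
  if (is.null(mask_radii)) mask_radii <- 0.28 * image_size
  if (luminance_gradient_amplitude < 0) {
    abort("`luminance_gradient_amplitude` must be >= 0.",
          class = "chromsep_config_error")
  }
  structure(
    list(lesion_id = as.character(lesion_id),
         modality = match_modality(modality),
         cancer_model = cancer_model,
         noncancer_model = noncancer_model,
         image_size = image_size,
         mask_center = as.numeric(mask_center),
         mask_radii = as.numeric(mask_radii),
         mask_irregularity = mask_irregularity,
         mask_lobes = as.integer(mask_lobes),
         mask_phase = mask_phase,
         luminance_gradient_amplitude = luminance_gradient_amplitude,
         seed = as.integer(seed)),
    class = "lesion_spec"
  )
}

# Rasterize the star-convex blob: a pixel is inside when its elliptical
# radius is below 1 + irregularity * sin(lobes * angle + phase).
blob_mask <- function(image_size, center, radii, irregularity, lobes, phase) {
  h <- image_size[1]; w <- image_size[2]
  dr <- (row(matrix(0, h, w)) - center[1]) / radii[1]
  dc <- (col(matrix(0, h, w)) - center[2]) / radii[2]
  theta <- atan2(dc, dr)
  r <- sqrt(dr^2 + dc^2)
  boundary <- 1 + irregularity * sin(lobes * theta + phase)
  mask <- matrix(0L, h, w)
  mask[r <= boundary] <- 1L
  mask
}

#' Render one synthetic image/mask pair
#'
#' Pixels inside the mask are drawn i.i.d. from the cancer color model,
#' pixels outside from the non-cancer model. An optional radial luminance
#' gradient is then added to all three channels, after which intensities are
#' clipped to \[0, 255\] and rounded to integers (8-bit quantization).
#' Rendering is bit-reproducible under the spec's seed.
#'
#' @param spec A [lesion_spec()].
#' @return A list with `image` (H x W x 3 integer array), `mask` (H x W 0/1
#'   integer matrix) and the `spec`, of class `labeled_image` so it feeds
#'   directly into the analysis pipeline.
#' @export
#' @examples
#' cm <- region_color_model(c(200, 40, 40), 0)
#' nm <- region_color_model(c(40, 40, 200), 0)
#' img <- generate_lesion_image(lesion_spec("L1", "WL", cm, nm))
#' table(img$mask)
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  mask <- blob_mask(spec$image_size, spec$mask_center, spec$mask_radii,
                    spec$mask_irregularity, spec$mask_lobes, spec$mask_phase)
  n_in <- sum(mask == 1L); n_out <- sum(mask == 0L)
  if (n_in < 2000) {
    abort(sprintf(
      "Cancer region has %d pixels; at least 2000 are required for sampling.",
      n_in), class = "chromsep_infeasible_spec_error")
  }
  if (n_out < 2000) {
    abort(sprintf(
      "Non-cancer region has %d pixels; at least 2000 are required for sampling.",
      n_out), class = "chromsep_infeasible_spec_error")
  }

  img <- with_seed(spec$seed, {
    arr <- array(0, dim = c(h, w, 3))
    draw <- function(n, model) {
      if (all(model$cov_rgb == 0)) {
        matrix(model$mean_rgb, n, 3, byrow = TRUE)
      } else {
        MASS::mvrnorm(n, mu = model$mean_rgb, Sigma = model$cov_rgb)
      }
    }
    px_in <- draw(n_in, spec$cancer_model)
    px_out <- draw(n_out, spec$noncancer_model)
    for (k in 1:3) {
      plane <- matrix(0, h, w)
      plane[mask == 1L] <- px_in[, k]
      plane[mask == 0L] <- px_out[, k]
      arr[, , k] <- plane
    }
    arr
  })

  if (spec$luminance_gradient_amplitude > 0) {
    ctr <- (spec$image_size + 1) / 2
    d <- sqrt(outer((seq_len(h) - ctr[1])^2, (seq_len(w) - ctr[2])^2, "+"))
    gradient <- spec$luminance_gradient_amplitude * (1 - d / max(d))
    for (k in 1:3) img[, , k] <- img[, , k] + gradient
  }

  storage.mode(img) <- "double"
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  new_labeled_image(img, mask, spec$lesion_id, spec$modality, spec = spec)
}

#' Specification of a full synthetic study
#'
#' Describes a paired study design: `n_lesions` lesions, each imaged under
#' all three modalities (white light, indigo carmine, acetic acid + indigo
#' carmine). Each modality multiplies a common chromatic class-mean
#' difference by its separation scale, so the ground-truth Mahalanobis
#' separation of lesion `l` under modality `m` is
#' `separation_scale[m] * lesion_factor[l]`. Per-lesion variation emulates
#' patient-to-patient differences: a shared baseline color shift (both
#' regions move together) and a log-normal lesion contrast factor (shared
#' across the three modalities of a lesion, so the modality ordering is
#' preserved within every lesion).
#'
#' The default separation scales (WL 1.5, Indigo 1.3, AIM 2.5) place the
#' three modalities at the relative color contrasts reported for early
#' gastric cancer imaging, with acetic acid + indigo carmine the most
#' separable.
#'
#' @param n_lesions Number of lesions (default 18).
#' @param separation_scale Named positive vector of per-modality scales.
#' @param base_noncancer_mean Baseline mucosa RGB mean.
#' @param sigma Per-channel pixel noise standard deviation (intensity units);
#'   region covariances are `sigma^2 * I`.
#' @param chromatic_direction Direction of the cancer-vs-background mean
#'   difference in RGB space. The default is orthogonal to the BT.601 luma
#'   weights, so the simulated class difference is purely chromatic (no
#'   brightness cue) — the confound the luminance-matched sampling stage is
#'   designed to remove.
#' @param mean_shift_sd SD (intensity units) of the per-lesion baseline shift.
#' @param lesion_scale_sdlog SD of the log-normal per-lesion contrast factor.
#' @param image_size,luminance_gradient_amplitude Passed to every
#'   [lesion_spec()].
#' @param seed Master seed; all per-lesion/per-modality seeds derive from it.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_lesions = 18,
                       separation_scale = c(WL = 1.5, Indigo = 1.3, AIM = 2.5),
                       base_noncancer_mean = c(150, 95, 85),
                       sigma = 12,
                       chromatic_direction = c(0.587, -0.299, 0),
                       mean_shift_sd = 8,
                       lesion_scale_sdlog = 0.15,
                       image_size = c(160, 160),
                       luminance_gradient_amplitude = 0,
                       seed = 1L) {
  n_lesions <- stopifnot_scalar_count(n_lesions, "n_lesions")
  if (!all(MODALITIES %in% names(separation_scale))) {
    abort("`separation_scale` must name all of WL, Indigo, AIM.",
          class = "chromsep_config_error")
  }
  if (any(!is.finite(separation_scale)) || any(separation_scale <= 0)) {
    abort("`separation_scale` values must be positive.",
          class = "chromsep_config_error")
  }
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "chromsep_config_error")
  }
  structure(
    list(n_lesions = n_lesions,
         separation_scale = separation_scale[MODALITIES],
         base_noncancer_mean = as.numeric(base_noncancer_mean),
         sigma = sigma,
         chromatic_direction = as.numeric(chromatic_direction) /
           sqrt(sum(chromatic_direction^2)),
         mean_shift_sd = mean_shift_sd,
         lesion_scale_sdlog = lesion_scale_sdlog,
         image_size = image_size,
         luminance_gradient_amplitude = luminance_gradient_amplitude,
         seed = as.integer(seed)),
    class = "study_spec"
  )
}

#' Generate a complete synthetic study
#'
#' Renders `n_lesions x 3` image/mask pairs (every lesion under all three
#' modalities) from a [study_spec()]. Per-lesion color variation and all
#' pixel noise are derived deterministically from the master seed.
#'
#' @param spec A [study_spec()].
#' @return A tibble with one row per image: `lesion_id`, `modality`,
#'   `true_separation` (closed-form ground-truth distance) and a `labeled`
#'   list-column of `labeled_image` objects ready for [analyze_image()].
#' @export
#' @examples
#' study <- generate_study(study_spec(n_lesions = 1))
#' study[, c("lesion_id", "modality", "true_separation")]
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  cov_rgb <- diag(spec$sigma^2, 3)
  u <- spec$chromatic_direction

  rows <- purrr::map(seq_len(spec$n_lesions), function(l) {
    lesion_id <- sprintf("L%02d", l)
    lseed <- derive_seed(spec$seed, "lesion", l)
    pert <- with_seed(lseed, list(
      shift = rnorm(3, 0, spec$mean_shift_sd),
      factor = exp(rnorm(1, 0, spec$lesion_scale_sdlog)),
      phase = runif(1, 0, 2 * pi)
    ))
    base_mean <- pmin(pmax(spec$base_noncancer_mean + pert$shift, 20), 235)

    purrr::map(MODALITIES, function(m) {
      # Isotropic covariance: a Euclidean step of sigma * D along any unit
      # direction yields Mahalanobis separation exactly D.
      d_true <- spec$separation_scale[[m]] * pert$factor
      cancer_mean <- base_mean + d_true * spec$sigma * u
      cancer_mean <- pmin(pmax(cancer_mean, 0), 255)
      lspec <- lesion_spec(
        lesion_id, m,
        cancer_model = region_color_model(cancer_mean, cov_rgb),
        noncancer_model = region_color_model(base_mean, cov_rgb),
        image_size = spec$image_size,
        mask_phase = pert$phase,
        luminance_gradient_amplitude = spec$luminance_gradient_amplitude,
        seed = derive_seed(spec$seed, "render", l, m)
      )
      tibble(
        lesion_id = lesion_id,
        modality = m,
        true_separation = closed_form_separation(lspec$cancer_model,
                                                 lspec$noncancer_model),
        labeled = list(generate_lesion_image(lspec))
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write a generated study to disk as PNG images plus a manifest
#'
#' Images are written as 8-bit RGB PNG, masks as single-channel 8-bit PNG
#' (0 = non-cancer, 255 = cancer). The manifest CSV lists one row per image
#' with the file paths and the ground-truth closed-form separation, and is
#' the input format of [run_study_files()].
#'
#' @param study Output of [generate_study()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::pmap(study, function(lesion_id, modality,
                                          true_separation, labeled) {
    stem <- sprintf("%s_%s", lesion_id, modality)
    image_path <- file.path(out_dir, paste0(stem, ".png"))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    write_labeled_image(labeled, image_path, mask_path)
    tibble(lesion_id = lesion_id, modality = modality,
           image = basename(image_path), mask = basename(mask_path),
           true_separation = true_separation)
  })
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
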