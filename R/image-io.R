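new_labeled_image <- function(image, mask, lesion_id, modality, spec = NULL) {
  structure(
    list(image = image, mask = mask,
         lesion_id = as.character(lesion_id),
         modality = match_modality(modality),
         spec = spec),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_image> %s / %s, %d x %d px (%d cancer, %d non-cancer)\n",
              x$lesion_id, x$modality, d[1], d[2],
              sum(x$mask == 1L), sum(x$mask == 0L)))
  invisible(x)
}

#' Load an endoscopic image and its tumor mask
#'
#' Reads an 8-bit RGB image (PNG or TIFF) and a PNG mask marking the
#' cancerous area, validates their geometry, and returns them as one labeled
#' image. Any nonzero mask value is treated as cancer; RGBA alpha channels
#' are dropped; 16-bit rasters are rejected because the pipeline's color
#' statistics are defined on the 8-bit scale.
#'
#' @param image_path Path to an RGB PNG or TIFF image.
#' @param mask_path Path to a mask PNG of the same height and width.
#' @param lesion_id Lesion identifier carried through the pipeline.
#' @param modality One of `"WL"`, `"Indigo"`, `"AIM"`.
#' @return A `labeled_image`: `image` (H x W x 3 integer array, 0-255),
#'   `mask` (H x W 0/1 integer matrix), `lesion_id`, `modality`.
#' @export
load_labeled_image <- function(image_path, mask_path, lesion_id, modality) {
  img <- read_raster_8bit(image_path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    abort(sprintf("`%s` is not an RGB image.", image_path),
          class = "chromsep_format_error")
  }
  img <- img[, , 1:3, drop = FALSE] # drop alpha if present

  msk <- read_raster_8bit(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  if (!all(dim(msk) == dim(img)[1:2])) {
    abort(sprintf(
      "Image and mask dimensions differ: image is %d x %d, mask is %d x %d.",
      dim(img)[1], dim(img)[2], dim(msk)[1], dim(msk)[2]),
      class = "chromsep_geometry_error")
  }
  mask <- matrix(0L, nrow(msk), ncol(msk))
  mask[msk != 0] <- 1L
  if (all(mask == 1L) || all(mask == 0L)) {
    abort("Mask marks the whole image as one region; both regions must be non-empty.",
          class = "chromsep_empty_region_error")
  }
  new_labeled_image(img, mask, lesion_id, modality)
}

# Read a PNG or TIFF raster, insisting on 8-bit depth, and return integer
# intensities on the 0-255 scale.
read_raster_8bit <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "chromsep_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8)) {
      abort(sprintf("`%s` is %d-bit; only 8-bit images are supported.",
                    path, max(bits)), class = "chromsep_format_error")
    }
  } else {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      abort(sprintf("`%s` is %d-bit; only 8-bit images are supported.",
                    path, info$bit.depth), class = "chromsep_format_error")
    }
  }
  out <- round(raw * 255)
  storage.mode(out) <- "integer"
  attributes(out) <- list(dim = dim(raw))
  out
}

#' Write a labeled image to disk
#'
#' The image goes out as 8-bit RGB PNG and the mask as single-channel 8-bit
#' PNG with 0 = non-cancer and 255 = cancer, the canonical on-disk form that
#' [load_labeled_image()] round-trips losslessly.
#'
#' @param labeled A `labeled_image`.
#' @param image_path,mask_path Output PNG paths.
#' @return Invisibly, `labeled`.
#' @export
write_labeled_image <- function(labeled, image_path, mask_path) {
  stopifnot(inherits(labeled, "labeled_image"))
  png::writePNG(labeled$image / 255, image_path)
  png::writePNG(labeled$mask * 1.0, mask_path)
  invisible(labeled)
}

#' Read a study manifest CSV
#'
#' The manifest format written by [write_study()]: one row per image with
#' `lesion_id`, `modality`, `image` and `mask` paths (relative to the
#' manifest's directory) and optionally `true_separation`.
#'
#' @param path Manifest CSV path.
#' @return A tibble with absolute `image` and `mask` paths.
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("lesion_id", "modality", "image", "mask")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(sprintf("Manifest is missing columns: %s.",
                  paste(missing, collapse = ", ")),
          class = "chromsep_format_error")
  }
  base <- dirname(path)
  manifest$image <- ifelse(grepl("^/", manifest$image), manifest$image,
                           file.path(base, manifest$image))
  manifest$mask <- ifelse(grepl("^/", manifest$mask), manifest$mask,
                          file.path(base, manifest$mask))
  manifest
}

#' Extract per-region pixels as a tidy table
#'
#' Returns every pixel of the image with its 0-based `(row, col)` coordinate,
#' RGB value, and region label, in deterministic row-major order (all of row
#' 0 left to right, then row 1, ...). The cancer and non-cancer extractions
#' partition the image exactly.
#'
#' @param labeled A `labeled_image`.
#' @param region `"both"` (default), `"cancer"` or `"noncancer"`.
#' @param boundary_erode Erode the cancer mask by this many pixels (4-neighbour
#'   binary erosion) before labeling, excluding uncertain pixels at the tumor
#'   boundary from *both* regions. Default 0 (no erosion; eroded pixels are
#'   dropped, not relabeled).
#' @return A tibble with columns `label` (`"cancer"`/`"noncancer"`), `row`,
#'   `col`, `R`, `G`, `B`.
#' @export
#' @examples
#' cm <- region_color_model(c(200, 40, 40), 0)
#' nm <- region_color_model(c(40, 40, 200), 0)
#' img <- generate_lesion_image(lesion_spec("L1", "WL", cm, nm))
#' dplyr::count(region_pixels(img), label)
region_pixels <- function(labeled, region = c("both", "cancer", "noncancer"),
                          boundary_erode = 0) {
  stopifnot(inherits(labeled, "labeled_image"))
  region <- match.arg(region)
  mask <- labeled$mask
  keep <- matrix(TRUE, nrow(mask), ncol(mask))
  if (boundary_erode > 0) {
    eroded <- erode_mask(mask, boundary_erode)
    keep <- !(mask == 1L & eroded == 0L) # drop boundary band entirely
    mask <- eroded
  }
  h <- nrow(mask); w <- ncol(mask)
  # walk pixels in row-major order (row 0 left to right, then row 1, ...)
  rows0 <- rep(seq_len(h) - 1L, each = w)
  cols0 <- rep(seq_len(w) - 1L, times = h)
  lin <- rows0 + 1L + cols0 * h # column-major linear index of row-major walk
  sel <- as.vector(keep)[lin]
  lin <- lin[sel]
  px <- tibble(
    label = ifelse(as.vector(mask)[lin] == 1L, "cancer", "noncancer"),
    row = rows0[sel], col = cols0[sel],
    R = as.numeric(labeled$image[, , 1][lin]),
    G = as.numeric(labeled$image[, , 2][lin]),
    B = as.numeric(labeled$image[, , 3][lin])
  )
  if (region != "both") {
    px <- px[px$label == region, ]
    if (nrow(px) == 0) {
      abort(sprintf("Region '%s' contains no pixels.", region),
            class = "chromsep_empty_region_error")
    }
  }
  px
}

#' @rdname region_pixels
#' @export
extract_region_pixels <- function(labeled, region, boundary_erode = 0) {
  region_pixels(labeled, region = region, boundary_erode = boundary_erode)
}

# Iterated 4-neighbour binary erosion of a 0/1 mask.
erode_mask <- function(mask, k) {
  for (i in seq_len(k)) {
    up <- rbind(mask[-1, , drop = FALSE], 0L)
    down <- rbind(0L, mask[-nrow(mask), , drop = FALSE])
    left <- cbind(mask[, -1, drop = FALSE], 0L)
    right <- cbind(0L, mask[, -ncol(mask), drop = FALSE])
    mask <- mask * up * down * left * right
  }
  mask
}
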