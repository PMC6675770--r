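test_that("write then load round-trips rasters losslessly", {
  img <- quick_labeled_image(seed = 4)
  d <- withr::local_tempdir()
  write_labeled_image(img, file.path(d, "a.png"), file.path(d, "a_mask.png"))
  back <- load_labeled_image(file.path(d, "a.png"), file.path(d, "a_mask.png"),
                             "Lq", "WL")
  expect_identical(back$image, img$image)
  expect_identical(back$mask, img$mask)
})

test_that("geometry and mask validity are enforced on load", {
  d <- withr::local_tempdir()
  png::writePNG(array(0.5, c(64, 64, 3)), file.path(d, "img.png"))
  png::writePNG(matrix(c(0, 1), 32, 32), file.path(d, "small_mask.png"))
  expect_error(
    load_labeled_image(file.path(d, "img.png"), file.path(d, "small_mask.png"),
                       "L1", "WL"),
    regexp = "64 x 64.*32 x 32", class = "chromsep_geometry_error")

  png::writePNG(matrix(0, 64, 64), file.path(d, "zero_mask.png"))
  expect_error(
    load_labeled_image(file.path(d, "img.png"), file.path(d, "zero_mask.png"),
                       "L1", "WL"),
    class = "chromsep_empty_region_error")

  png::writePNG(matrix(0.5, 64, 64), file.path(d, "gray.png"))
  expect_error(
    load_labeled_image(file.path(d, "gray.png"), file.path(d, "zero_mask.png"),
                       "L1", "WL"),
    class = "chromsep_format_error")

  expect_error(
    load_labeled_image(file.path(d, "nope.png"), file.path(d, "zero_mask.png"),
                       "L1", "WL"),
    class = "chromsep_io_error")
})

test_that("any nonzero mask value is read as cancer", {
  d <- withr::local_tempdir()
  png::writePNG(array(0.5, c(64, 64, 3)), file.path(d, "img.png"))
  m <- matrix(0, 64, 64)
  m[10:20, 10:20] <- 0.5 # 127, not the canonical 255
  png::writePNG(m, file.path(d, "mask.png"))
  got <- load_labeled_image(file.path(d, "img.png"), file.path(d, "mask.png"),
                            "L1", "WL")
  expect_identical(sum(got$mask), 121L)
  expect_setequal(unique(as.vector(got$mask)), c(0L, 1L))
})

test_that("16-bit rasters are rejected, RGBA alpha is dropped", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(array(0.5, c(64, 64, 3)), file.path(d, "deep.tif"),
                  bits.per.sample = 16)
  png::writePNG(matrix(c(0, 1), 64, 64), file.path(d, "mask.png"))
  expect_error(
    load_labeled_image(file.path(d, "deep.tif"), file.path(d, "mask.png"),
                       "L1", "WL"),
    regexp = "16-bit", class = "chromsep_format_error")

  png::writePNG(array(0.25, c(64, 64, 4)), file.path(d, "rgba.png"))
  got <- load_labeled_image(file.path(d, "rgba.png"), file.path(d, "mask.png"),
                            "L1", "WL")
  expect_identical(dim(got$image), c(64L, 64L, 3L))

  # 8-bit TIFF is accepted
  tiff::writeTIFF(array(102 / 255, c(64, 64, 3)), file.path(d, "flat.tif"),
                  bits.per.sample = 8)
  got8 <- load_labeled_image(file.path(d, "flat.tif"), file.path(d, "mask.png"),
                             "L1", "WL")
  expect_true(all(got8$image == 102L))
})

test_that("region extraction partitions the image in deterministic row-major order", {
  img <- quick_labeled_image(seed = 9)
  px <- region_pixels(img)
  h <- dim(img$image)[1]; w <- dim(img$image)[2]
  expect_identical(nrow(px), h * w)

  cancer <- extract_region_pixels(img, "cancer")
  noncancer <- extract_region_pixels(img, "noncancer")
  expect_identical(nrow(cancer) + nrow(noncancer), h * w)
  key <- function(df) paste(df$row, df$col)
  expect_length(intersect(key(cancer), key(noncancer)), 0)

  # row-major: rows non-decreasing, columns increasing within a row
  expect_true(all(diff(px$row) >= 0))
  expect_true(all(diff(px$col[px$row == px$row[1]]) == 1))
  # 0-based coordinates
  expect_identical(range(px$row), c(0L, h - 1L))

  # repeated extraction yields the identical sequence
  expect_identical(px, region_pixels(img))

  # counts match the mask
  expect_identical(nrow(cancer), sum(img$mask == 1L))
})

test_that("boundary erosion shrinks the cancer region and drops the band", {
  img <- quick_labeled_image(seed = 2)
  full <- region_pixels(img)
  eroded <- region_pixels(img, boundary_erode = 2)
  n_cancer_full <- sum(full$label == "cancer")
  n_cancer_eroded <- sum(eroded$label == "cancer")
  expect_lt(n_cancer_eroded, n_cancer_full)
  # the band is excluded entirely, not relabeled
  expect_identical(sum(eroded$label == "noncancer"),
                   sum(full$label == "noncancer"))
  expect_identical(nrow(eroded), nrow(full) - (n_cancer_full - n_cancer_eroded))
})

test_that("manifest round-trip resolves paths and feeds the loader", {
  study <- generate_study(small_study_spec(n_lesions = 1, seed = 6))
  d <- withr::local_tempdir()
  write_study(study, d)
  manifest <- read_manifest(file.path(d, "manifest.csv"))
  expect_identical(nrow(manifest), 3L)
  expect_true(all(file.exists(manifest$image)))
  expect_true(all(file.exists(manifest$mask)))
  back <- load_labeled_image(manifest$image[1], manifest$mask[1],
                             manifest$lesion_id[1], manifest$modality[1])
  expect_identical(back$image, study$labeled[[1]]$image)
  expect_identical(back$mask, study$labeled[[1]]$mask)
})
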