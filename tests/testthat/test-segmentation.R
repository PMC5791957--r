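# Mean shift, distance map, k-means region classification and the composed
# segmentation pipeline.

test_that("mean shift leaves flat and well-separated regions unchanged", {
  flat <- array(120, dim = c(32, 32, 3))
  out <- mean_shift_filter(flat, 4, 10)
  expect_equal(out, flat, tolerance = 1e-6)

  # two half-planes far apart in colour: each half is preserved
  half <- array(60, dim = c(32, 32, 3))
  half[, 17:32, 1] <- 230; half[, 17:32, 2] <- 40; half[, 17:32, 3] <- 40
  outh <- mean_shift_filter(half, 4, 10)
  expect_lt(max(abs(outh[, 1:12, ] - half[, 1:12, ])), 2)
  expect_lt(max(abs(outh[, 21:32, ] - half[, 21:32, ])), 2)
})

test_that("mean shift reduces intra-ROI colour variance on noisy specimens", {
  sp <- fixture_specimen(t = 10, seed = 51, config = small_config(noise_sd = 8))
  img <- sp$images$A
  roi <- as.vector(sp$roi_truth$A)
  filt <- mean_shift_filter(img, 4, 12)
  v_in <- sum(apply(array_to_pixmat_local(img)[roi, ], 2, var))
  v_out <- sum(apply(array_to_pixmat_local(filt)[roi, ], 2, var))
  expect_lt(v_out, v_in)
})

test_that("mean shift rejects invalid inputs", {
  expect_error(mean_shift_filter(array(1, c(4, 4, 3)), 0, 5),
               class = "gummix_error_parameter")
  expect_error(mean_shift_filter(matrix(1, 4, 4), 4, 5),
               class = "gummix_error_input")
})

test_that("distance map is 0 at centre, 1 at corners, and hand-exact on 3x3", {
  d <- distance_map(c(3, 3))
  # centre 0; corners sqrt(2)/sqrt(2) = 1; edges 1/sqrt(2)
  expected <- matrix(c(1, 1 / sqrt(2), 1,
                       1 / sqrt(2), 0, 1 / sqrt(2),
                       1, 1 / sqrt(2), 1), nrow = 3)
  expect_equal(d, expected, tolerance = 1e-12)
  big <- distance_map(c(65, 65))
  expect_equal(big[33, 33], 0)
  expect_equal(big[1, 1], 1)
  expect_equal(max(big), 1)
})

test_that("a flat disk on a flat background segments exactly", {
  dk <- disk_image()
  m <- segment(dk$image)
  expect_equal(mask_jaccard(m$mask, dk$mask), 1)
  expect_equal(m$roi_pixel_count, sum(dk$mask))
})

test_that("segmentation recovers generator ground truth (Jaccard >= 0.95)", {
  js <- c()
  for (seed in 61:65) for (t in c(0, 10, 20)) {
    sp <- fixture_specimen(t = t, seed = seed)
    for (side in c("A", "B")) {
      m <- segment(sp$images[[side]])
      js <- c(js, mask_jaccard(m$mask, sp$roi_truth[[side]]))
    }
  }
  expect_gte(min(js), 0.95)
})

test_that("segmentation is deterministic and areas match truth within 10%", {
  sp <- fixture_specimen(t = 15, seed = 71)
  m1 <- segment(sp$images$A)
  m2 <- segment(sp$images$A)
  expect_identical(m1$mask, m2$mask)
  truth_area <- sum(sp$roi_truth$A)
  expect_lt(abs(m1$roi_pixel_count - truth_area) / truth_area, 0.10)
  # partition: exactly the ROI pixels are TRUE, everything else background
  expect_identical(sort(unique(as.vector(m1$mask))), c(FALSE, TRUE))
  # final ROI is one connected component (holes filled)
  expect_equal(max(EBImage::bwlabel(m1$mask * 1)), 1)
})

test_that("degenerate and background-only images fail loudly", {
  expect_error(segment(array(100, dim = c(64, 64, 3))),
               class = "gummix_error_segmentation")
  bgonly <- array(60, dim = c(64, 64, 3))
  bgonly <- bgonly + array(rnorm(length(bgonly), sd = 3), dim = dim(bgonly))
  expect_error(segment(bgonly), class = "gummix_error_segmentation")
})

test_that("the full MS+DM+KM pipeline beats plain k-means on average", {
  j_full <- c(); j_km <- c()
  for (seed in 81:88) {
    sp <- fixture_specimen(t = c(0, 5, 10, 15, 20)[(seed %% 5) + 1], seed = seed)
    j_full <- c(j_full, mask_jaccard(
      segment(sp$images$A, segment_params(variant = "ms_dm_km"))$mask,
      sp$roi_truth$A))
    m_km <- tryCatch(segment(sp$images$A, segment_params(variant = "km")),
                     gummix_error = function(e) NULL)
    j_km <- c(j_km, if (is.null(m_km)) 0 else
      mask_jaccard(m_km$mask, sp$roi_truth$A))
  }
  expect_gte(mean(j_full), mean(j_km))
})

test_that("a pure-red unmixed face yields an ROI in the red hue band", {
  sp <- fixture_specimen(t = 0, seed = 91)
  m <- segment(sp$images$A)
  px <- array_to_pixmat_local(sp$images$A)[as.vector(m$mask), ]
  h <- rgb_to_hsi(px)[, "H"]
  h <- h[!is.na(h)]
  # red band: within 0.5 rad of 0 (mod 2*pi)
  expect_gt(mean(pmin(h, 2 * pi - h) < 0.5), 0.95)
})

test_that("masks serialize with a JSON sidecar", {
  dir <- withr::local_tempdir()
  dk <- disk_image()
  m <- segment(dk$image)
  p <- file.path(dir, "mask.png")
  write_mask(m, p)
  expect_true(file.exists(p))
  side <- jsonlite::read_json(file.path(dir, "mask.json"))
  expect_equal(side$roi_pixel_count, m$roi_pixel_count)
  expect_equal(dim(png::readPNG(p)), c(64, 64))
})
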