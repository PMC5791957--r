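# Generator contracts: mixing model, determinism, mask sanity, cohort sizes.

test_that("zero cycles gives pure unmixed faces and mixing_level 0", {
  sp <- fixture_specimen(t = 0, seed = 21)
  expect_equal(sp$mixing_level, 0)
  px_a <- pool_roi_pixels(sp, list(A = sp$roi_truth$A, B = sp$roi_truth$B & FALSE))
  px_b <- pool_roi_pixels(sp, list(A = sp$roi_truth$A & FALSE, B = sp$roi_truth$B))
  # side A red-dominant (R much larger than G), side B near-white
  expect_gt(mean(px_a[, 1]) - mean(px_a[, 2]), 100)
  expect_lt(mean(px_b[, 1]) - mean(px_b[, 2]), 20)
  # zero interleaving: within-side red/white class is uniform
  expect_lt(sd(px_a[, 2]), 3 * small_config()$noise_sd)
})

test_that("saturating mixing model balances the two phases at large t", {
  sp <- fixture_specimen(t = 10000, rate = 0.1, seed = 22)
  expect_lt(abs(sp$mixing_level - 1), 1e-4)
  for (side in c("A", "B")) {
    px <- array_to_pixmat_local(sp$images[[side]])[as.vector(sp$roi_truth[[side]]), ]
    red <- px[, 1] - px[, 2] > 80  # red-leaning vs white-leaning pixels
    frac <- mean(red)
    expect_lt(abs(frac - 0.5), 0.10)
  }
})

test_that("generation is bit-identical for identical (t, rate, seed)", {
  a <- fixture_specimen(t = 10, seed = 23)
  b <- fixture_specimen(t = 10, seed = 23)
  expect_identical(a, b)
  c <- fixture_specimen(t = 10, seed = 24)
  expect_false(identical(a$images$A, c$images$A))
})

test_that("ground-truth masks are connected, central, and sane in area", {
  for (seed in c(31, 32, 33, 34, 35)) {
    sp <- fixture_specimen(t = 5, seed = seed)
    m <- sp$roi_truth$A
    frac <- mean(m)
    expect_gt(frac, 0.10)
    expect_lt(frac, 0.70)
    # boundary untouched
    expect_false(any(m[1, ]) || any(m[nrow(m), ]) ||
                   any(m[, 1]) || any(m[, ncol(m)]))
    # single connected component
    lab <- EBImage::bwlabel(m * 1)
    expect_equal(max(lab), 1)
  }
})

test_that("expected pink fraction inside the ROI increases with t", {
  cfg <- small_config()
  pink_frac <- function(sp, side) {
    px <- array_to_pixmat_local(sp$images[[side]])[as.vector(sp$roi_truth[[side]]), ]
    diff_rg <- px[, 1] - px[, 2]
    mean(diff_rg > 40 & diff_rg < 120)  # between the pure-phase bands
  }
  cycles <- c(0, 5, 10, 15, 20)
  means <- sapply(cycles, function(t) {
    mean(sapply(1:20, function(s) {
      sp <- generate_specimen(t, 0.08, cfg, seed = 700 + 31 * s + t)
      (pink_frac(sp, "A") + pink_frac(sp, "B")) / 2
    }))
  })
  expect_gt(cor(cycles, means, method = "spearman"), 0.9)
})

test_that("calibration set has n_subjects x cycles specimens, reproducibly", {
  cfg <- small_config(seed = 5L)
  set <- generate_calibration_set(cfg)
  expect_length(set$specimens, 4L * 5L)
  expect_equal(nrow(set$manifest), 20L)
  expect_equal(sort(unique(set$manifest$t)), c(0L, 5L, 10L, 15L, 20L))
  # one rate per subject
  expect_equal(length(unique(set$manifest$subject_rate)), 4L)
  set2 <- generate_calibration_set(cfg)
  expect_identical(set, set2)
  one <- generate_calibration_set(synthetic_config(n_subjects = 1, cycles = 0,
                                                   image_size = c(64, 64)))
  expect_length(one$specimens, 1L)
  expect_equal(one$specimens[[1]]$mixing_level, 0)
})

test_that("diagnosis cohorts pair two specimens per patient and phase", {
  cfg <- small_config()
  coh <- generate_diagnosis_cohort(n_patients = 3, T = 20, config = cfg, seed = 9)
  expect_length(coh$pre$specimens, 6L)
  expect_length(coh$post$specimens, 6L)
  expect_true(all(coh$pre$manifest$t == 20L))
  # treatment effect on the latent mixing level
  expect_gt(mean(coh$post$manifest$mixing_level),
            mean(coh$pre$manifest$mixing_level))
  # near-zero pre-treatment rate keeps pre-cohort mixing levels low
  low <- generate_diagnosis_cohort(n_patients = 4, pre_rate_mean = 1e-3,
                                   post_rate_mean = 0.06, T = 20,
                                   config = cfg, seed = 10)
  expect_true(all(low$pre$manifest$mixing_level < 0.05))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_specimen(5, 0, small_config()), class = "gummix_error_parameter")
  expect_error(generate_specimen(-1, 0.1, small_config()), class = "gummix_error_parameter")
  expect_error(synthetic_config(cycles = c(5, 10)), class = "gummix_error_parameter")
  expect_error(synthetic_config(cycles = c(0, 10, 10)), class = "gummix_error_parameter")
  expect_error(synthetic_config(image_size = c(32, 32)), class = "gummix_error_parameter")
})

test_that("write_specimen_set emits PNGs and a manifest that reload", {
  dir <- withr::local_tempdir()
  set <- generate_calibration_set(synthetic_config(n_subjects = 1,
                                                   image_size = c(64, 64)))
  man <- write_specimen_set(set, dir)
  expect_equal(nrow(man), 2L * length(set$specimens))
  expect_true(all(file.exists(man$path)))
  img <- read_image(man$path[1])
  expect_equal(dim(img), c(64L, 64L, 3L))
  # PNG round trip is lossless up to 8-bit quantization
  expect_lt(max(abs(img - round(set$specimens[[1]]$images$A))), 1)
})
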