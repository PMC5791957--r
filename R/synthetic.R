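# Synthetic two-colour chewing-gum specimens.
#
# Each specimen is a pair of scanned-wafer-like images (side A / side B) of
# an irregular elliptical bolus on a scanner-lid background. The wafer is a
# red layer stacked on a white layer; mastication interleaves the two
# phases. The mixing level after t chewing strokes follows a saturating
# exponential in t with one per-subject rate parameter:
#
#   mixing_level(t) = 1 - exp(-subject_rate * t)
#
# The red/white interleaving is a thresholded smoothed-noise patch field
# whose characteristic patch scale shrinks, and whose hue-blended (pink)
# fraction grows, monotonically with the mixing level.

# Wafer phase colours (8-bit sRGB): watermelon-red layer and a near-white
# layer. The white is slightly warm but close enough to neutral that scan
# noise dominates its hue, as on a real white gum face.
.RED_RGB <- c(200, 35, 55)
.WHITE_RGB <- c(240, 234, 226)

#' Configuration for the synthetic specimen generator
#'
#' Defaults encode the study conditions the generator emulates: 80 reference
#' subjects, five specimens per subject at 0/5/10/15/20 chewing cycles
#' (400 specimens), and a homogeneous healthy reference cohort (small
#' between-subject spread of the mixing rate).
#'
#' @param n_subjects number of reference subjects (>= 1).
#' @param cycles strictly increasing chewing-stroke counts, starting at 0.
#' @param image_size `c(width, height)` in pixels, each >= 64.
#' @param subject_rate_mean,subject_rate_sd mean and sd of the per-subject
#'   mixing rate (per chewing stroke, > 0); draws are truncated below at
#'   `subject_rate_mean / 10`.
#' @param blob_eccentricity_range range of the bolus axis ratio (>= 1).
#' @param noise_sd additive Gaussian pixel noise, 8-bit intensity units.
#' @param background_grey scanner background level, 8-bit value; the dark
#'   default emulates an open-lid flatbed scan, which also separates both
#'   wafer colours from the background.
#' @param seed master seed for dataset-level generation.
#' @return object of class `gum_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 80L,
                             cycles = c(0L, 5L, 10L, 15L, 20L),
                             image_size = c(128L, 128L),
                             subject_rate_mean = 0.04,
                             subject_rate_sd = 0.001,
                             blob_eccentricity_range = c(1, 1.6),
                             noise_sd = 5,
                             background_grey = 60,
                             seed = 1L) {
  cycles <- as.integer(cycles)
  if (length(cycles) < 1L || cycles[1] != 0L || any(diff(cycles) <= 0)) {
    stop_gummix("`cycles` must be strictly increasing and start at 0", "parameter")
  }
  if (n_subjects < 1L) stop_gummix("`n_subjects` must be >= 1", "parameter")
  if (length(image_size) != 2L || any(image_size < 64L)) {
    stop_gummix("`image_size` must be at least 64 x 64", "parameter")
  }
  if (subject_rate_mean <= 0 || subject_rate_sd <= 0) {
    stop_gummix("subject rate distribution parameters must be > 0", "parameter")
  }
  if (length(blob_eccentricity_range) != 2L || any(blob_eccentricity_range < 1)) {
    stop_gummix("`blob_eccentricity_range` must be >= 1", "parameter")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), cycles = cycles,
    image_size = as.integer(image_size),
    subject_rate_mean = subject_rate_mean, subject_rate_sd = subject_rate_sd,
    blob_eccentricity_range = blob_eccentricity_range,
    noise_sd = noise_sd, background_grey = background_grey,
    seed = as.integer(seed)
  ), class = "gum_config")
}

# Irregular ellipse mask: low-order Fourier perturbation of an ellipse
# radius, jittered centre. Star-shaped, hence one connected component; the
# axes are capped so the boundary never reaches the frame border.
make_blob_mask <- function(w, h, ecc_range) {
  cx <- w / 2 + runif(1, -0.03, 0.03) * w
  cy <- h / 2 + runif(1, -0.03, 0.03) * h
  area_frac <- runif(1, 0.22, 0.34)
  ecc <- runif(1, ecc_range[1], ecc_range[2])
  r0 <- sqrt(area_frac * w * h / pi)
  a <- r0 * sqrt(ecc)
  b <- r0 / sqrt(ecc)
  cap <- 0.5 * min(w, h) / 1.25 - 2
  if (a > cap) { b <- b * cap / a; a <- cap }
  phi <- runif(1, 0, pi)
  cf <- rnorm(4, 0, 0.035)
  sf <- rnorm(4, 0, 0.035)
  x <- matrix(rep(seq_len(w), each = h), nrow = h) - cx
  y <- matrix(rep(seq_len(h), times = w), nrow = h) - cy
  xr <- x * cos(phi) + y * sin(phi)
  yr <- -x * sin(phi) + y * cos(phi)
  theta <- atan2(yr / b, xr / a)
  pert <- 1
  for (j in 2:5) pert <- pert + cf[j - 1] * cos(j * theta) + sf[j - 1] * sin(j * theta)
  pert <- pmax(pert, 0.6)
  ((xr / a)^2 + (yr / b)^2) <= pert^2
}

# Smoothed standard-normal noise field with isotropic Gaussian kernel of
# width sigma (pixels), standardized to unit variance.
smooth_field <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), nrow = h)
  f <- EBImage::gblur(z, sigma = sigma)
  f <- as.matrix(f)
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Generate one synthetic specimen (image pair + ground truth)
#'
#' @param t chewing-stroke count (>= 0).
#' @param subject_rate per-subject mixing rate (> 0).
#' @param config a [synthetic_config()].
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @param subject_id optional label carried into the manifest.
#' @return object of class `gum_specimen`: list with `images` (named list
#'   `A`, `B` of `H x W x 3` arrays, 0..255), `roi_truth` (logical masks per
#'   side), `t`, `subject_id`, `mixing_level`, `seed`.
#' @export
generate_specimen <- function(t, subject_rate, config = synthetic_config(),
                              seed = 1L, subject_id = NA_character_) {
  if (!is.numeric(t) || t < 0) stop_gummix("`t` must be >= 0", "parameter")
  if (!is.numeric(subject_rate) || subject_rate <= 0) {
    stop_gummix("`subject_rate` must be > 0", "parameter")
  }
  w <- config$image_size[1]; h <- config$image_size[2]
  mixing <- 1 - exp(-subject_rate * t)
  with_seed(seed, {
    mask <- make_blob_mask(w, h, config$blob_eccentricity_range)
    grad_slope <- runif(2, -0.015, 0.015)
    sides <- list(A = NULL, B = NULL)
    # Patch scale shrinks with mixing; hue-blend softness grows with it.
    # The scale range is small relative to the bolus so that each wafer
    # face carries many patches and its summary statistics are stable.
    sigma <- 0.7 + (2.5 - 0.7) * (1 - mixing)
    softness <- 0.15 + 0.9 * mixing
    red_frac <- c(A = 1 - 0.5 * mixing, B = 0.5 * mixing)
    for (s in c("A", "B")) {
      if (t == 0) {
        alpha <- matrix(if (s == "A") 1 else 0, nrow = h, ncol = w)
      } else {
        field <- smooth_field(h, w, sigma)
        tau <- as.numeric(quantile(field[mask], 1 - red_frac[[s]]))
        alpha <- plogis((field - tau) / softness)
      }
      img <- array(config$background_grey, dim = c(h, w, 3L))
      for (ch in 1:3) {
        plane <- alpha * .RED_RGB[ch] + (1 - alpha) * .WHITE_RGB[ch]
        chan <- img[, , ch]
        chan[mask] <- plane[mask]
        img[, , ch] <- chan
      }
      gx <- matrix(rep(seq_len(w) / w - 0.5, each = h), nrow = h)
      gain <- 1 + grad_slope[if (s == "A") 1 else 2] * gx
      for (ch in 1:3) {
        img[, , ch] <- clip255(img[, , ch] * gain +
                                 rnorm(h * w, sd = config$noise_sd))
      }
      sides[[s]] <- img
    }
    structure(list(
      images = sides, roi_truth = list(A = mask, B = mask),
      t = as.integer(t), subject_id = subject_id,
      mixing_level = mixing, seed = as.integer(seed)
    ), class = "gum_specimen")
  })
}

draw_subject_rates <- function(n, config) {
  pmax(rnorm(n, config$subject_rate_mean, config$subject_rate_sd),
       config$subject_rate_mean / 10)
}

#' Generate a full calibration set
#'
#' One specimen per subject per cycle count; each subject draws one mixing
#' rate from the configured distribution. Deterministic for a fixed config
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return object of class `gum_specimen_set`: list with `specimens` (list
#'   of `gum_specimen`) and `manifest` (data frame: specimen_id, subject_id,
#'   t, mixing_level, subject_rate, seed).
#' @export
generate_calibration_set <- function(config = synthetic_config()) {
  n <- config$n_subjects
  cyc <- config$cycles
  rates <- with_seed(config$seed, draw_subject_rates(n, config))
  seeds <- derive_seeds(config$seed + 1L, n * length(cyc))
  specs <- vector("list", n * length(cyc))
  man <- vector("list", n * length(cyc))
  idx <- 0L
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    for (t in cyc) {
      idx <- idx + 1L
      sp <- generate_specimen(t, rates[i], config, seed = seeds[idx],
                              subject_id = sid)
      specs[[idx]] <- sp
      man[[idx]] <- data.frame(
        specimen_id = sprintf("%s_t%02d", sid, t), subject_id = sid,
        t = t, mixing_level = sp$mixing_level, subject_rate = rates[i],
        seed = seeds[idx], stringsAsFactors = FALSE
      )
    }
  }
  structure(list(specimens = specs, manifest = do.call(rbind, man)),
            class = "gum_specimen_set")
}

#' Generate paired pre-/post-treatment diagnosis cohorts
#'
#' Per patient: two pre-treatment and two post-treatment specimens, all
#' masticated exactly `T` strokes, with the post-treatment mixing rate drawn
#' from a higher-mean distribution (the treatment effect).
#'
#' @param n_patients patients in the testing cohort.
#' @param pre_rate_mean,post_rate_mean mean mixing rates before/after
#'   treatment (per stroke).
#' @param T applied chewing strokes (> 0; clinical protocol uses 20).
#' @param config a [synthetic_config()] (its rate sd and image parameters
#'   are reused).
#' @param seed master seed.
#' @return list with `pre` and `post`, each a `gum_specimen_set` whose
#'   manifest carries `patient_id` and `repeat_id` (1 or 2).
#' @export
generate_diagnosis_cohort <- function(n_patients = 40L,
                                      pre_rate_mean = 0.01,
                                      post_rate_mean = 0.03,
                                      T = 20L,
                                      config = synthetic_config(),
                                      seed = 1L) {
  if (T <= 0) stop_gummix("`T` must be > 0", "parameter")
  seeds <- derive_seeds(seed, 4L * n_patients + 2L)
  rates <- with_seed(seed + 7L, list(
    pre = pmax(rnorm(n_patients, pre_rate_mean, config$subject_rate_sd), 1e-4),
    post = pmax(rnorm(n_patients, post_rate_mean, config$subject_rate_sd), 1e-4)
  ))
  build <- function(phase, offset) {
    specs <- list(); man <- list(); k <- 0L
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%03d", i)
      for (rep in 1:2) {
        k <- k + 1L
        sd_i <- seeds[offset + (i - 1L) * 2L + rep]
        sp <- generate_specimen(T, rates[[phase]][i], config, seed = sd_i,
                                subject_id = pid)
        specs[[k]] <- sp
        man[[k]] <- data.frame(
          specimen_id = sprintf("%s_%s_r%d", pid, phase, rep),
          subject_id = pid, patient_id = pid, repeat_id = rep,
          phase = phase, t = as.integer(T), mixing_level = sp$mixing_level,
          subject_rate = rates[[phase]][i], seed = sd_i,
          stringsAsFactors = FALSE
        )
      }
    }
    structure(list(specimens = specs, manifest = do.call(rbind, man)),
              class = "gum_specimen_set")
  }
  list(pre = build("pre", 0L), post = build("post", 2L * n_patients))
}

#' Write a specimen set to disk (PNG images + CSV manifest)
#'
#' @param set a `gum_specimen_set`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame (one row per image file), invisibly.
#' @export
write_specimen_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(set$specimens)) {
    sp <- set$specimens[[i]]
    id <- set$manifest$specimen_id[i]
    for (s in c("A", "B")) {
      fn <- file.path(dir, sprintf("%s_%s.png", id, s))
      write_image(sp$images[[s]], fn)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, subject_id = sp$subject_id, side = s, t = sp$t,
        mixing_level = sp$mixing_level, path = fn, seed = sp$seed,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
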