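# Shared fixtures, built in code at test time.

array_to_pixmat_local <- function(img) matrix(img, ncol = 3)

# Small frames keep the unit suite fast; study-scale runs live in
# test-acceptance.R.
small_config <- function(...) {
  synthetic_config(n_subjects = 4L, image_size = c(64L, 64L), ...)
}

fixture_specimen <- function(t = 10, rate = 0.08, seed = 101,
                             config = small_config()) {
  generate_specimen(t, rate, config, seed = seed)
}

# A noiseless disk-on-background image: trivially separable two-region
# scene with an exact ground-truth mask.
disk_image <- function(n = 64, radius = 18, fg = c(200, 40, 60), bg = 60) {
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), nrow = n) - ctr
  y <- matrix(rep(seq_len(n), times = n), nrow = n) - ctr
  mask <- x^2 + y^2 <= radius^2
  img <- array(bg, dim = c(n, n, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fg[ch]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask)
}

# Planted multi-class Gaussian feature table: `m_signal` columns whose
# class means move linearly with the stroke count, plus pure-noise columns.
planted_mp_table <- function(n_per_class = 20, classes = c(0, 5, 10, 15, 20),
                             m_signal = 5, m_noise = 10, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    t_lab <- rep(classes, each = n_per_class)
    n <- length(t_lab)
    cols <- list()
    for (j in seq_len(m_signal)) {
      cols[[paste0("sig", j)]] <- t_lab / 5 * sep + rnorm(n)
    }
    for (j in seq_len(m_noise)) {
      cols[[paste0("noise", j)]] <- rnorm(n)
    }
    mp <- do.call(cbind, cols)
    list(mp = mp, t = t_lab)
  })
}

# Build a tiny but suitable cascade from well-separated planted data
# (cheap sweep); used by MEPAT / diagnosis plumbing tests.
planted_cascade <- function(seed = 7) {
  dat <- planted_mp_table(n_per_class = 12, m_signal = 4, m_noise = 2,
                          sep = 6, seed = seed)
  colnames(dat$mp) <- c("MpR", "MpG", "MpB", "MpL", "VpR", "VpG")[seq_len(ncol(dat$mp))]
  fit <- train_cascade(dat$mp, dat$t, kept_codes = c("MpR", "MpG", "MpB", "MpL"),
                       params = cascade_params(sweep_points = 2L, restarts = 2L,
                                               max_chunks = 3L),
                       seed = seed)
  list(fit = fit, dat = dat)
}

# Wrap a cascade into a full MEPAT record with plausible metadata.
fixture_mepat <- function(fit, cycles = c(0L, 5L, 10L, 15L, 20L), seed = 11) {
  ev <- fit$evaluation
  ch <- data.frame(code = fit$cascade$kept_codes,
                   q = rep(0.9, length(fit$cascade$kept_codes)),
                   center = as.numeric(fit$cascade$center),
                   scale = as.numeric(fit$cascade$scale),
                   stringsAsFactors = FALSE)
  mepat_record(
    tf = list(brand = "synthetic wafer", colour_a = "red", colour_b = "white",
              dimensions_mm = c(38, 9, 5), colour_pair = "red-white"),
    es = list(cycles = cycles, dpi = 300, thickness_mm = 1,
              segmentation = unclass(segment_params())),
    ch = ch, cls = fit$cascade,
    op = list(name = "tester", institution = "lab"),
    per = list(global = c(ev$pooled[c("mcc", "sensitivity", "specificity",
                                      "accuracy")],
                          list(n_unclassified = ev$n_unclassified)),
               per_stage = ev$per_stage[, c("target_t", "mcc")]),
    uid = uuid_v4(seed = seed),
    created = "2026-01-01T00:00:00Z"
  )
}
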