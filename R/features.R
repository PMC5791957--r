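# Masticatory Performance (MP) feature vector: 10 extraction models applied
# to each of the 12 colour channels, plus the circular variance of hue
# (CVOH), for a total of 121 features per specimen. Features are computed
# over the pooled ROI pixels of both sides of the specimen.
#
# Extraction model codes (the "Mixture Feature Code" grammar is
# <model><channel>, e.g. VhH = histogram variance of the Hue channel):
#   Mp  mean of the pixel values
#   Vp  absolute (population) variance of the pixel values
#   Vh  absolute variance of the 256 raw histogram bin counts
#   Sh  count-weighted Fisher-Pearson skewness of the histogram over bins
#   Gh  histogram energy, sum(p_i^2)
#   Eh  histogram entropy, -sum(p_i log2 p_i), bits
#   Nh  number of histogram peaks (prominence >= 1% of total count)
#   V1  height of the tallest peak (raw count; 0 if none)
#   V2  height of the 2nd tallest peak (0 if fewer than two)
#   P2  bin index (0-based) of the 2nd tallest peak (-1 if absent)

MODEL_CODES <- c("Mp", "Vp", "Vh", "Sh", "Gh", "Eh", "Nh", "V1", "V2", "P2")

#' The default Mixture Feature Code registry
#'
#' @return data frame with columns `code`, `model`, `channel` — 120 rows of
#'   model x channel combinations plus the `CVOH` row, 121 in all. The row
#'   order fixes the MP vector ordering.
#' @export
mfc_registry <- function() {
  grid <- expand.grid(channel = channel_codes(), model = MODEL_CODES,
                      stringsAsFactors = FALSE)[, c("model", "channel")]
  out <- rbind(
    data.frame(code = paste0(grid$model, grid$channel),
               model = grid$model, channel = grid$channel,
               stringsAsFactors = FALSE),
    data.frame(code = "CVOH", model = "CVOH", channel = "H",
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Pool ROI pixels from both sides of a specimen
#'
#' Region-of-interest pixels from the two sides are pooled into a single
#' collection before any statistic is computed, so each feature describes
#' the specimen, not a side.
#'
#' @param specimen a `gum_specimen` (or any list with `images$A`, `images$B`).
#' @param masks named list of `gum_region_mask` (or logical matrices) for
#'   sides `A` and `B`.
#' @return `N x 3` matrix of pooled RGB pixel rows.
#' @export
pool_roi_pixels <- function(specimen, masks) {
  get_mask <- function(m) if (is.list(m)) m$mask else m
  px <- list()
  for (s in c("A", "B")) {
    m <- get_mask(masks[[s]])
    img <- specimen$images[[s]]
    if (!identical(dim(m), dim(img)[1:2])) {
      stop_gummix("mask not aligned to image", "input")
    }
    sel <- as.vector(m)
    if (any(sel)) px[[s]] <- array_to_pixmat(img)[sel, , drop = FALSE]
  }
  if (length(px) == 0L) stop_gummix("empty ROI on both sides", "feature")
  do.call(rbind, px)
}

#' 256-bin histogram of a channel over its fixed range
#'
#' Bins are equal-width over the channel's full range (e.g. 0..255 for
#' 8-bit channels, `[0, 2*pi)` for hue); values are clamped into range so
#' the counts always total the number of contributing pixels.
#'
#' @param values numeric vector (non-empty; `NA` not allowed — undefined
#'   hues must be dropped by the caller).
#' @param channel channel code, see [channel_codes()].
#' @param nbins number of bins (256).
#' @return object of class `gum_histogram`: list with `counts`, `breaks`,
#'   `total`, `p` (normalized probabilities).
#' @export
channel_histogram <- function(values, channel, nbins = 256L) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop_gummix("cannot histogram an empty value set", "feature")
  }
  rng <- channel_range(channel)
  values <- pmin(pmax(values, rng[1]), rng[2])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  idx[idx > nbins] <- nbins
  counts <- tabulate(idx, nbins)
  structure(list(counts = counts, breaks = breaks,
                 total = length(values), p = counts / length(values)),
            class = "gum_histogram")
}

# Peak detection on a 256-bin histogram. The raw counts are smoothed with a
# (1,2,1)/4 kernel (scan histograms are jagged); a bin is a peak candidate
# if strictly greater than both smoothed neighbours; candidates are kept if
# their topographic prominence on the smoothed profile is at least
# `min_prom_frac` of the total count. Returns peaks sorted by raw height.
hist_peaks <- function(hist, min_prom_frac = 0.01) {
  y <- hist$counts
  n <- length(y)
  ys <- c(y[1], y[-n]) * 0.25 + y * 0.5 + c(y[-1], y[n]) * 0.25
  cand <- which(ys > c(-Inf, ys[-n]) & ys > c(ys[-1], -Inf))
  if (length(cand) == 0L) return(data.frame(bin = integer(), height = numeric()))
  prom <- vapply(cand, function(i) {
    # Saddle on one side: minimum of the smoothed profile between the peak
    # and the nearest bin at least as high (or the edge if none). An empty
    # side does not constrain the prominence.
    base_side <- function(side_nearest_first) {
      if (length(side_nearest_first) == 0L) return(-Inf)
      higher <- which(side_nearest_first >= ys[i])
      upto <- if (length(higher) == 0L) length(side_nearest_first) else min(higher)
      min(side_nearest_first[seq_len(upto)])
    }
    lb <- base_side(rev(ys[seq_len(i - 1)]))
    rb <- base_side(if (i < n) ys[(i + 1):n] else numeric())
    ys[i] - max(lb, rb)
  }, numeric(1))
  keep <- prom >= min_prom_frac * hist$total
  cand <- cand[keep]
  if (length(cand) == 0L) return(data.frame(bin = integer(), height = numeric()))
  ord <- order(y[cand], decreasing = TRUE)
  data.frame(bin = cand[ord] - 1L, height = y[cand][ord])  # 0-based bins
}

#' Evaluate one extraction model
#'
#' Computes a single scalar feature from the pixel values and/or histogram
#' of one channel. See the model-code table in [mfc_registry()].
#'
#' @param model_code one of `Mp, Vp, Vh, Sh, Gh, Eh, Nh, V1, V2, P2`.
#' @param values numeric pixel values (required by `Mp`, `Vp`).
#' @param hist a [channel_histogram()] (required by the histogram models).
#' @return scalar feature value.
#' @export
extract_feature <- function(model_code, values = NULL, hist = NULL) {
  if (!model_code %in% MODEL_CODES) {
    stop_gummix(paste0("unknown extraction model: ", model_code), "registry")
  }
  pop_var <- function(x) mean((x - mean(x))^2)
  if (model_code %in% c("Mp", "Vp")) {
    values <- values[!is.na(values)]
    if (length(values) == 0L) stop_gummix("no defined pixel values", "feature")
    return(switch(model_code, Mp = mean(values), Vp = pop_var(values)))
  }
  if (is.null(hist)) stop_gummix("histogram models need a histogram", "feature")
  cnt <- hist$counts
  p <- hist$p
  switch(model_code,
    Vh = pop_var(cnt),
    Sh = {
      i <- seq_along(cnt) - 1
      mu <- sum(p * i)
      m2 <- sum(p * (i - mu)^2)
      if (m2 < 1e-12) 0 else sum(p * (i - mu)^3) / m2^1.5
    },
    Gh = sum(p^2),
    Eh = { pp <- p[p > 0]; -sum(pp * log2(pp)) },
    Nh = nrow(hist_peaks(hist)),
    V1 = { pk <- hist_peaks(hist); if (nrow(pk) >= 1) pk$height[1] else 0 },
    V2 = { pk <- hist_peaks(hist); if (nrow(pk) >= 2) pk$height[2] else 0 },
    P2 = { pk <- hist_peaks(hist); if (nrow(pk) >= 2) pk$bin[2] else -1 }
  )
}

#' Circular variance of the hue channel (CVOH)
#'
#' `CVOH = 1 - Rbar`, where `Rbar` is the length of the mean resultant
#' vector of the hue angles. 0 when all hues coincide; 1 when they cancel
#' (e.g. equal mass at antipodal hues) — a classical single-number mixture
#' index for two-colour wafers.
#'
#' @param hue_values hue angles in radians; `NA` (undefined hue) dropped.
#' @return scalar in `[0, 1]`.
#' @export
cvoh <- function(hue_values) {
  h <- hue_values[!is.na(hue_values)]
  if (length(h) == 0L) {
    stop_gummix("CVOH undefined: all pixels achromatic (no defined hue)",
                "feature")
  }
  1 - sqrt(sum(cos(h))^2 + sum(sin(h))^2) / length(h)
}

#' Extract the Masticatory Performance vector of a specimen
#'
#' Pools the ROI pixels of both sides, converts them to the 12 analysis
#' channels, and evaluates every feature in the registry. Undefined-hue
#' pixels are excluded from all `H`-channel statistics (never imputed).
#'
#' @param specimen a `gum_specimen`.
#' @param masks per-side masks, see [pool_roi_pixels()].
#' @param registry feature registry (default [mfc_registry()]); pass a
#'   subset to compute only selected features (e.g. a MEPAT's CH block).
#' @return named numeric vector, one element per registry row, in registry
#'   order.
#' @export
extract_mp <- function(specimen, masks, registry = mfc_registry()) {
  px <- pool_roi_pixels(specimen, masks)
  chans <- channel_set(px)
  needed <- unique(registry$channel)
  hists <- list()
  for (ch in intersect(needed, colnames(chans))) {
    mods <- registry$model[registry$channel == ch]
    if (any(!mods %in% c("Mp", "Vp", "CVOH"))) {
      hists[[ch]] <- channel_histogram(chans[, ch], ch)
    }
  }
  out <- numeric(nrow(registry))
  names(out) <- registry$code
  for (i in seq_len(nrow(registry))) {
    m <- registry$model[i]; ch <- registry$channel[i]
    out[i] <- if (m == "CVOH") {
      cvoh(chans[, "H"])
    } else {
      extract_feature(m, values = chans[, ch], hist = hists[[ch]])
    }
  }
  out
}

#' Extract MP vectors for a whole specimen set
#'
#' Segments (unless masks are supplied) and featurizes every specimen.
#'
#' @param set a `gum_specimen_set`.
#' @param params segmentation parameters.
#' @param masks optional pre-computed list of per-specimen mask pairs; when
#'   `NULL`, ground-truth masks are used if `use_truth = TRUE`, otherwise
#'   each specimen is segmented.
#' @param use_truth use the generator's ground-truth masks (fast path for
#'   simulation studies).
#' @param registry feature registry.
#' @return list with `mp` (matrix, specimens x features), `t` (stroke
#'   labels), `manifest`.
#' @export
extract_mp_set <- function(set, params = segment_params(), masks = NULL,
                           use_truth = FALSE, registry = mfc_registry()) {
  n <- length(set$specimens)
  mp <- matrix(NA_real_, nrow = n, ncol = nrow(registry),
               dimnames = list(set$manifest$specimen_id, registry$code))
  for (i in seq_len(n)) {
    sp <- set$specimens[[i]]
    mk <- if (!is.null(masks)) {
      masks[[i]]
    } else if (use_truth) {
      sp$roi_truth
    } else {
      segment_specimen(sp, params)
    }
    mp[i, ] <- extract_mp(sp, mk, registry)
  }
  list(mp = mp, t = set$manifest$t, manifest = set$manifest)
}
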