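# Single diagnosis mixing-test: segment a new specimen with the calibrated
# settings, extract only the MEPAT's selected features, classify through
# the binary cascade to obtain the predicted stroke count P, and report
# ME = P / T with a linguistic tag. A specimen no stage claims is surfaced
# as UNCLASSIFIED, never silently coerced to ME = 0.

.ME_LEVELS <- c(0, 0.25, 0.5, 0.75, 1)
.ME_TAGS <- c("Totally impaired", "Impeded", "Limited", "Adequate", "Normal")

#' Masticatory efficiency ME = P / T
#'
#' @param P predicted stroke count (>= 0).
#' @param T applied stroke count (> 0).
#' @return the ratio `P / T` (0 = total absence of mixture, 1 = normal,
#'   > 1 = better than the healthy reference norm).
#' @export
compute_me <- function(P, T) {
  if (any(T <= 0)) stop_gummix("`T` must be > 0", "parameter")
  if (any(P < 0)) stop_gummix("`P` must be >= 0", "parameter")
  P / T
}

#' Linguistic tag for an ME level
#'
#' Maps an ME ratio to the nearest reference level among 0/25/50/75/100%
#' ("Totally impaired", "Impeded", "Limited", "Adequate", "Normal");
#' midpoints round up, and anything above 100% is "Better than the norm".
#'
#' @param me ME ratio (>= 0).
#' @return character tag.
#' @export
me_tag <- function(me) {
  if (any(is.na(me)) || any(me < 0)) stop_gummix("ME must be >= 0", "parameter")
  vapply(me, function(x) {
    if (x > 1 + 1e-9) return("Better than the norm")
    d <- abs(x - .ME_LEVELS)
    # midpoint ties resolve to the higher level
    .ME_TAGS[max(which(d == min(d)))]
  }, character(1))
}

#' Diagnose a specimen image pair with a MEPAT
#'
#' @param side_a,side_b `H x W x 3` RGB arrays (0..255) of the two wafer
#'   sides, or file paths readable by [read_image()].
#' @param mepat a `gum_mepat` (or path to a `.mepat.xml` file).
#' @param T applied chewing strokes; must be one of the calibrated cycle
#'   counts (clinical protocol: 20, the largest calibrated count).
#' @param specimen_id optional identifier echoed in the result.
#' @return object of class `gum_diagnosis`: list with `P` (integer or `NA`
#'   when unclassified), `T`, `me`, `me_pct`, `tag`, `status`
#'   (`"classified"` / `"unclassified"`), `mepat_uid`, `specimen_id`.
#' @export
diagnose <- function(side_a, side_b, mepat, T = 20L, specimen_id = NA_character_) {
  if (is.character(mepat)) mepat <- read_mepat(mepat)
  validate_mepat(mepat)
  if (T <= 0) stop_gummix("`T` must be > 0", "parameter")
  if (!T %in% mepat$es$cycles) {
    stop_gummix(sprintf(
      "T = %d is outside the calibrated cycle list (%s); diagnosis is only defined at calibrated counts",
      T, paste(mepat$es$cycles, collapse = ", ")), "parameter")
  }
  if (is.character(side_a)) side_a <- read_image(side_a)
  if (is.character(side_b)) side_b <- read_image(side_b)
  sp <- mepat$es$segmentation
  params <- segment_params(spatial_bandwidth = sp$spatial_bandwidth,
                           range_bandwidth = sp$range_bandwidth,
                           dist_weight = sp$dist_weight,
                           restarts = sp$restarts, seed = sp$seed,
                           variant = sp$variant)
  specimen <- list(images = list(A = side_a, B = side_b))
  masks <- list(A = segment(side_a, params), B = segment(side_b, params))
  reg <- mfc_registry()
  reg <- reg[match(mepat$ch$code, reg$code), , drop = FALSE]
  mp <- extract_mp(specimen, masks, registry = reg)
  P <- classify_mp(mp, mepat$cls)
  classified <- !is.na(P)
  me <- if (classified) compute_me(P, T) else NA_real_
  structure(list(
    P = P, T = as.integer(T), me = me,
    me_pct = if (classified) 100 * me else NA_real_,
    tag = if (classified) me_tag(me) else "Unclassified",
    status = if (classified) "classified" else "unclassified",
    mepat_uid = mepat$uid, specimen_id = specimen_id
  ), class = "gum_diagnosis")
}

#' @export
print.gum_diagnosis <- function(x, ...) {
  cat("Mixing-test diagnosis (MEPAT ", x$mepat_uid, ")\n", sep = "")
  if (x$status == "classified") {
    cat(sprintf("  P = %d strokes, T = %d strokes\n  ME = %.2f (%.0f%%) - %s\n",
                x$P, x$T, x$me, x$me_pct, x$tag))
  } else {
    cat("  UNCLASSIFIED: no cascade stage claimed this specimen\n")
  }
  invisible(x)
}

#' Agreement between repeated categorical measurements (Cohen's kappa)
#'
#' @param results_a,results_b paired label vectors (e.g. repeated P values
#'   or ME tags of the same patients).
#' @return Cohen's kappa.
#' @export
repeat_agreement <- function(results_a, results_b) {
  if (length(results_a) != length(results_b)) {
    stop_gummix("paired result lists differ in length", "input")
  }
  lev <- sort(unique(c(results_a, results_b)))
  # single observed category: chance agreement is 1 and kappa's ratio is
  # 0/0; perfect duplicate measurements still mean perfect agreement
  if (length(lev) == 1L) return(1)
  tab <- table(factor(results_a, levels = lev), factor(results_b, levels = lev))
  e1071::classAgreement(tab)$kappa
}
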