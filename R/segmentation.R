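# Automatic bolus/background segmentation: mean-shift smoothing (MS), a
# normalized distance-to-centre map (DM), and k-means region classification
# (KM). The bolus sits in the centre of the scan, so the distance feature
# biases k-means to gather the central blob into one cluster even when its
# colours are heterogeneous (a half-mixed wafer contains both red and white
# patches, which pure colour clustering would happily split).

#' Segmentation parameters
#'
#' @param spatial_bandwidth mean-shift spatial bandwidth, pixels.
#' @param range_bandwidth mean-shift range bandwidth, CIE-L*u*v* units.
#' @param dist_weight weight of the normalized centre-distance feature in
#'   the k-means stack (applied after per-channel standardization).
#' @param restarts k-means restarts.
#' @param seed seed for k-means initialization.
#' @param variant which pipeline to run: the full `"ms_dm_km"` or the
#'   ablations `"km"`, `"ms_km"`, `"dm_km"`.
#' @return a validated parameter list of class `gum_segment_params`.
#' @export
segment_params <- function(spatial_bandwidth = 8, range_bandwidth = 12,
                           dist_weight = 1.0, restarts = 10L, seed = 1L,
                           variant = c("ms_dm_km", "km", "ms_km", "dm_km")) {
  if (spatial_bandwidth <= 0 || range_bandwidth <= 0) {
    stop_gummix("bandwidths must be > 0", "parameter")
  }
  variant <- match.arg(variant)
  structure(list(spatial_bandwidth = spatial_bandwidth,
                 range_bandwidth = range_bandwidth,
                 dist_weight = dist_weight, restarts = as.integer(restarts),
                 seed = as.integer(seed), variant = variant),
            class = "gum_segment_params")
}

# Mean shift over an H x W x 3 L*u*v* array.
ms_filter_luv <- function(luv_arr, spatial_bandwidth, range_bandwidth,
                          max_iter = 5L, tol = 0.05) {
  out <- ms_filter_cpp(luv_arr[, , 1], luv_arr[, , 2], luv_arr[, , 3],
                       as.integer(spatial_bandwidth), range_bandwidth,
                       as.integer(max_iter), tol)
  array(c(out[[1]], out[[2]], out[[3]]), dim = dim(luv_arr))
}

rgb_array_to_luv_array <- function(image) {
  d <- dim(image)
  pixmat_to_array(rgb_to_luv(array_to_pixmat(image)), d)
}

#' Mean-shift edge-preserving smoothing of an RGB image
#'
#' Filters the image in CIE-L*u*v* (so the range bandwidth is a perceptual
#' colour distance): each pixel converges to the mode of its joint
#' spatial-colour neighbourhood, flattening near-uniform regions while
#' preserving boundaries whose colour contrast exceeds the range bandwidth.
#'
#' @param image `H x W x 3` RGB array (0..255).
#' @param spatial_bandwidth spatial kernel radius, pixels (> 0).
#' @param range_bandwidth colour kernel radius, L*u*v* units (> 0).
#' @return filtered RGB array of the same shape.
#' @export
mean_shift_filter <- function(image, spatial_bandwidth = 8,
                              range_bandwidth = 12) {
  assert_rgb(image)
  if (spatial_bandwidth <= 0 || range_bandwidth <= 0) {
    stop_gummix("bandwidths must be > 0", "parameter")
  }
  luv <- rgb_array_to_luv_array(image)
  f <- ms_filter_luv(luv, spatial_bandwidth, range_bandwidth)
  d <- dim(image)
  pixmat_to_array(luv_to_rgb(array_to_pixmat(f)), d)
}

#' Normalized distance-to-centre map
#'
#' Per-pixel Euclidean distance to the image centre, min-max normalized to
#' `[0, 1]` (0 at the most central pixel, 1 at the corners).
#'
#' @param image_shape `c(height, width)`.
#' @return `height x width` numeric matrix.
#' @export
distance_map <- function(image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  if (h < 1 || w < 1) stop_gummix("empty image shape", "input")
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  x <- matrix(rep(seq_len(w), each = h), nrow = h) - cx
  y <- matrix(rep(seq_len(h), times = w), nrow = h) - cy
  d <- sqrt(x^2 + y^2)
  if (max(d) == min(d)) return(matrix(0, h, w))
  (d - min(d)) / (max(d) - min(d))
}

# Keep only the ROI connected component containing the image centre (or the
# largest, if the centre fell into background); everything else becomes
# background. Interior holes — wafer patches whose colour sided with the
# background cluster — are filled: the bolus is a solid object.
keep_central_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (max(lab) == 0L) return(mask & FALSE)
  centre <- lab[round(nrow(mask) / 2), round(ncol(mask) / 2)]
  keep <- if (centre > 0L) centre else which.max(tabulate(lab[lab > 0L]))
  out <- EBImage::fillHull((lab == keep) * 1)
  matrix(as.integer(out), nrow = nrow(mask)) > 0L
}

#' K-means region classification into ROI and background
#'
#' Runs k-means (k = 2, multiple restarts, fixed seed) on a per-pixel
#' feature stack, labels as ROI the cluster with the smaller mean
#' normalized centre distance (ties: the smaller cluster), and keeps only
#' the ROI connected component containing the image centre.
#'
#' @param feature_stack numeric matrix, one row per pixel (columns already
#'   standardized by the caller).
#' @param dist_feature normalized centre distance per pixel (used to decide
#'   which cluster is the bolus; it need not be part of the stack).
#' @param dim image `c(height, width)`.
#' @param k number of clusters (the method partitions into exactly 2).
#' @param seed,restarts k-means initialization control.
#' @return object of class `gum_region_mask`: list with `mask` (logical
#'   `H x W`, `TRUE` = ROI) and `roi_pixel_count`.
#' @export
kmeans_region_classify <- function(feature_stack, dist_feature, dim,
                                   k = 2L, seed = 1L, restarts = 10L) {
  if (nrow(feature_stack) != prod(dim)) {
    stop_gummix("feature stack rows must equal pixel count", "input")
  }
  rng <- apply(feature_stack, 2, function(col) diff(range(col)))
  if (all(rng < 1e-9)) {
    stop_gummix("degenerate input: all pixels identical", "segmentation")
  }
  km <- with_seed(seed, kmeans(feature_stack, centers = k,
                               nstart = restarts, iter.max = 50L))
  mean_dist <- tapply(dist_feature, km$cluster, mean)
  ord <- order(mean_dist, tabulate(km$cluster, k))
  roi_cluster <- as.integer(names(mean_dist))[ord[1]]
  mask <- matrix(km$cluster == roi_cluster, nrow = dim[1])
  mask <- keep_central_component(mask)
  n <- sum(mask)
  if (n == 0) stop_gummix("segmentation produced an empty ROI", "segmentation")
  structure(list(mask = mask, roi_pixel_count = n, cluster = km),
            class = "gum_region_mask")
}

#' Segment a specimen image into bolus (ROI) and background
#'
#' Full pipeline: mean-shift smoothing in L*u*v*, append the normalized
#' centre-distance feature, z-standardize every channel, k-means (k = 2)
#' region classification, connected-component cleanup. The `variant`
#' parameter exposes the ablations (KM only, MS+KM, DM+KM) used to justify
#' the full combination.
#'
#' @param image `H x W x 3` RGB array (0..255).
#' @param params a [segment_params()].
#' @return a `gum_region_mask` (see [kmeans_region_classify()]).
#' @export
segment <- function(image, params = segment_params()) {
  assert_rgb(image)
  d <- dim(image)[1:2]
  luv <- rgb_array_to_luv_array(image)
  use_ms <- params$variant %in% c("ms_dm_km", "ms_km")
  use_dm <- params$variant %in% c("ms_dm_km", "dm_km")
  if (use_ms) {
    luv <- ms_filter_luv(luv, params$spatial_bandwidth, params$range_bandwidth)
  }
  feat <- apply(array_to_pixmat(luv), 2, function(col) {
    s <- sd(col)
    if (s < 1e-12) col * 0 else (col - mean(col)) / s
  })
  dmap <- distance_map(d)
  dvec <- as.vector(dmap)
  if (use_dm) {
    ds <- sd(dvec)
    feat <- cbind(feat, params$dist_weight * (dvec - mean(dvec)) / ds)
  }
  res <- kmeans_region_classify(feat, dvec, d, k = 2L,
                                seed = params$seed, restarts = params$restarts)
  # Failure guard: a background-only frame still splits into two clusters,
  # but their colours are then indistinguishable.
  luv_px <- array_to_pixmat(luv)
  roi_col <- colMeans(luv_px[as.vector(res$mask), , drop = FALSE])
  bg_col <- colMeans(luv_px[!as.vector(res$mask), , drop = FALSE])
  if (sqrt(sum((roi_col - bg_col)^2)) < 4) {
    stop_gummix("segmentation failure: no colour contrast between regions",
                "segmentation")
  }
  res$cluster <- NULL
  res$params <- params
  res
}

#' Segment both sides of a specimen
#'
#' @param specimen a `gum_specimen`.
#' @param params a [segment_params()].
#' @return named list of `gum_region_mask` for sides `A` and `B`.
#' @export
segment_specimen <- function(specimen, params = segment_params()) {
  list(A = segment(specimen$images$A, params),
       B = segment(specimen$images$B, params))
}

#' Write a region mask as a single-channel PNG with a JSON sidecar
#'
#' @param mask a `gum_region_mask`.
#' @param path destination PNG path (`.json` sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$mask * 1, target = path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(roi_pixel_count = mask$roi_pixel_count,
                            params = unclass(mask$params)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
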