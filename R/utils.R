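#' @useDynLib gummix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov cor kmeans prcomp rnorm runif sd var wilcox.test
#'   pairwise.t.test quantile plogis median
#' @importFrom utils write.csv read.csv
NULL

# Typed conditions: every user-facing failure carries a gummix_error_* class
# so callers (and the CLI) can react per error family.
stop_gummix <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("gummix_error_", class), "gummix_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generator determinism funnels through
# this helper.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_gummix("`seed` must be a single finite number", "parameter")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a vector of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Canonical number -> text used by MEPAT files: 17 significant digits
# guarantees behavioural (bit-exact double) round-trips.
fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

is_rgb_array <- function(img) {
  is.numeric(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
    all(dim(img)[1:2] > 0L)
}

assert_rgb <- function(img) {
  if (!is_rgb_array(img)) {
    stop_gummix("expected an HxWx3 numeric RGB array (8-bit scale 0..255)", "input")
  }
  invisible(img)
}

# Flatten HxWx3 array to an N x 3 pixel matrix (row-major over the raster
# in R's column order; the inverse is pixmat_to_array).
array_to_pixmat <- function(img) {
  d <- dim(img)
  matrix(img, nrow = d[1] * d[2], ncol = 3L)
}

pixmat_to_array <- function(px, dm) {
  array(px, dim = c(dm[1], dm[2], 3L))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Read an 8-bit RGB raster image
#'
#' Reads a PNG (or any format `png` can decode from a connection written by
#' [write_image()]) into the package's internal representation: a numeric
#' `H x W x 3` array on the 0..255 scale.
#'
#' @param path file path to a PNG image.
#' @return numeric array `H x W x 3`, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_gummix(paste0("image not found: ", path), "io")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB raster image as PNG
#'
#' @param img numeric `H x W x 3` array, 0..255 scale.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  png::writePNG(clip255(img) / 255, target = path)
  invisible(path)
}

#' Jaccard index between two binary masks
#'
#' Intersection over union of two logical rasters of equal shape; the
#' standard overlap score used to compare a segmentation against ground
#' truth.
#'
#' @param a,b logical matrices of identical dimension.
#' @return scalar in `[0, 1]` (1 when both masks are empty).
#' @export
mask_jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_gummix("mask dimensions differ", "input")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
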