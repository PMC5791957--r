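# Relevancy-based feature selection. Each feature's relevancy combines its
# Spearman correlation with the chewing-stroke count and the number of
# stroke-class pairs it separates (one-way ANOVA with Bonferroni-corrected
# pairwise comparisons):
#
#   q = ( |rho| + (gamma / C(n,2))^2 ) / 2,    0 <= q <= 1
#
# where n is the number of distinct stroke classes. Features with q < 0.5
# are discarded. The formula is isolated in q_score() so it can be revised
# in one place.

#' Spearman correlation of a feature with the stroke count
#'
#' Average-rank tie handling (the default of [stats::cor()]). A constant
#' feature returns 0 with attribute `degenerate = TRUE`.
#'
#' @param feature_values numeric vector.
#' @param stroke_labels numeric vector of chewing-stroke counts.
#' @return scalar rho in `[-1, 1]`.
#' @export
spearman_rho <- function(feature_values, stroke_labels) {
  if (length(feature_values) < 3L || length(unique(stroke_labels)) < 2L) {
    stop_gummix("need >= 3 samples and >= 2 distinct stroke labels", "input")
  }
  if (sd(feature_values) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(feature_values, stroke_labels, method = "spearman")
}

#' Count of Bonferroni-significant stroke-class pairs (gamma)
#'
#' One-way ANOVA with the stroke count as the fixed factor; if the omnibus
#' test is significant at `alpha`, pairwise pooled-variance t-tests with
#' Bonferroni correction count the significantly different class pairs.
#'
#' @param feature_values numeric vector.
#' @param stroke_labels stroke counts (>= 2 samples per class).
#' @param alpha significance level (0.05).
#' @return integer gamma in `0 .. C(n,2)`.
#' @export
gamma_count <- function(feature_values, stroke_labels, alpha = 0.05) {
  f <- factor(stroke_labels)
  if (any(table(f) < 2L)) {
    stop_gummix("every stroke class needs >= 2 samples", "input")
  }
  if (sd(feature_values) == 0) return(0L)
  fit <- aov(feature_values ~ f)
  pval <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (!is.finite(pval) || pval >= alpha) return(0L)
  pw <- suppressWarnings(
    pairwise.t.test(feature_values, f, p.adjust.method = "bonferroni",
                    pool.sd = TRUE)
  )
  sum(pw$p.value < alpha, na.rm = TRUE)
}

#' Relevancy score q of a feature
#'
#' @param rho Spearman correlation with the stroke count (`|rho| <= 1`).
#' @param gamma count of significantly different class pairs.
#' @param n number of distinct stroke classes (>= 2).
#' @return q in `[0, 1]`; features below 0.5 are discarded.
#' @export
q_score <- function(rho, gamma, n) {
  if (n < 2) stop_gummix("need >= 2 stroke classes", "input")
  npairs <- choose(n, 2)
  if (abs(rho) > 1 + 1e-12) stop_gummix("|rho| must be <= 1", "input")
  if (gamma < 0 || gamma > npairs) {
    stop_gummix("gamma out of the 0..C(n,2) bound", "input")
  }
  (abs(rho) + (gamma / npairs)^2) / 2
}

#' Score and select features by relevancy
#'
#' @param mp_table numeric matrix/data frame, columns named by MFC codes.
#' @param stroke_labels chewing-stroke count per row.
#' @param alpha significance level for gamma.
#' @return data frame (class `gum_relevancy`) with columns `code`, `rho`,
#'   `gamma`, `q`, `kept`, sorted by decreasing q; attribute `kept_codes`
#'   holds the kept codes in original column order.
#' @export
select_features <- function(mp_table, stroke_labels, alpha = 0.05) {
  mp_table <- as.matrix(mp_table)
  n <- length(unique(stroke_labels))
  res <- lapply(colnames(mp_table), function(code) {
    x <- mp_table[, code]
    rho <- spearman_rho(x, stroke_labels)
    gam <- gamma_count(x, stroke_labels, alpha)
    data.frame(code = code, rho = as.numeric(rho), gamma = gam,
               q = q_score(rho, gam, n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$kept <- out$q >= 0.5
  kept_codes <- out$code[out$kept]
  out <- out[order(-out$q), ]
  rownames(out) <- NULL
  structure(out, kept_codes = kept_codes, class = c("gum_relevancy", "data.frame"))
}

#' PCA reduction of the kept features
#'
#' Standardized principal component analysis of the non-discarded feature
#' columns (zero-variance columns dropped). Offered as an optional
#' dimensionality-reduction path; the cascade trains on the bare kept
#' features by default.
#'
#' @param kept_feature_table numeric matrix of kept features (>= 2 columns).
#' @param n_components number of components to report.
#' @return list with `scores`, `loadings`, `explained` (variance fractions
#'   per component).
#' @export
pca_reduce <- function(kept_feature_table, n_components = 3L) {
  x <- as.matrix(kept_feature_table)
  x <- x[, apply(x, 2, sd) > 0, drop = FALSE]
  if (ncol(x) < 2L) stop_gummix("need >= 2 varying kept features", "input")
  n_components <- min(n_components, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)])
}
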