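# Binary-cascade pattern classifier. For every calibrated stroke class a
# one-vs-rest multilayer perceptron (k inputs, h hidden logistic units, one
# logistic output) is trained on the Training Group with early stopping
# monitored on the Validation Group; the hidden-layer size h is swept over
# k/3..k with several restarts per h, and the network with the best Matthews
# correlation coefficient (MCC) on the held-out Testing Group is kept. A
# stage is suitable only if that MCC exceeds the suitability threshold
# (0.95); the suitable stages, ordered by ascending stroke count, form the
# cascade: a new sample is queried stage by stage and takes the stroke count
# of the first stage that fires; if none fires it is UNCLASSIFIED.

#' Stratified 40/30/30 split into training/validation/testing groups
#'
#' @param stroke_labels class label per sample.
#' @param seed split seed.
#' @param fractions split fractions for TG, VG, SG (sum to 1).
#' @return factor of tags `TG`, `VG`, `SG`, one per sample; stratified by
#'   class, deterministic per seed.
#' @export
split_dataset <- function(stroke_labels, seed = 1L,
                          fractions = c(TG = 0.4, VG = 0.3, SG = 0.3)) {
  f <- factor(stroke_labels)
  if (any(table(f) < 10L)) {
    stop_gummix("every stroke class needs >= 10 samples to appear in all splits",
                "input")
  }
  tags <- character(length(f))
  with_seed(seed, {
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      nc <- length(idx)
      n_tg <- round(fractions[1] * nc)
      n_vg <- round(fractions[2] * nc)
      tags[idx[seq_len(n_tg)]] <- "TG"
      tags[idx[n_tg + seq_len(n_vg)]] <- "VG"
      tags[idx[(n_tg + n_vg + 1):nc]] <- "SG"
    }
  })
  factor(tags, levels = c("TG", "VG", "SG"))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary-classification quality score: 1 for perfect prediction,
#' 0 for a random-equivalent one, -1 for complete disagreement. When any
#' denominator factor is zero the score is defined as 0 (standard
#' convention).
#'
#' @param tp,tn,fp,fn non-negative confusion counts (total > 0). `tp` may
#'   also be a list/vector with named elements `tp`, `tn`, `fp`, `fn`.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L && !is.null(names(tp)))) {
    cc <- as.list(tp)
    tn <- cc$tn; fp <- cc$fp; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop_gummix("confusion counts must be >= 0", "input")
  if (sum(counts) == 0) stop_gummix("all-zero confusion matrix", "input")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

binary_confusion <- function(pred, truth) {
  list(tp = sum(pred & truth), tn = sum(!pred & !truth),
       fp = sum(pred & !truth), fn = sum(!pred & truth))
}

# ---- MLP internals -------------------------------------------------------

# Weight layout of a single-hidden-layer nnet: for each hidden unit j the
# block (bias, w_1j..w_kj), then the output block (bias, v_1..v_h).
nnet_to_weights <- function(fit, k, h) {
  w <- fit$wts
  W1 <- matrix(w[seq_len((k + 1) * h)], nrow = k + 1)      # (k+1) x h
  W2 <- w[(k + 1) * h + seq_len(h + 1)]                    # length h+1
  list(W1 = W1, W2 = W2, k = k, h = h)
}

# Forward pass of the serialized network (logistic hidden and output
# units); independent of nnet so MEPAT-deserialized cascades need only the
# weight matrices.
mlp_forward <- function(weights, X) {
  X <- as.matrix(X)
  Z <- plogis(cbind(1, X) %*% weights$W1)                  # n x h
  as.numeric(plogis(cbind(1, Z) %*% weights$W2))
}

# One training execution: batch Rprop training in chunks of epochs,
# monitoring MCC on the validation set after each chunk and keeping the
# weights of the best chunk (early stopping with patience). Case weights
# balance the 1-vs-rest class imbalance. The trainer (src/mlp.cpp) uses the
# same weight layout as nnet, so mlp_forward() serves both.
mlp_train_once <- function(Xtr, ytr, Xval, yval, h, seed,
                           decay = 1e-3, chunk = 100L, max_chunks = 5L,
                           patience = 2L) {
  k <- ncol(Xtr)
  n <- length(ytr)
  npos <- sum(ytr); nneg <- n - npos
  w <- ifelse(ytr == 1, n / (2 * max(npos, 1)), n / (2 * max(nneg, 1)))
  nw <- (k + 1) * h + h + 1
  wts <- with_seed(seed, runif(nw, -0.5, 0.5))
  best <- list(score = -Inf, weights = NULL)
  stale <- 0L
  for (ch in seq_len(max_chunks)) {
    wts <- mlp_train_cpp(Xtr, as.numeric(ytr), w, h, wts,
                         as.integer(chunk), decay)
    ww <- list(W1 = matrix(wts[seq_len((k + 1) * h)], nrow = k + 1),
               W2 = wts[(k + 1) * h + seq_len(h + 1)], k = k, h = h)
    pred <- mlp_forward(ww, Xval) > 0.5
    score <- tryCatch(mcc(binary_confusion(pred, yval == 1)),
                      gummix_error = function(e) -Inf)
    if (score > best$score) {
      best <- list(score = score, weights = ww)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (score >= 1 || stale > patience) break
  }
  best
}

#' Cascade training parameters
#'
#' @param sweep_points number of hidden-layer sizes tried, evenly spaced
#'   over `ceiling(k/3) .. k` (the full sweep tries every integer; the
#'   default samples 10 of them).
#' @param restarts training executions per hidden-layer size.
#' @param suitability_threshold a stage is suitable if its held-out MCC
#'   exceeds this (strictly); default 0.95.
#' @param decay,chunk,max_chunks,patience MLP training controls: L2 weight
#'   decay, epochs per early-stopping check, maximum checks, and checks
#'   without validation improvement tolerated.
#' @return parameter list of class `gum_cascade_params`.
#' @export
cascade_params <- function(sweep_points = 10L, restarts = 3L,
                           suitability_threshold = 0.95,
                           decay = 1e-3, chunk = 100L, max_chunks = 5L,
                           patience = 2L) {
  structure(list(sweep_points = as.integer(sweep_points),
                 restarts = as.integer(restarts),
                 suitability_threshold = suitability_threshold,
                 decay = decay, chunk = as.integer(chunk),
                 max_chunks = as.integer(max_chunks),
                 patience = as.integer(patience)),
            class = "gum_cascade_params")
}

h_sweep_values <- function(k, sweep_points) {
  lo <- ceiling(k / 3)
  unique(round(seq(lo, k, length.out = min(sweep_points, k - lo + 1L))))
}

#' Train one binary cascade stage
#'
#' Sweeps the hidden-layer size over `ceiling(k/3) .. k` with several
#' seeded training executions per size (training on TG, early stopping on
#' VG) and returns the network with the highest MCC on SG.
#'
#' @param X standardized feature matrix (samples x kept features).
#' @param stroke_labels stroke count per sample.
#' @param split split tags from [split_dataset()].
#' @param target_t the stroke class this stage detects.
#' @param params a [cascade_params()].
#' @param seed stage seed (training-execution seeds derive from it).
#' @return object of class `gum_cascade_stage`: `target_t`, `h`, `weights`
#'   (`W1`, `W2`), `mcc_sg`, `suitable`, `threshold` (output firing
#'   threshold, 0.5), `seed`.
#' @export
train_stage <- function(X, stroke_labels, split, target_t,
                        params = cascade_params(), seed = 1L) {
  y <- as.integer(stroke_labels == target_t)
  k <- ncol(X)
  hs <- h_sweep_values(k, params$sweep_points)
  seeds <- derive_seeds(seed, length(hs) * params$restarts)
  Xtr <- X[split == "TG", , drop = FALSE]; ytr <- y[split == "TG"]
  Xvg <- X[split == "VG", , drop = FALSE]; yvg <- y[split == "VG"]
  Xsg <- X[split == "SG", , drop = FALSE]; ysg <- y[split == "SG"]
  best <- list(mcc = -Inf)
  i <- 0L
  for (h in hs) {
    for (r in seq_len(params$restarts)) {
      i <- i + 1L
      fit <- mlp_train_once(Xtr, ytr, Xvg, yvg, h, seeds[i],
                            decay = params$decay, chunk = params$chunk,
                            max_chunks = params$max_chunks,
                            patience = params$patience)
      if (is.null(fit$weights)) next
      pred <- mlp_forward(fit$weights, Xsg) > 0.5
      m <- tryCatch(mcc(binary_confusion(pred, ysg == 1)),
                    gummix_error = function(e) -Inf)
      if (m > best$mcc) {
        best <- list(mcc = m, weights = fit$weights, h = h, seed = seeds[i])
      }
      if (best$mcc >= 1) break
    }
    if (best$mcc >= 1) break
  }
  if (!is.finite(best$mcc)) {
    stop_gummix(sprintf("no trained network converged for class t=%d", target_t),
                "training")
  }
  structure(list(
    target_t = as.integer(target_t), h = best$h, weights = best$weights,
    mcc_sg = best$mcc, suitable = best$mcc > params$suitability_threshold,
    threshold = 0.5, seed = best$seed
  ), class = "gum_cascade_stage")
}

#' Assemble suitable stages into a binary cascade
#'
#' @param stages list of `gum_cascade_stage`, one per calibrated class.
#' @param kept_codes MFC codes of the input features, in order.
#' @param center,scale standardization applied to MP vectors before the
#'   networks see them (estimated on the Training Group).
#' @return object of class `gum_cascade`: stages ordered by ascending
#'   target stroke count. Fails (calibration failure) if any stage is
#'   missing or unsuitable.
#' @export
assemble_cascade <- function(stages, kept_codes, center, scale) {
  if (length(stages) == 0L) stop_gummix("no stages to assemble", "calibration")
  bad <- vapply(stages, function(s) !isTRUE(s$suitable), logical(1))
  if (any(bad)) {
    t_bad <- vapply(stages[bad], function(s) s$target_t, integer(1))
    stop_gummix(sprintf(
      "calibration failure: no suitable network for stroke class(es) %s (MCC <= threshold)",
      paste(t_bad, collapse = ", ")), "calibration")
  }
  ord <- order(vapply(stages, function(s) s$target_t, integer(1)))
  structure(list(stages = stages[ord], kept_codes = kept_codes,
                 center = center, scale = scale),
            class = "gum_cascade")
}

#' Classify an MP vector with the binary cascade
#'
#' Stages are queried in ascending stroke-count order; the first stage
#' whose binary output fires determines the predicted stroke count P. If no
#' stage fires the sample is UNCLASSIFIED (`NA`).
#'
#' @param mp named numeric MP vector (must contain every kept feature), or
#'   a matrix with MFC-coded columns (one prediction per row).
#' @param cascade a `gum_cascade`.
#' @return integer P (stroke count) per sample; `NA` = UNCLASSIFIED.
#' @export
classify_mp <- function(mp, cascade) {
  if (is.null(dim(mp))) mp <- matrix(mp, nrow = 1, dimnames = list(NULL, names(mp)))
  missing <- setdiff(cascade$kept_codes, colnames(mp))
  if (length(missing) > 0L) {
    stop_gummix(paste0("MP vector lacks required features: ",
                       paste(missing, collapse = ", ")), "feature_mismatch")
  }
  X <- mp[, cascade$kept_codes, drop = FALSE]
  X <- sweep(sweep(X, 2, cascade$center, "-"), 2, cascade$scale, "/")
  out <- rep(NA_integer_, nrow(X))
  undecided <- rep(TRUE, nrow(X))
  for (st in cascade$stages) {
    if (!any(undecided)) break
    p <- mlp_forward(st$weights, X[undecided, , drop = FALSE]) > st$threshold
    idx <- which(undecided)[p]
    out[idx] <- st$target_t
    undecided[idx] <- FALSE
  }
  out
}

#' Evaluate a cascade on labelled test rows
#'
#' @param cascade a `gum_cascade`.
#' @param mp MP matrix (rows = samples).
#' @param stroke_labels true stroke counts.
#' @return list with `per_stage` (data frame of binary confusions and MCC
#'   per stage over classified samples), `pooled` (micro-averaged TP/TN/
#'   FP/FN with global `mcc`, `sensitivity`, `specificity`, `accuracy`),
#'   `n_unclassified`, and `P` (the predictions).
#' @export
evaluate_cascade <- function(cascade, mp, stroke_labels) {
  if (length(stroke_labels) == 0L) stop_gummix("empty test set", "input")
  P <- classify_mp(mp, cascade)
  keep <- !is.na(P)
  n_un <- sum(!keep)
  if (!any(keep)) {
    return(list(per_stage = NULL, pooled = NULL, n_unclassified = n_un, P = P))
  }
  Pc <- P[keep]; tc <- stroke_labels[keep]
  per <- lapply(cascade$stages, function(st) {
    cc <- binary_confusion(Pc == st$target_t, tc == st$target_t)
    data.frame(target_t = st$target_t, tp = cc$tp, tn = cc$tn, fp = cc$fp,
               fn = cc$fn, mcc = mcc(cc))
  })
  per <- do.call(rbind, per)
  tot <- colSums(per[, c("tp", "tn", "fp", "fn")])
  pooled <- list(
    tp = tot[["tp"]], tn = tot[["tn"]], fp = tot[["fp"]], fn = tot[["fn"]],
    mcc = mcc(tot[["tp"]], tot[["tn"]], tot[["fp"]], tot[["fn"]]),
    sensitivity = tot[["tp"]] / (tot[["tp"]] + tot[["fn"]]),
    specificity = tot[["tn"]] / (tot[["tn"]] + tot[["fp"]]),
    accuracy = (tot[["tp"]] + tot[["tn"]]) / sum(tot)
  )
  list(per_stage = per, pooled = pooled, n_unclassified = n_un, P = P)
}

#' Train the full binary cascade from an MP table
#'
#' Splits the data 40/30/30 (stratified), standardizes the kept features
#' with Training-Group statistics, trains one stage per stroke class,
#' assembles the cascade and evaluates it on the Testing Group.
#'
#' @param mp MP matrix (rows = specimens, MFC-coded columns).
#' @param stroke_labels stroke count per row.
#' @param kept_codes feature codes to use (e.g. from [select_features()]).
#' @param params a [cascade_params()].
#' @param seed master seed (split and stage seeds derive from it).
#' @return list with `cascade`, `split`, `stages`, `evaluation` (the
#'   Testing-Group evaluation from [evaluate_cascade()]).
#' @export
train_cascade <- function(mp, stroke_labels, kept_codes,
                          params = cascade_params(), seed = 1L) {
  X <- as.matrix(mp)[, kept_codes, drop = FALSE]
  split <- split_dataset(stroke_labels, seed = seed)
  ctr <- colMeans(X[split == "TG", , drop = FALSE])
  scl <- apply(X[split == "TG", , drop = FALSE], 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  classes <- sort(unique(stroke_labels))
  seeds <- derive_seeds(seed + 13L, length(classes))
  stages <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    stages[[i]] <- train_stage(Xs, stroke_labels, split, classes[i],
                               params = params, seed = seeds[i])
  }
  cascade <- assemble_cascade(stages, kept_codes, ctr, scl)
  ev <- evaluate_cascade(cascade, as.matrix(mp)[split == "SG", , drop = FALSE],
                         stroke_labels[split == "SG"])
  list(cascade = cascade, split = split, stages = stages, evaluation = ev)
}
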