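# End-to-end orchestration: the calibration stage (specimens -> segmentation
# -> 121 features -> relevancy selection -> cascade training -> validation
# -> MEPAT) and the diagnosis stage (MEPAT + image pairs -> per-specimen
# ME). These functions are the programmatic interface behind the
# command-line wrapper shipped in inst/cli/gummix.R.

#' Calibration run configuration
#'
#' @param synthetic a [synthetic_config()] describing the reference dataset
#'   (set `specimen_dir` instead to calibrate from scanned images).
#' @param specimen_dir optional directory with PNG images and a
#'   `manifest.csv` (columns `specimen_id`, `side`, `t`, `path`) to
#'   calibrate from instead of generating synthetic specimens.
#' @param segmentation a [segment_params()].
#' @param training a [cascade_params()].
#' @param alpha significance level for the relevancy gamma term.
#' @param seed master run seed.
#' @param out_dir output directory for the MEPAT and CSV reports (`NULL` =
#'   in-memory only).
#' @param operator,institution operator metadata stored in the MEPAT OP
#'   block.
#' @return configuration list of class `gum_run_config`.
#' @export
calibration_config <- function(synthetic = synthetic_config(),
                               specimen_dir = NULL,
                               segmentation = segment_params(),
                               training = cascade_params(),
                               alpha = 0.05, seed = 42L, out_dir = NULL,
                               operator = "gummix", institution = "synthetic") {
  structure(list(synthetic = synthetic, specimen_dir = specimen_dir,
                 segmentation = segmentation, training = training,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 operator = operator, institution = institution),
            class = "gum_run_config")
}

load_specimen_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop_gummix("manifest.csv not found", "io")
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  ids <- unique(man$specimen_id)
  specs <- lapply(ids, function(id) {
    rows <- man[man$specimen_id == id, ]
    a <- rows[rows$side == "A", ][1, ]; b <- rows[rows$side == "B", ][1, ]
    structure(list(images = list(A = read_image(a$path), B = read_image(b$path)),
                   roi_truth = NULL, t = a$t,
                   subject_id = if ("subject_id" %in% names(rows)) a$subject_id else NA,
                   mixing_level = NA_real_, seed = NA_integer_),
              class = "gum_specimen")
  })
  manifest <- man[man$side == "A", setdiff(names(man), c("side", "path")),
                  drop = FALSE]
  structure(list(specimens = specs, manifest = manifest),
            class = "gum_specimen_set")
}

#' Run the full calibration stage
#'
#' Generates (or loads) the reference specimen set, segments every image,
#' extracts the 121-feature MP vectors, scores and selects features by
#' relevancy, trains the binary cascade, evaluates it on the held-out
#' Testing Group and packages everything as a MEPAT record. Fails loudly
#' (calibration-failure error) if any stroke class lacks a suitable
#' network.
#'
#' @param config a [calibration_config()].
#' @return list of class `gum_calibration`: `mepat`, `relevancy`,
#'   `evaluation`, `mp` (feature matrix), `split`, `manifest`, and
#'   `mepat_path`/report paths when `out_dir` is set.
#' @export
run_calibration <- function(config = calibration_config()) {
  set <- if (!is.null(config$specimen_dir)) {
    load_specimen_dir(config$specimen_dir)
  } else {
    generate_calibration_set(config$synthetic)
  }
  feats <- extract_mp_set(set, params = config$segmentation)
  rel <- select_features(feats$mp, feats$t, alpha = config$alpha)
  kept <- attr(rel, "kept_codes")
  if (length(kept) < 2L) {
    stop_gummix("calibration failure: fewer than 2 relevant features", "calibration")
  }
  fit <- train_cascade(feats$mp, feats$t, kept, params = config$training,
                       seed = config$seed)
  ev <- fit$evaluation
  ch <- data.frame(code = kept,
                   q = rel$q[match(kept, rel$code)],
                   center = as.numeric(fit$cascade$center),
                   scale = as.numeric(fit$cascade$scale),
                   stringsAsFactors = FALSE)
  cycles <- sort(unique(feats$t))
  mepat <- mepat_record(
    tf = list(brand = "synthetic two-layer wafer",
              colour_a = "red", colour_b = "white",
              dimensions_mm = c(38, 9, 5), colour_pair = "red-white"),
    es = list(cycles = cycles, dpi = 300, thickness_mm = 1,
              segmentation = unclass(config$segmentation)),
    ch = ch, cls = fit$cascade,
    op = list(name = config$operator, institution = config$institution),
    per = list(global = ev$pooled[c("mcc", "sensitivity", "specificity",
                                    "accuracy")] |>
                 c(list(n_unclassified = ev$n_unclassified)),
               per_stage = ev$per_stage[, c("target_t", "mcc")]),
    uid = uuid_v4(seed = config$seed + 101L)
  )
  out <- list(mepat = mepat, relevancy = rel, evaluation = ev,
              mp = feats$mp, split = fit$split, manifest = set$manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out$mepat_path <- file.path(config$out_dir, "calibration.mepat.xml")
    write_mepat(mepat, out$mepat_path)
    rel_path <- file.path(config$out_dir, "relevancy.csv")
    write.csv(as.data.frame(rel), rel_path, row.names = FALSE)
    perf_path <- file.path(config$out_dir, "performance.csv")
    write.csv(ev$per_stage, perf_path, row.names = FALSE)
    prov <- list(seed = config$seed, mepat_uid = mepat$uid,
                 n_specimens = nrow(set$manifest),
                 kept_features = length(kept),
                 global_mcc = ev$pooled$mcc,
                 r_version = as.character(getRversion()),
                 config_hash = unname(tools::md5sum(rel_path)))
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    out$report_paths <- c(rel_path, perf_path)
  }
  out
}

#' Run the diagnosis stage over a set of specimens
#'
#' @param mepat a `gum_mepat` or path to a `.mepat.xml`.
#' @param set a `gum_specimen_set` (e.g. from
#'   [generate_diagnosis_cohort()]) or a directory loadable like a
#'   calibration `specimen_dir`.
#' @param T applied stroke count (must be calibrated).
#' @param out_dir optional directory for a JSON-lines result file.
#' @return data frame, one row per specimen: `specimen_id`, `patient_id`
#'   (when present), `P`, `T`, `me`, `me_pct`, `tag`, `status`. Specimens
#'   whose segmentation fails are reported with status `"error"`; the run
#'   continues.
#' @export
run_diagnosis <- function(mepat, set, T = 20L, out_dir = NULL) {
  if (is.character(mepat)) mepat <- read_mepat(mepat)
  if (is.character(set)) set <- load_specimen_dir(set)
  rows <- lapply(seq_along(set$specimens), function(i) {
    sp <- set$specimens[[i]]
    id <- set$manifest$specimen_id[i]
    base <- data.frame(
      specimen_id = id,
      patient_id = if ("patient_id" %in% names(set$manifest))
        set$manifest$patient_id[i] else NA_character_,
      stringsAsFactors = FALSE)
    res <- tryCatch(
      diagnose(sp$images$A, sp$images$B, mepat, T = T, specimen_id = id),
      gummix_error = function(e) e)
    if (inherits(res, "gum_diagnosis")) {
      cbind(base, data.frame(P = ifelse(is.na(res$P), NA_integer_, res$P),
                             T = res$T, me = res$me, me_pct = res$me_pct,
                             tag = res$tag, status = res$status,
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, data.frame(P = NA_integer_, T = as.integer(T),
                             me = NA_real_, me_pct = NA_real_,
                             tag = NA_character_, status = "error",
                             stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "diagnosis.jsonl"), open = "wt")
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
    }
    close(con)
  }
  out
}

#' Per-patient ME summary over repeated tests
#'
#' Summarizes repeated diagnoses per patient by the highest ME observed
#' (the per-patient score used when comparing appointments).
#'
#' @param results a [run_diagnosis()] data frame.
#' @return data frame: `patient_id`, `me` (maximum over the patient's
#'   classified tests), `tag`.
#' @export
summarize_patients <- function(results) {
  ok <- results[results$status == "classified", ]
  if (nrow(ok) == 0L) stop_gummix("no classified results to summarize", "input")
  me <- tapply(ok$me, ok$patient_id, max)
  data.frame(patient_id = names(me), me = as.numeric(me),
             tag = me_tag(as.numeric(me)), stringsAsFactors = FALSE)
}
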