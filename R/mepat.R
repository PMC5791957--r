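# MEPAT — the portable calibration artefact. A MEPAT record bundles
# everything a clinic needs to run single diagnosis mixing-tests with a
# calibrated system: the test-food description (TF), experimental settings
# (ES), the selected feature set with extraction context (CH), the trained
# cascade (CLS), operator metadata (OP) and the validation performance
# block (PER), plus a UID and creation/upload timestamps. Records
# serialize to a custom XML dialect (shipped XSD: inst/extdata/mepat.xsd);
# weights are stored as decimal text with 17 significant digits so that a
# deserialized cascade reproduces bit-identical predictions.

#' Construct a MEPAT record
#'
#' @param tf list: test-food block (`brand`, `colour_a`, `colour_b`,
#'   `dimensions_mm`, `colour_pair`).
#' @param es list: experimental settings (`cycles`, `dpi`, `thickness_mm`,
#'   `segmentation` = list of [segment_params()] fields).
#' @param ch data frame: kept features — columns `code`, `q`, `center`,
#'   `scale` (the per-feature standardization of the cascade inputs).
#' @param cls a `gum_cascade`.
#' @param op list: operator metadata (`name`, `institution`).
#' @param per list: performance block (`global` = list with `mcc`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_unclassified`;
#'   `per_stage` = data frame `target_t`, `mcc`).
#' @param uid RFC-4122 UUID string (default: a fresh v4 UUID).
#' @param created,uploaded timestamp strings.
#' @return object of class `gum_mepat`.
#' @export
mepat_record <- function(tf, es, ch, cls, op, per,
                         uid = uuid_v4(),
                         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         uploaded = created) {
  rec <- structure(list(tf = tf, es = es, ch = ch, cls = cls, op = op,
                        per = per, uid = uid, created = created,
                        uploaded = uploaded),
                   class = "gum_mepat")
  validate_mepat(rec)
  rec
}

#' Validate a MEPAT record's invariants
#'
#' @param record a `gum_mepat`.
#' @return `record`, invisibly; otherwise a validation error listing the
#'   offending fields.
#' @export
validate_mepat <- function(record) {
  problems <- character()
  if (is.null(record$ch) || nrow(record$ch) == 0L) {
    problems <- c(problems, "CH: kept-feature block is empty")
  }
  if (is.null(record$cls) || !inherits(record$cls, "gum_cascade")) {
    problems <- c(problems, "CLS: missing trained cascade")
  } else if (!is.null(record$es$cycles) &&
             length(record$cls$stages) != length(record$es$cycles)) {
    problems <- c(problems, "CLS: stage count != |ES.cycles|")
  }
  if (is.null(record$uid) ||
      !grepl("^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$",
             record$uid)) {
    problems <- c(problems, "UID: not an RFC-4122 UUID")
  }
  if (length(problems) > 0L) {
    stop_gummix(paste0("invalid MEPAT record: ",
                       paste(problems, collapse = "; ")), "mepat_validation")
  }
  invisible(record)
}

#' Generate an RFC-4122 version-4 UUID
#'
#' @param seed optional seed for reproducible UIDs (provenance runs).
#' @return a UUID string.
#' @export
uuid_v4 <- function(seed = NULL) {
  draw <- function() sample.int(256L, 16L, replace = TRUE) - 1L
  b <- if (is.null(seed)) draw() else with_seed(seed, draw())
  b[7] <- bitwOr(bitwAnd(b[7], 0x0FL), 0x40L)  # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3FL), 0x80L)  # RFC variant
  hx <- sprintf("%02x", b)
  paste0(paste(hx[1:4], collapse = ""), "-", paste(hx[5:6], collapse = ""), "-",
         paste(hx[7:8], collapse = ""), "-", paste(hx[9:10], collapse = ""), "-",
         paste(hx[11:16], collapse = ""))
}

mepat_xsd_path <- function() {
  system.file("extdata", "mepat.xsd", package = "gummix", mustWork = TRUE)
}

num_vec_text <- function(x) paste(fmt_num(x), collapse = " ")

#' Write a MEPAT record to an XML file
#'
#' Produces a UTF-8 XML document following the package's MEPAT dialect and
#' checks it against the shipped XSD. Writing is canonical: the same record
#' always yields byte-identical files.
#'
#' @param record a valid `gum_mepat`.
#' @param path destination path (conventionally `*.mepat.xml`).
#' @return `path`, invisibly.
#' @export
write_mepat <- function(record, path) {
  validate_mepat(record)
  doc <- xml2::xml_new_root("mepat", uid = record$uid,
                            created = record$created,
                            uploaded = record$uploaded)
  tf <- xml2::xml_add_child(doc, "TF")
  for (f in names(record$tf)) {
    xml2::xml_add_child(tf, "item", name = f,
                        value = paste(as.character(record$tf[[f]]), collapse = " "))
  }
  es <- xml2::xml_add_child(doc, "ES")
  xml2::xml_add_child(es, "cycles", paste(record$es$cycles, collapse = " "))
  xml2::xml_add_child(es, "dpi", as.character(record$es$dpi))
  xml2::xml_add_child(es, "thickness_mm", fmt_num(record$es$thickness_mm))
  sg <- xml2::xml_add_child(es, "segmentation")
  sp <- record$es$segmentation
  for (f in c("spatial_bandwidth", "range_bandwidth", "dist_weight",
              "restarts", "seed")) {
    xml2::xml_add_child(sg, f, fmt_num(sp[[f]]))
  }
  xml2::xml_add_child(sg, "variant", sp$variant)
  ch <- xml2::xml_add_child(doc, "CH")
  for (i in seq_len(nrow(record$ch))) {
    xml2::xml_add_child(ch, "feature", code = record$ch$code[i],
                        q = fmt_num(record$ch$q[i]),
                        center = fmt_num(record$ch$center[i]),
                        scale = fmt_num(record$ch$scale[i]))
  }
  cls <- xml2::xml_add_child(doc, "CLS")
  for (st in record$cls$stages) {
    stn <- xml2::xml_add_child(cls, "stage",
                               target_t = as.character(st$target_t),
                               h = as.character(st$h),
                               k = as.character(nrow(st$weights$W1) - 1L),
                               threshold = fmt_num(st$threshold),
                               mcc_sg = fmt_num(st$mcc_sg),
                               seed = as.character(st$seed))
    xml2::xml_add_child(stn, "W1", num_vec_text(st$weights$W1))
    xml2::xml_add_child(stn, "W2", num_vec_text(st$weights$W2))
  }
  op <- xml2::xml_add_child(doc, "OP")
  for (f in names(record$op)) {
    xml2::xml_add_child(op, "item", name = f,
                        value = as.character(record$op[[f]]))
  }
  per <- xml2::xml_add_child(doc, "PER")
  g <- record$per$global
  xml2::xml_add_child(per, "global", mcc = fmt_num(g$mcc),
                      sensitivity = fmt_num(g$sensitivity),
                      specificity = fmt_num(g$specificity),
                      accuracy = fmt_num(g$accuracy),
                      n_unclassified = as.character(g$n_unclassified))
  if (!is.null(record$per$per_stage)) {
    for (i in seq_len(nrow(record$per$per_stage))) {
      xml2::xml_add_child(per, "stage",
                          target_t = as.character(record$per$per_stage$target_t[i]),
                          mcc = fmt_num(record$per$per_stage$mcc[i]))
    }
  }
  xml2::write_xml(doc, path)
  ok <- xml2::xml_validate(xml2::read_xml(path), xml2::read_xml(mepat_xsd_path()))
  if (!isTRUE(ok)) {
    stop_gummix(paste0("written MEPAT does not validate against the schema: ",
                       paste(attr(ok, "errors"), collapse = "; ")),
                "mepat_validation")
  }
  invisible(path)
}

parse_num_vec <- function(text, what) {
  x <- suppressWarnings(as.numeric(strsplit(trimws(text), "\\s+")[[1]]))
  if (length(x) == 0L || anyNA(x)) {
    stop_gummix(paste0("corrupted or truncated numeric block in MEPAT: ", what),
                "mepat_corrupt")
  }
  x
}

#' Read a MEPAT record from an XML file
#'
#' Validates the document against the shipped XSD, reconstructs the record
#' and the cascade; the deserialized cascade reproduces bit-identical
#' predictions to the one that was written.
#'
#' @param path path to a `*.mepat.xml` file.
#' @return a `gum_mepat`.
#' @export
read_mepat <- function(path) {
  if (!file.exists(path)) stop_gummix(paste0("no such file: ", path), "io")
  doc <- xml2::read_xml(path)
  ok <- xml2::xml_validate(doc, xml2::read_xml(mepat_xsd_path()))
  if (!isTRUE(ok)) {
    stop_gummix(paste0("MEPAT schema violation: ",
                       paste(attr(ok, "errors"), collapse = "; ")),
                "mepat_schema")
  }
  attr1 <- function(node, a) xml2::xml_attr(node, a)
  get1 <- function(node, xp) xml2::xml_find_first(node, xp)
  tf_nodes <- xml2::xml_find_all(doc, "./TF/item")
  tf <- stats::setNames(as.list(xml2::xml_attr(tf_nodes, "value")),
                        xml2::xml_attr(tf_nodes, "name"))
  es_node <- get1(doc, "./ES")
  sg_node <- get1(es_node, "./segmentation")
  seg <- list(
    spatial_bandwidth = as.numeric(xml2::xml_text(get1(sg_node, "./spatial_bandwidth"))),
    range_bandwidth = as.numeric(xml2::xml_text(get1(sg_node, "./range_bandwidth"))),
    dist_weight = as.numeric(xml2::xml_text(get1(sg_node, "./dist_weight"))),
    restarts = as.integer(as.numeric(xml2::xml_text(get1(sg_node, "./restarts")))),
    seed = as.integer(as.numeric(xml2::xml_text(get1(sg_node, "./seed")))),
    variant = xml2::xml_text(get1(sg_node, "./variant"))
  )
  es <- list(
    cycles = as.integer(parse_num_vec(xml2::xml_text(get1(es_node, "./cycles")), "ES/cycles")),
    dpi = as.numeric(xml2::xml_text(get1(es_node, "./dpi"))),
    thickness_mm = as.numeric(xml2::xml_text(get1(es_node, "./thickness_mm"))),
    segmentation = seg
  )
  ch_nodes <- xml2::xml_find_all(doc, "./CH/feature")
  codes <- xml2::xml_attr(ch_nodes, "code")
  known <- c(mfc_registry()$code)
  unknown <- setdiff(codes, known)
  if (length(unknown) > 0L) {
    stop_gummix(paste0("unknown MFC code(s) in MEPAT CH: ",
                       paste(unknown, collapse = ", ")), "mepat_unknown_code")
  }
  ch <- data.frame(code = codes,
                   q = as.numeric(xml2::xml_attr(ch_nodes, "q")),
                   center = as.numeric(xml2::xml_attr(ch_nodes, "center")),
                   scale = as.numeric(xml2::xml_attr(ch_nodes, "scale")),
                   stringsAsFactors = FALSE)
  stage_nodes <- xml2::xml_find_all(doc, "./CLS/stage")
  stages <- lapply(stage_nodes, function(sn) {
    k <- as.integer(attr1(sn, "k")); h <- as.integer(attr1(sn, "h"))
    w1 <- parse_num_vec(xml2::xml_text(get1(sn, "./W1")), "stage W1")
    w2 <- parse_num_vec(xml2::xml_text(get1(sn, "./W2")), "stage W2")
    if (length(w1) != (k + 1L) * h || length(w2) != h + 1L) {
      stop_gummix("truncated weight block in MEPAT stage", "mepat_corrupt")
    }
    structure(list(
      target_t = as.integer(attr1(sn, "target_t")), h = h,
      weights = list(W1 = matrix(w1, nrow = k + 1L), W2 = w2, k = k, h = h),
      mcc_sg = as.numeric(attr1(sn, "mcc_sg")),
      suitable = TRUE, threshold = as.numeric(attr1(sn, "threshold")),
      seed = as.integer(attr1(sn, "seed"))
    ), class = "gum_cascade_stage")
  })
  cascade <- structure(list(stages = stages, kept_codes = ch$code,
                            center = stats::setNames(ch$center, ch$code),
                            scale = stats::setNames(ch$scale, ch$code)),
                       class = "gum_cascade")
  op_nodes <- xml2::xml_find_all(doc, "./OP/item")
  op <- stats::setNames(as.list(xml2::xml_attr(op_nodes, "value")),
                        xml2::xml_attr(op_nodes, "name"))
  g_node <- get1(doc, "./PER/global")
  per_stage_nodes <- xml2::xml_find_all(doc, "./PER/stage")
  per <- list(
    global = list(mcc = as.numeric(attr1(g_node, "mcc")),
                  sensitivity = as.numeric(attr1(g_node, "sensitivity")),
                  specificity = as.numeric(attr1(g_node, "specificity")),
                  accuracy = as.numeric(attr1(g_node, "accuracy")),
                  n_unclassified = as.integer(attr1(g_node, "n_unclassified"))),
    per_stage = if (length(per_stage_nodes) > 0L) {
      data.frame(target_t = as.integer(xml2::xml_attr(per_stage_nodes, "target_t")),
                 mcc = as.numeric(xml2::xml_attr(per_stage_nodes, "mcc")))
    }
  )
  root <- xml2::xml_find_first(doc, "/mepat")
  mepat_record(tf = tf, es = es, ch = ch, cls = cascade, op = op, per = per,
               uid = attr1(root, "uid"), created = attr1(root, "created"),
               uploaded = attr1(root, "uploaded"))
}
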