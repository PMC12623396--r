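# Declarative model definitions and per-subject configurations.
#
# A model definition (XML) lists the marker set (with type, class, segment
# and, for hosted landmarks, the host technical cluster), the technical
# clusters, the coordinate-system recipes, the kinematic chain and the
# segment-orientation list, using side placeholders: {s}/{p} for the
# prosthetic side (upper/lower case prefix) and {c}/{q} for the sound
# side. Building a configuration resolves the placeholders for a specific
# subject (amputation level, prosthetic side, RPF shape, anthropometrics).

.recipe_registry <- list(
  pelvis       = list(n_inputs = 4L, sided = FALSE),
  socket       = list(n_inputs = 5L, sided = TRUE),
  socket_clamp = list(n_inputs = 4L, sided = TRUE),
  foot_clamp_C = list(n_inputs = 4L, sided = TRUE),
  foot_clamp_J = list(n_inputs = 4L, sided = TRUE),
  knee_pk      = list(n_inputs = 2L, sided = TRUE, depends = TRUE),
  knee_dk      = list(n_inputs = 2L, sided = TRUE, depends = TRUE),
  distal_rpf   = list(n_inputs = 3L, sided = TRUE),
  technical_fp = list(n_inputs = 3L, sided = FALSE),
  hjc_k        = list(n_inputs = 3L, sided = TRUE),
  gt_kl        = list(n_inputs = 2L, sided = TRUE),
  thigh        = list(n_inputs = 3L, sided = TRUE),
  shank        = list(n_inputs = 4L, sided = TRUE),
  foot         = list(n_inputs = 3L, sided = TRUE)
)

.attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

.split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ",")[[1L]])
}

#' Load a model definition from XML
#'
#' Parses and validates a model-definition file: every recipe input and
#' cluster member must appear in the marker table, every chain endpoint
#' must have a frame recipe, and Cardan sequences must be one of
#' zxy / zyx / rpy.
#'
#' @param path Path to a model XML file, or one of the bundled shorthands
#'   `"TF"` / `"TT"`.
#' @return Object of class `rsp_model`.
#' @export
load_model_definition <- function(path) {
  if (path %in% c("TF", "TT")) {
    path <- system.file("extdata", "models",
                        paste0("model_", tolower(path), ".xml"),
                        package = "rspkin", mustWork = TRUE)
  }
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  stopifnot(xml2::xml_name(root) == "model")
  level <- xml2::xml_attr(root, "level")
  if (!level %in% c("TF", "TT")) stop("schema error: level must be TF or TT")

  mk <- xml2::xml_find_all(doc, ".//markers/marker")
  markers <- data.frame(
    name = xml2::xml_attr(mk, "name"),
    type = xml2::xml_attr(mk, "type"),
    class = xml2::xml_attr(mk, "class"),
    segment = xml2::xml_attr(mk, "segment"),
    host = vapply(mk, .attr_or, "", name = "host", default = ""),
    stringsAsFactors = FALSE
  )
  if (!all(markers$type %in% c("anatomical", "mechanical", "technical"))) {
    stop("schema error: unknown marker type")
  }
  if (!all(markers$class %in% c("permanent", "static", "wand", "virtual"))) {
    stop("schema error: unknown marker class")
  }
  if (anyDuplicated(markers$name)) {
    stop("schema error: duplicate marker names")
  }

  cl <- xml2::xml_find_all(doc, ".//clusters/cluster")
  clusters <- stats::setNames(
    lapply(cl, function(n) .split_csv(xml2::xml_attr(n, "markers"))),
    xml2::xml_attr(cl, "segment"))

  fr <- xml2::xml_find_all(doc, ".//frames/frame")
  frames <- data.frame(
    tag = xml2::xml_attr(fr, "tag"),
    recipe = xml2::xml_attr(fr, "recipe"),
    inputs = xml2::xml_attr(fr, "inputs"),
    depends = vapply(fr, .attr_or, "", name = "depends", default = ""),
    side = xml2::xml_attr(fr, "side"),
    stringsAsFactors = FALSE
  )
  jn <- xml2::xml_find_all(doc, ".//chain/joint")
  chain <- data.frame(
    name = xml2::xml_attr(jn, "name"),
    prox = xml2::xml_attr(jn, "prox"),
    dist = xml2::xml_attr(jn, "dist"),
    sequence = xml2::xml_attr(jn, "sequence"),
    flip = xml2::xml_attr(jn, "flip"),
    stringsAsFactors = FALSE
  )
  orient <- .split_csv(xml2::xml_attr(
    xml2::xml_find_first(doc, ".//orientations"), "tags"))

  model <- structure(list(
    name = xml2::xml_attr(root, "name"),
    level = level,
    rpf_shapes = .split_csv(xml2::xml_attr(root, "rpf_shapes")),
    markers = markers, clusters = clusters, frames = frames,
    chain = chain, orientations = orient
  ), class = "rsp_model")
  .validate_model(model)
  model
}

.validate_model <- function(model) {
  known <- model$markers$name
  for (i in seq_len(nrow(model$frames))) {
    f <- model$frames[i, ]
    reg <- .recipe_registry[[f$recipe]]
    if (is.null(reg)) stop("schema error: unknown recipe '", f$recipe, "'")
    ins <- .split_csv(f$inputs)
    if (length(ins) != reg$n_inputs) {
      stop("schema error: recipe ", f$recipe, " takes ", reg$n_inputs,
           " inputs, got ", length(ins))
    }
    missing <- setdiff(ins, known)
    if (length(missing)) {
      stop("schema error: recipe for ", f$tag,
           " references unknown marker(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (seg in names(model$clusters)) {
    missing <- setdiff(model$clusters[[seg]], known)
    if (length(missing)) {
      stop("schema error: cluster ", seg, " references unknown marker(s): ",
           paste(missing, collapse = ", "))
    }
  }
  tags <- model$frames$tag
  for (i in seq_len(nrow(model$chain))) {
    j <- model$chain[i, ]
    if (!j$sequence %in% c("zxy", "zyx", "rpy")) {
      stop("schema error: joint ", j$name, ": unknown sequence ", j$sequence)
    }
    miss <- setdiff(c(j$prox, j$dist), tags)
    if (length(miss)) {
      stop("schema error: joint ", j$name, " references unknown frame(s): ",
           paste(miss, collapse = ", "))
    }
  }
  miss <- setdiff(model$orientations, tags)
  if (length(miss)) {
    stop("schema error: orientation tags without recipe: ",
         paste(miss, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.rsp_model <- function(x, ...) {
  cat("<rsp_model> ", x$name, " (", x$level, "): ", nrow(x$markers),
      " markers, ", nrow(x$frames), " frames, ", nrow(x$chain),
      " joints\n", sep = "")
  invisible(x)
}

.expand_side <- function(x, side) {
  other <- if (side == "L") "R" else "L"
  x <- gsub("{s}", side, x, fixed = TRUE)
  x <- gsub("{c}", other, x, fixed = TRUE)
  x <- gsub("{p}", tolower(side), x, fixed = TRUE)
  gsub("{q}", tolower(other), x, fixed = TRUE)
}

#' Build a subject configuration from a model definition
#'
#' Resolves side placeholders for the subject's prosthetic side, checks
#' level/shape compatibility, and derives the lookup maps the pipeline
#' needs: technical clusters, hosted-landmark map, wand-calibrated and
#' static-only marker lists, and the kinematic chain.
#'
#' A configuration is uniquely identified by (subject id, session date);
#' re-registration after a marker detaches is an update (see
#' [update_configuration()]), not a new configuration.
#'
#' @param model `rsp_model`.
#' @param subject_id Subject identifier.
#' @param session_date Session date string (e.g. "2026-01-15").
#' @param side Prosthetic side, "L" or "R".
#' @param rpf_shape "C" or "J"; must be offered by the model.
#' @param anthropometrics Named list; `inter_asis` (mm) enables the hip
#'   joint centre regression.
#' @param hjc_coefficients Regression coefficients, see [hjc_regression()].
#' @return Object of class `rsp_configuration`.
#' @export
build_configuration <- function(model, subject_id, session_date,
                                side = c("L", "R"), rpf_shape = NULL,
                                anthropometrics = list(inter_asis = 240),
                                hjc_coefficients = c(-0.19, -0.30, 0.36)) {
  side <- match.arg(side)
  if (is.null(rpf_shape)) rpf_shape <- model$rpf_shapes[1L]
  if (!rpf_shape %in% model$rpf_shapes) {
    stop("validation error: RPF shape ", rpf_shape, " not available for ",
         model$level, " model (offers: ",
         paste(model$rpf_shapes, collapse = ","), ")")
  }
  ex <- function(x) .expand_side(x, side)

  markers <- model$markers
  markers$name <- ex(markers$name)
  markers$host <- ex(markers$host)
  clusters <- lapply(model$clusters, ex)
  frames <- model$frames
  frames$tag <- ex(frames$tag)
  frames$inputs <- ex(frames$inputs)
  frames$depends <- ex(frames$depends)
  frames$side <- vapply(model$frames$side, function(sd) {
    switch(sd, prosthetic = side, sound = if (side == "L") "R" else "L",
           none = "R", stop("unknown frame side tag: ", sd))
  }, "")
  chain <- model$chain
  chain$name <- ex(chain$name)
  chain$prox <- ex(chain$prox)
  chain$dist <- ex(chain$dist)
  chain$side <- ifelse(grepl(paste0("^", tolower(side)), chain$name),
                       side, if (side == "L") "R" else "L")

  hosted <- stats::setNames(as.list(markers$host[nzchar(markers$host)]),
                            markers$name[nzchar(markers$host)])
  wand_landmarks <- markers$name[markers$class == "wand"]
  static_markers <- markers$name[markers$class == "static"]
  fc_markers <- markers$name[markers$segment == "foot_clamp" &
                               markers$class == "permanent"]
  hjc_names <- markers$name[markers$class == "virtual" &
                              grepl("HJC$", markers$name)]
  hjc_sides <- substr(hjc_names, 1L, 1L)

  structure(list(
    subject_id = subject_id, session_date = session_date, revision = 1L,
    static_ref = NA_character_, recalibrate = character(),
    level = model$level, side = side, rpf_shape = rpf_shape,
    model_name = model$name,
    markers = markers, clusters = clusters, frames = frames, chain = chain,
    orientations = ex(model$orientations),
    hosted = hosted, wand_landmarks = wand_landmarks,
    static_markers = static_markers, fc_markers = fc_markers,
    hjc_sides = hjc_sides,
    anthropometrics = anthropometrics,
    hjc_coefficients = hjc_coefficients
  ), class = "rsp_configuration")
}

#' @export
print.rsp_configuration <- function(x, ...) {
  cat("<rsp_configuration> subject ", x$subject_id, " @ ", x$session_date,
      " rev ", x$revision, "\n  ", x$level, ", prosthetic side ", x$side,
      ", RPF shape ", x$rpf_shape, "; ", nrow(x$markers), " markers, ",
      nrow(x$chain), " joints\n", sep = "")
  if (length(x$recalibrate)) {
    cat("  needs recalibration:", paste(x$recalibrate, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Update a configuration after a new static acquisition
#'
#' A new static trial within the same session (e.g. after a marker
#' detached and was repositioned) is an updated registration of the same
#' configuration, not a new one: identity (subject, date) and prosthesis
#' set-up are preserved, the revision counter is incremented, and any wand
#' landmark hosted on a cluster containing a detached marker is flagged
#' for recalibration. Changing level, side or RPF shape requires a new
#' configuration and is refused.
#'
#' @param config `rsp_configuration`.
#' @param new_static_id Identifier of the new static trial.
#' @param detached Labels of markers that detached (may be empty).
#' @param level,side,rpf_shape Optionally passed to assert identity; any
#'   change is an error.
#' @return Updated `rsp_configuration` (revision incremented).
#' @export
update_configuration <- function(config, new_static_id,
                                 detached = character(),
                                 level = config$level, side = config$side,
                                 rpf_shape = config$rpf_shape) {
  if (!identical(level, config$level) || !identical(side, config$side) ||
      !identical(rpf_shape, config$rpf_shape)) {
    stop("new configuration required: amputation level, side and RPF ",
         "shape cannot change in an update")
  }
  config$revision <- config$revision + 1L
  config$static_ref <- new_static_id
  recal <- character()
  for (seg in names(config$clusters)) {
    if (any(detached %in% config$clusters[[seg]])) {
      hosted_here <- names(config$hosted)[unlist(config$hosted) == seg]
      recal <- c(recal, intersect(hosted_here, config$wand_landmarks))
    }
  }
  config$recalibrate <- unique(recal)
  config
}

#' Serialize a configuration to XML
#' @param config `rsp_configuration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(config, path) {
  doc <- xml2::xml_new_root(
    "configuration",
    subject = config$subject_id, date = config$session_date,
    revision = as.character(config$revision),
    level = config$level, side = config$side, rpf_shape = config$rpf_shape,
    model = config$model_name,
    static_ref = ifelse(is.na(config$static_ref), "", config$static_ref)
  )
  an <- xml2::xml_add_child(doc, "anthropometrics")
  for (nm in names(config$anthropometrics)) {
    xml2::xml_add_child(an, "value", name = nm,
                        mm = as.character(config$anthropometrics[[nm]]))
  }
  xml2::xml_add_child(doc, "hjc_coefficients",
                      value = paste(config$hjc_coefficients, collapse = ","))
  if (length(config$recalibrate)) {
    xml2::xml_add_child(doc, "recalibrate",
                        markers = paste(config$recalibrate, collapse = ","))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load a configuration from XML
#'
#' Rebuilds the full configuration by re-expanding the named bundled model
#' with the stored options, then restoring revision and recalibration
#' state.
#' @param path Path written by [write_configuration()].
#' @return `rsp_configuration`.
#' @export
load_configuration <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  stopifnot(xml2::xml_name(root) == "configuration")
  level <- xml2::xml_attr(root, "level")
  anv <- xml2::xml_find_all(doc, ".//anthropometrics/value")
  anthro <- stats::setNames(
    lapply(anv, function(n) as.numeric(xml2::xml_attr(n, "mm"))),
    xml2::xml_attr(anv, "name"))
  coefs <- as.numeric(.split_csv(xml2::xml_attr(
    xml2::xml_find_first(doc, ".//hjc_coefficients"), "value")))
  config <- build_configuration(
    load_model_definition(level),
    subject_id = xml2::xml_attr(root, "subject"),
    session_date = xml2::xml_attr(root, "date"),
    side = xml2::xml_attr(root, "side"),
    rpf_shape = xml2::xml_attr(root, "rpf_shape"),
    anthropometrics = anthro, hjc_coefficients = coefs
  )
  config$revision <- as.integer(xml2::xml_attr(root, "revision"))
  sref <- xml2::xml_attr(root, "static_ref")
  config$static_ref <- if (is.na(sref) || !nzchar(sref)) NA_character_
                       else sref
  rec <- xml2::xml_find_first(doc, ".//recalibrate")
  if (!inherits(rec, "xml_missing")) {
    config$recalibrate <- .split_csv(xml2::xml_attr(rec, "markers"))
  }
  config
}

#' Export a configuration as JSON (for inspection)
#' @param config `rsp_configuration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_configuration_json <- function(config, path) {
  jsonlite::write_json(
    list(subject = config$subject_id, date = config$session_date,
         revision = config$revision, level = config$level,
         side = config$side, rpf_shape = config$rpf_shape,
         markers = config$markers, clusters = config$clusters,
         chain = config$chain, anthropometrics = config$anthropometrics),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
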