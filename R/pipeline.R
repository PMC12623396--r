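# Three-step processing pipeline mirroring the protocol software flow:
# configurator (model -> subject configuration), static processor
# (static + wand trials -> processed static trial, optionally an updated
# configuration), and trial analyzer (dynamic trials -> enriched C3D +
# normalized-cycle summaries). The CLI in exec/rspkin wraps these
# one-for-one.

#' Configure a session
#'
#' Builds a subject configuration from a bundled model definition and
#' writes it as an XML configuration file.
#'
#' @param level "TF" or "TT" (bundled model), or a path to a model XML.
#' @param subject_id,session_date Configuration identity.
#' @param side Prosthetic side "L"/"R".
#' @param rpf_shape "C"/"J" (default: the model's).
#' @param inter_asis Inter-ASIS distance (mm).
#' @param out Output configuration path (optional).
#' @return `rsp_configuration`, invisibly if `out` given.
#' @export
configure_session <- function(level, subject_id, session_date, side = "L",
                              rpf_shape = NULL, inter_asis = 240,
                              out = NULL) {
  model <- load_model_definition(level)
  config <- build_configuration(
    model, subject_id = subject_id, session_date = session_date,
    side = side, rpf_shape = rpf_shape,
    anthropometrics = list(inter_asis = inter_asis))
  if (!is.null(out)) {
    write_configuration(config, out)
    message("configuration rev ", config$revision, " written to ", out)
    return(invisible(config))
  }
  config
}

#' Process the static session
#'
#' Runs wand-tip localization on every wand trial, localizes all wand
#' landmarks and static-only markers in their host clusters, adds the
#' regression hip joint centres, and assembles the processed static trial
#' embedding all physical, virtual and calibrated reconstructed markers.
#'
#' @param config `rsp_configuration`.
#' @param static_trial `rsp_trial` (or C3D path) of the standing trial.
#' @param wand_trials Named list of `rsp_trial` (or paths), keyed by
#'   landmark label.
#' @param geometry `wand_geometry` (default shipped wand).
#' @param out Optional output C3D path for the processed static.
#' @return Processed static `rsp_trial` (with attribute `"landmarks"`).
#' @export
process_static_trial <- function(config, static_trial, wand_trials = list(),
                                 geometry = default_wand_geometry(),
                                 out = NULL) {
  if (is.character(static_trial)) static_trial <- read_trial(static_trial)
  wand_trials <- lapply(wand_trials, function(w) {
    if (is.character(w)) read_trial(w) else w
  })
  missing <- setdiff(config$wand_landmarks, names(wand_trials))
  if (length(missing)) {
    stop("missing wand trial(s) for declared landmark(s): ",
         paste(missing, collapse = ", "))
  }
  wand_results <- lapply(wand_trials, wand_tip, geometry = geometry)
  processed <- build_processed_static(static_trial, wand_results, config)
  if (!is.null(out)) {
    lmks <- attr(processed, "landmarks")
    write_trial(processed, out)
    attr(processed, "landmarks") <- lmks
  }
  processed
}

#' Analyze a dynamic trial
#'
#' Reconstructs all hosted landmarks with per-frame SVD cluster fits
#' (with the FP-triad fallback for foot-clamp markers), constructs every
#' protocol coordinate system, computes chain joint angles and segment
#' orientations, static reference angles (reported, never subtracted),
#' stride/stance-normalized cycles, RPF compression and mean running
#' speed.
#'
#' @param config `rsp_configuration`.
#' @param processed_static Processed static `rsp_trial` (or path).
#' @param dynamic_trial Dynamic `rsp_trial` (or path).
#' @param out_c3d Optional path for the enriched C3D.
#' @param out_csv Optional path for the tidy normalized-cycle CSV.
#' @return List: `trial` (reconstructed), `frames`, `kinematics`,
#'   `static_reference`, `strides`, `cycles` (tidy data frame), `speed`
#'   (m/s), `compression`, `residuals` (per-segment fit rms, mm).
#' @export
analyze_trial <- function(config, processed_static, dynamic_trial,
                          out_c3d = NULL, out_csv = NULL) {
  if (is.character(processed_static)) {
    processed_static <- read_trial(processed_static)
  }
  if (is.character(dynamic_trial)) dynamic_trial <- read_trial(dynamic_trial)

  recon <- reconstruct_markers(dynamic_trial, processed_static, config)
  recon <- fallback_fc_from_fp(recon, processed_static, config)
  frames <- compute_frames(recon, config)
  kin <- compute_kinematics(recon, config, frames)
  static_ref <- static_reference(processed_static, config)
  strides <- suppressWarnings(get_strides(recon, config$side))
  speed <- mean_running_speed(recon, frames[["PL"]])

  fp_tag <- paste0(config$side, "FP")
  comp <- NULL
  if (fp_tag %in% names(frames)) {
    comp <- rpf_compression(recon, frames[[fp_tag]],
                            paste0(config$side, "FDA"),
                            reference = rpf_static_length(processed_static,
                                                          config))
  }

  cycles <- .cycles_table(kin, strides, config$side)

  if (!is.null(out_c3d)) {
    extra <- recon$points[setdiff(names(recon$points),
                                  names(dynamic_trial$points))]
    write_enriched(dynamic_trial, extra, kin, out_c3d)
  }
  if (!is.null(out_csv)) {
    utils::write.csv(cycles, out_csv, row.names = FALSE)
  }
  list(trial = recon, frames = frames, kinematics = kin,
       static_reference = static_ref, strides = strides, cycles = cycles,
       speed = speed, compression = comp,
       residuals = attr(recon, "residuals"))
}

# tidy long table: one row per joint x stride x domain x percent
.cycles_table <- function(kin, strides, side) {
  rows <- list()
  for (a in kin) {
    for (k in seq_along(strides)) {
      for (domain in c("stride", "stance")) {
        nc <- suppressWarnings(normalize_cycle(a, strides[[k]], domain))
        rows[[length(rows) + 1L]] <- data.frame(
          joint = a$name, side = a$side, stride = k, domain = domain,
          percent = nc$percent, a1 = nc$values[, 1L], a2 = nc$values[, 2L],
          a3 = nc$values[, 3L],
          foot_off_pct = nc$foot_off_pct
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(joint = character(), side = character(),
                      stride = integer(), domain = character(),
                      percent = integer(), a1 = numeric(), a2 = numeric(),
                      a3 = numeric(), foot_off_pct = numeric()))
  }
  do.call(rbind, rows)
}
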