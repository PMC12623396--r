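# C3D trial container and binary I/O.
#
# C3D is the de-facto standard container for marker-based motion capture:
# a 512-byte header block, a parameter section (grouped key/value records)
# and a frame-by-frame 3D point data section. This reader/writer covers the
# subset needed for kinematic processing: labelled 3D points (float or
# integer storage, mm or m), point rate, first/last frame, and the EVENT
# parameter group (foot-strike / foot-off with Left/Right context). Intel
# processor type (84) only, which is what every current acquisition system
# writes.

#' Construct a motion-capture trial
#'
#' A trial holds labelled marker trajectories in mm, the point sample rate,
#' the first-frame index and the gait events. Occluded/invalid samples are
#' encoded as `NA` rows in the marker matrices.
#'
#' @param points Named list of n x 3 numeric matrices (mm); all the same
#'   number of rows. `NA` rows mark invalid (occluded) samples.
#' @param rate Point sample rate in Hz (> 0).
#' @param events Data frame with columns `context` ("Left"/"Right"/"General"),
#'   `label` ("foot_strike"/"foot_off") and `time` (seconds from the first
#'   frame of the trial). May be empty.
#' @param first_frame Index of the first frame as recorded (default 1).
#' @param units Point units; must be convertible to mm ("mm" or "m").
#' @return Object of class `rsp_trial`.
#' @export
new_trial <- function(points, rate, events = empty_events(),
                      first_frame = 1L, units = "mm") {
  stopifnot(is.list(points), length(points) > 0L, rate > 0)
  labels <- names(points)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("validation error: marker labels must be unique and non-empty")
  }
  nf <- nrow(points[[1L]])
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 3L)
    if (nrow(p) != nf) stop("validation error: trajectories differ in length")
    storage.mode(p) <- "double"
    # a sample is valid only if all three coordinates are finite
    bad <- !stats::complete.cases(p) | !is.finite(rowSums(p))
    p[bad, ] <- NA_real_
    p
  })
  if (units == "m") {
    points <- lapply(points, function(p) p * 1000)
    units <- "mm"
  } else if (units != "mm") {
    stop("validation error: units must be 'mm' or 'm', got '", units, "'")
  }
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(c("context", "label", "time") %in% names(events)))
    span <- (nf - 1) / rate
    # 0.1 ms slack absorbs float32 storage rounding of event times
    if (any(events$time < -1e-4 | events$time > span + 1e-4)) {
      stop("validation error: event times outside trial span")
    }
    events$time <- pmin(pmax(events$time, 0), span)
  }
  structure(list(points = points, rate = as.numeric(rate),
                 first_frame = as.integer(first_frame),
                 events = events, units = "mm"),
            class = "rsp_trial")
}

#' @rdname new_trial
#' @export
empty_events <- function() {
  data.frame(context = character(), label = character(), time = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.rsp_trial <- function(x, ...) {
  cat("<rsp_trial> ", length(x$points), " markers x ", n_frames(x),
      " frames @ ", x$rate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Number of frames in a trial
#' @param trial `rsp_trial`.
#' @export
n_frames <- function(trial) nrow(trial$points[[1L]])

#' Validity mask of one marker
#' @param trial `rsp_trial`.
#' @param label Marker label.
#' @return Logical vector, one element per frame.
#' @export
marker_valid <- function(trial, label) {
  p <- trial$points[[label]]
  if (is.null(p)) stop("no such marker: ", label)
  stats::complete.cases(p)
}

#' Frame index of an event time
#'
#' Events are stored in seconds from the first frame; samples are indexed
#' from 1, so frame = round(time * rate) + 1.
#' @param trial `rsp_trial`.
#' @param time Seconds.
#' @export
event_frame <- function(trial, time) as.integer(round(time * trial$rate)) + 1L

## ---------------------------------------------------------------------------
## binary plumbing

.c3d_read_bin <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("format error: not a C3D file: ", path)
  readBin(path, "raw", n = sz)
}

.r_int16 <- function(raw, at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                                      signed = TRUE, endian = "little")
.r_uint8 <- function(raw, at) as.integer(raw[at])
.r_int8 <- function(raw, at) {
  v <- as.integer(raw[at]); ifelse(v > 127L, v - 256L, v)
}
.r_float <- function(raw, at, n = 1L) {
  readBin(raw[at:(at + 4L * n - 1L)], "double", n = n, size = 4L,
          endian = "little")
}

#' Read a C3D trial
#'
#' Loads all labelled 3D points, flags invalid/occluded samples (negative
#' residual or missing data), converts meters to millimeters, and reads the
#' EVENT parameter group into the trial's event table.
#'
#' @param path Path to a `.c3d` file.
#' @return `rsp_trial`.
#' @export
read_trial <- function(path) {
  raw <- .c3d_read_bin(path)
  if (.r_uint8(raw, 2L) != 0x50) stop("format error: missing C3D magic byte")
  param_block <- .r_uint8(raw, 1L)
  npoints_hdr <- .r_int16(raw, 3L)
  first_frame <- .r_int16(raw, 7L)
  last_frame <- .r_int16(raw, 9L)

  poff <- (param_block - 1L) * 512L
  proc <- .r_uint8(raw, poff + 4L)
  if (proc != 84L) {
    stop("format error: unsupported processor type ", proc,
         " (only Intel/84 supported)")
  }
  params <- .c3d_parse_params(raw, poff)
  pt <- params$POINT
  if (is.null(pt)) stop("format error: no POINT group")
  used <- pt$USED
  rate <- pt$RATE
  scale <- pt$SCALE
  data_start <- pt$DATA_START
  nframes <- pt$FRAMES
  if (is.null(nframes)) nframes <- last_frame - first_frame + 1L
  labels <- .c3d_char_matrix(pt$LABELS)
  units <- if (is.null(pt$UNITS)) "mm" else
    tolower(trimws(.c3d_char_matrix(pt$UNITS)))[1L]
  if (length(labels) < used) stop("format error: fewer labels than POINT:USED")
  labels <- trimws(labels[seq_len(used)])
  if (anyDuplicated(labels)) {
    stop("validation error: duplicate point labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }

  doff <- (data_start - 1L) * 512L
  float_data <- scale < 0
  nw <- 4L * used # x, y, z, residual words per frame
  if (float_data) {
    vals <- .r_float(raw, doff + 1L, n = nw * nframes)
  } else {
    vals <- readBin(raw[(doff + 1L):(doff + 2L * nw * nframes)], "integer",
                    n = nw * nframes, size = 2L, signed = TRUE,
                    endian = "little")
  }
  arr <- array(vals, dim = c(4L, used, nframes))
  points <- vector("list", used)
  names(points) <- labels
  for (i in seq_len(used)) {
    xyz <- t(arr[1:3, i, , drop = TRUE])
    if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L)
    resid <- arr[4L, i, ]
    if (!float_data) xyz <- xyz * abs(scale)
    xyz[resid < 0, ] <- NA_real_
    points[[i]] <- xyz
  }

  events <- empty_events()
  ev <- params$EVENT
  if (!is.null(ev) && !is.null(ev$USED) && ev$USED > 0L) {
    nev <- ev$USED
    ctx <- trimws(.c3d_char_matrix(ev$CONTEXTS))[seq_len(nev)]
    lab <- trimws(.c3d_char_matrix(ev$LABELS))[seq_len(nev)]
    tm <- matrix(ev$TIMES, nrow = 2L)[, seq_len(nev), drop = FALSE]
    secs <- tm[1L, ] * 60 + tm[2L, ]
    events <- data.frame(context = ctx,
                         label = .normalize_event_label(lab),
                         time = secs - (first_frame - 1L) / rate,
                         stringsAsFactors = FALSE)
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  new_trial(points, rate = rate, events = events,
            first_frame = first_frame, units = units)
}

.normalize_event_label <- function(lab) {
  out <- tolower(gsub("[ _-]+", "_", trimws(lab)))
  out[out %in% c("foot_strike", "footstrike")] <- "foot_strike"
  out[out %in% c("foot_off", "footoff")] <- "foot_off"
  out
}

.c3d_parse_params <- function(raw, poff) {
  pos <- poff + 5L
  groups_by_id <- list()  # id -> name
  out <- list()
  repeat {
    nname <- .r_int8(raw, pos)
    if (nname == 0L) break
    locked <- nname < 0L
    nname <- abs(nname)
    gid <- .r_int8(raw, pos + 1L)
    name <- rawToChar(raw[(pos + 2L):(pos + 1L + nname)])
    off_at <- pos + 2L + nname
    offset <- .r_int16(raw, off_at)
    body <- off_at + 2L
    if (gid < 0L) { # group definition
      groups_by_id[[as.character(-gid)]] <- name
      if (is.null(out[[name]])) out[[name]] <- list()
    } else {        # parameter belonging to group gid
      type <- .r_int8(raw, body)
      ndim <- .r_uint8(raw, body + 1L)
      dims <- if (ndim > 0L) {
        vapply(seq_len(ndim), function(k) .r_uint8(raw, body + 1L + k), 0L)
      } else integer()
      nel <- prod(c(1L, dims))
      dpos <- body + 2L + ndim
      value <- switch(as.character(type),
        `-1` = {
          ch <- raw[dpos:(dpos + nel - 1L)]
          if (length(dims) >= 1L) {
            attr(ch, "c3d_dims") <- dims
          }
          ch
        },
        `1` = as.integer(raw[dpos:(dpos + nel - 1L)]),
        `2` = readBin(raw[dpos:(dpos + 2L * nel - 1L)], "integer", n = nel,
                      size = 2L, signed = TRUE, endian = "little"),
        `4` = .r_float(raw, dpos, n = nel),
        stop("format error: unknown parameter type ", type))
      gname <- groups_by_id[[as.character(gid)]]
      if (is.null(gname)) gname <- paste0("GROUP", gid)
      if (is.null(out[[gname]])) out[[gname]] <- list()
      out[[gname]][[name]] <- value
    }
    if (offset == 0L) break
    pos <- off_at + 2L + offset
    # offset counts from the byte after the offset field
    if (pos > length(raw)) break
  }
  out
}

.c3d_char_matrix <- function(x) {
  # decode a char parameter with dims [width, n] into n trimmed strings
  if (is.null(x)) return(character())
  dims <- attr(x, "c3d_dims")
  if (is.null(dims) || length(dims) == 1L) {
    return(rawToChar(as.raw(x)))
  }
  w <- dims[1L]; n <- prod(dims[-1L])
  m <- matrix(as.raw(x), nrow = w)
  vapply(seq_len(n), function(i) rawToChar(m[, i]), "")
}

## ---------------------------------------------------------------------------
## writing

.w_int16 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                      endian = "little")
.w_float <- function(con, v) writeBin(as.numeric(v), con, size = 4L,
                                      endian = "little")

.pad_block <- function(con, upto) {
  at <- seek(con, where = NA)
  if (at < upto) writeBin(raw(upto - at), con)
}

.param_record <- function(name, gid, payload) {
  nm <- charToRaw(name)
  c(as.raw(length(nm)), as.raw(bitwAnd(gid + 256L, 255L)), nm, payload)
}

.with_offset <- function(rec_head_len, body) {
  # body follows the 2-byte offset; offset = length(body) points to next rec
  off <- length(body)
  c(writeBin(as.integer(off), raw(), size = 2L, endian = "little"), body)
}

.param_group <- function(name, id, desc = "") {
  d <- charToRaw(desc)
  body <- c(as.raw(length(d)), d)
  .param_record(name, -id, .with_offset(0L, body))
}

.param_value <- function(name, gid, type, dims, data_raw, desc = "") {
  d <- charToRaw(desc)
  body <- c(as.raw(bitwAnd(type + 256L, 255L)), as.raw(length(dims)),
            as.raw(dims), data_raw, as.raw(length(d)), d)
  .param_record(name, gid, .with_offset(0L, body))
}

.raw_int16 <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                   endian = "little")
.raw_float <- function(v) writeBin(as.numeric(v), raw(), size = 4L,
                                   endian = "little")
.raw_chars <- function(strings, width) {
  out <- raw(0)
  for (s in strings) {
    ch <- charToRaw(formatC(substr(s, 1L, width), width = -width))
    out <- c(out, ch, raw(width - length(ch)))
  }
  out
}

#' Write a trial to a C3D file
#'
#' Emits float point data (negative POINT:SCALE), mm units, and the trial's
#' events in the EVENT parameter group. `read_trial()` of the output
#' reproduces positions within float32 precision and the event list exactly.
#'
#' @param trial `rsp_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "rsp_trial"))
  used <- length(trial$points)
  nf <- n_frames(trial)
  if (nf > 32000L) stop("validation error: trial too long for int16 FRAMES")
  labels <- names(trial$points)
  lw <- max(4L, min(127L, max(nchar(labels))))
  first_frame <- trial$first_frame
  events <- trial$events

  ## parameter section ----
  prm <- c(
    .param_group("POINT", 1L, "3D point parameters"),
    .param_value("USED", 1L, 2L, integer(), .raw_int16(used)),
    .param_value("FRAMES", 1L, 2L, integer(), .raw_int16(nf)),
    .param_value("RATE", 1L, 4L, integer(), .raw_float(trial$rate)),
    .param_value("SCALE", 1L, 4L, integer(), .raw_float(-1.0)),
    .param_value("UNITS", 1L, -1L, 2L, .raw_chars("mm", 2L)),
    .param_value("LABELS", 1L, -1L, c(lw, used), .raw_chars(labels, lw))
  )
  nev <- nrow(events)
  if (nev > 0L) {
    tsec <- events$time + (first_frame - 1L) / trial$rate
    times <- as.numeric(rbind(0, tsec)) # [minutes, seconds] pairs
    prm <- c(prm,
      .param_group("EVENT", 2L, "gait events"),
      .param_value("USED", 2L, 2L, integer(), .raw_int16(nev)),
      .param_value("CONTEXTS", 2L, -1L, c(16L, nev),
                   .raw_chars(events$context, 16L)),
      .param_value("LABELS", 2L, -1L, c(16L, nev),
                   .raw_chars(.c3d_event_label(events$label), 16L)),
      .param_value("TIMES", 2L, 4L, c(2L, nev), .raw_float(times))
    )
  }
  # DATA_START is patched once the parameter length is known
  nparam_blocks <- ceiling((length(prm) + 5L + 10L + 20L) / 512)
  data_start <- 2L + nparam_blocks
  prm <- c(prm,
           .param_value("DATA_START", 1L, 2L, integer(),
                        .raw_int16(data_start)),
           as.raw(0L)) # terminator record

  con <- file(path, "wb")
  on.exit(close(con))
  ## header block ----
  writeBin(as.raw(c(2L, 0x50)), con)
  .w_int16(con, used)              # word 2: points used
  .w_int16(con, 0L)                # word 3: analog samples per frame
  .w_int16(con, first_frame)       # word 4
  .w_int16(con, first_frame + nf - 1L) # word 5
  .w_int16(con, 10L)               # word 6: max interpolation gap
  .w_float(con, -1.0)              # words 7-8: scale (negative = float)
  .w_int16(con, data_start)        # word 9
  .w_int16(con, 0L)                # word 10: analog per video frame
  .w_float(con, trial$rate)        # words 11-12
  .pad_block(con, 512L)

  ## parameter section ----
  writeBin(as.raw(c(1L, 0x50, nparam_blocks, 84L)), con)
  writeBin(prm, con)
  .pad_block(con, (data_start - 1L) * 512L)

  ## point data ----
  arr <- array(0, dim = c(4L, used, nf))
  for (i in seq_len(used)) {
    p <- trial$points[[i]]
    ok <- stats::complete.cases(p)
    q <- p
    q[!ok, ] <- 0
    arr[1:3, i, ] <- t(q)
    arr[4L, i, ] <- ifelse(ok, 0, -1)
  }
  .w_float(con, as.numeric(arr))
  invisible(path)
}

.c3d_event_label <- function(lab) {
  vapply(lab, function(l) switch(l, foot_strike = "Foot Strike",
                                 foot_off = "Foot Off", l), "")
}

#' Write an enriched C3D trial
#'
#' Adds reconstructed/virtual points and joint-angle channels to a trial and
#' writes it as a single C3D file. Angle channels are stored as point-type
#' channels with the reserved suffix `".ang"`, degrees in all three
#' components (as model outputs are commonly stored).
#'
#' @param trial `rsp_trial` original trial.
#' @param extra_points Named list of n x 3 matrices (mm), same frame count as
#'   `trial`; may be empty.
#' @param angle_series List of `angle_series` objects (see
#'   [joint_angles()]); may be empty.
#' @param path Output path.
#' @return The enriched `rsp_trial`, invisibly.
#' @export
write_enriched <- function(trial, extra_points = list(),
                           angle_series = list(), path) {
  nf <- n_frames(trial)
  pts <- trial$points
  for (nm in names(extra_points)) {
    p <- as.matrix(extra_points[[nm]])
    if (nrow(p) != nf) {
      stop("validation error: extra point '", nm, "' length ", nrow(p),
           " != trial frames ", nf)
    }
    pts[[nm]] <- p
  }
  for (a in angle_series) {
    ang <- a$angles
    if (nrow(ang) != nf) {
      stop("validation error: angle series '", a$name, "' length mismatch")
    }
    pts[[paste0(a$name, ".ang")]] <- ang
  }
  out <- new_trial(pts, rate = trial$rate, events = trial$events,
                   first_frame = trial$first_frame, units = "mm")
  write_trial(out, path)
  invisible(out)
}

#' Extract stride windows from a trial's events
#'
#' A stride spans two subsequent foot-strikes of the same side, with the
#' foot-off strictly inside. Strides whose foot-off is missing or falls
#' outside are dropped with a warning.
#'
#' @param trial `rsp_trial` with events.
#' @param side "L" or "R" (matched to event contexts Left/Right).
#' @return List of integer triples `c(strike, foot_off, next_strike)` (frame
#'   indices); empty if fewer than two strikes.
#' @export
get_strides <- function(trial, side) {
  ctx <- switch(side, L = "Left", R = "Right",
                stop("side must be 'L' or 'R'"))
  ev <- trial$events
  ev <- ev[ev$context == ctx, , drop = FALSE]
  strikes <- sort(event_frame(trial, ev$time[ev$label == "foot_strike"]))
  offs <- sort(event_frame(trial, ev$time[ev$label == "foot_off"]))
  if (length(strikes) < 2L) {
    warning("fewer than two ", ctx, " foot-strikes: no strides")
    return(list())
  }
  out <- list()
  for (i in seq_len(length(strikes) - 1L)) {
    s0 <- strikes[i]; s1 <- strikes[i + 1L]
    fo <- offs[offs > s0 & offs < s1]
    if (length(fo) != 1L) {
      warning("stride ", s0, "-", s1, " dropped: ", length(fo),
              " foot-offs inside")
      next
    }
    out[[length(out) + 1L]] <- c(s0, fo, s1)
  }
  out
}
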