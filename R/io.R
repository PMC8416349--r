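# Trial and session serialization: one CSV per trial (time_s, emg_ta,
# emg_gm, angle_deg, moment_nmkg) plus a JSON sidecar for events, condition
# and sampling rates, and a session manifest JSON. Plain-text formats chosen
# deliberately: the data are small and inspectability wins.

#' Write a trial to CSV + JSON sidecar
#'
#' Writes `<base>.csv` with the 120 Hz channels, `<base>.json` with events,
#' condition and rates, and (when present) `<base>_raw.csv` with the 1,200 Hz
#' raw EMG.
#'
#' @param trial A `raw_trial`.
#' @param base Path prefix (no extension).
#' @return `base`, invisibly.
#' @export
write_trial <- function(trial, base) {
  if (!inherits(trial, "raw_trial")) stop("write_trial expects a raw_trial")
  n <- length(trial$angle)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / trial$fs,
    emg_ta = trial$emg_envelope[, 1],
    emg_gm = trial$emg_envelope[, 2],
    angle_deg = trial$angle,
    moment_nmkg = trial$moment
  )
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  side <- list(
    schema = "narxgait-trial-1",
    trial_id = trial$trial_id,
    condition = trial$condition,
    fs = trial$fs, fs_raw = trial$fs_raw,
    events = trial$events
  )
  jsonlite::write_json(side, paste0(base, ".json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(trial$emg_raw)) {
    utils::write.csv(
      data.frame(time_s = (seq_len(nrow(trial$emg_raw)) - 1) / trial$fs_raw,
                 emg_ta = trial$emg_raw[, 1], emg_gm = trial$emg_raw[, 2]),
      paste0(base, "_raw.csv"), row.names = FALSE)
  }
  invisible(base)
}

#' Read a trial written by [write_trial()]
#'
#' @param base Path prefix (no extension).
#' @return A `raw_trial`. Missing sidecar, schema violations or NaN samples
#'   raise errors naming the offending file/row.
#' @export
read_trial <- function(base) {
  csv <- paste0(base, ".csv"); side_path <- paste0(base, ".json")
  if (!file.exists(csv)) stop("trial CSV not found: ", csv)
  if (!file.exists(side_path)) stop("events sidecar not found: ", side_path)
  df <- utils::read.csv(csv)
  need <- c("time_s", "emg_ta", "emg_gm", "angle_deg", "moment_nmkg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial CSV missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("non-finite value in column '", col, "' at row ", bad[1], " of ", csv)
    }
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$schema, "narxgait-trial-1")) {
    stop("unrecognized trial schema in ", side_path)
  }
  raw <- NULL
  raw_csv <- paste0(base, "_raw.csv")
  if (file.exists(raw_csv)) {
    rdf <- utils::read.csv(raw_csv)
    raw <- cbind(emg_ta = rdf$emg_ta, emg_gm = rdf$emg_gm)
  }
  events <- lapply(side$events, as.numeric)
  structure(
    list(emg_raw = raw,
         emg_envelope = cbind(emg_ta = df$emg_ta, emg_gm = df$emg_gm),
         angle = df$angle_deg, moment = df$moment_nmkg,
         fs_raw = side$fs_raw, fs = side$fs,
         events = events, condition = side$condition, trial_id = side$trial_id),
    class = "raw_trial"
  )
}

#' Write / read a session directory
#'
#' A session is one trial per `<trial_id>.csv/.json` pair plus
#' `manifest.json` recording the schema, trial list and generator provenance.
#'
#' @param session A `gait_session`.
#' @param dir Output directory (created if needed).
#' @rdname session-io
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(session$trials, function(tr) tr$trial_id, "")
  if (anyDuplicated(ids)) stop("duplicate trial ids in session")
  for (tr in session$trials) write_trial(tr, file.path(dir, tr$trial_id))
  manifest <- list(
    schema = "narxgait-session-1",
    trials = lapply(session$trials, function(tr)
      list(trial_id = tr$trial_id, condition = tr$condition,
           file = paste0(tr$trial_id, ".csv"))),
    fs = FS, fs_raw = FS_RAW,
    provenance = list(
      seed = session$variability$seed,
      emg_coupling = session$variability$emg_coupling,
      amplitude_jitter_sd = session$variability$amplitude_jitter_sd,
      time_warp_sd = session$variability$time_warp_sd,
      n_per_condition = session$n_per_condition
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @param dir Session directory containing `manifest.json`.
#' @rdname session-io
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("session manifest not found: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!identical(manifest$schema, "narxgait-session-1")) {
    stop("unrecognized session schema in ", mpath)
  }
  trials <- lapply(manifest$trials, function(m)
    read_trial(file.path(dir, m$trial_id)))
  structure(
    list(trials = trials,
         variability = NULL,
         n_per_condition = manifest$provenance$n_per_condition %||% NA_integer_),
    class = "gait_session"
  )
}
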