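#' Chair geometry
#'
#' Geometry of the three-point load-cell layout under the seat. The
#' coordinate frame has its origin at the right-back (RB) cell, the X axis
#' pointing toward the left-back (LB) cell and the Y axis toward the front
#' (F) cell.
#'
#' @param dRL distance (cm) from the RB cell to the LB cell along X.
#' @param dRF X offset (cm) of the F cell from the RB cell.
#' @param dBF Y offset (cm) of the F cell from the back cells.
#' @param max_capacity_g rated maximum capacity of each load cell, in grams.
#'
#' @details Defaults correspond to a seat plane of 30.3 x 26.1 cm with the
#'   front cell on the midline (`dRF = dRL / 2`). All distances are
#'   config-overridable (see [load_config()]).
#'
#' @return An object of class `chair_geometry`.
#' @export
#' @examples
#' g <- chair_geometry()
#' g$dRL
chair_geometry <- function(dRL = 30.3, dRF = 15.15, dBF = 26.1,
                           max_capacity_g = 50000) {
  if (!(dRL > 0 && dRF > 0 && dRF < dRL)) {
    stop_sc("invalid geometry: need 0 < dRF < dRL (got dRF=%g, dRL=%g)",
            dRF, dRL)
  }
  if (dBF <= 0) stop_sc("invalid geometry: dBF must be > 0 (got %g)", dBF)
  if (max_capacity_g <= 0) {
    stop_sc("invalid geometry: max_capacity_g must be > 0")
  }
  structure(list(dRL = dRL, dRF = dRF, dBF = dBF,
                 max_capacity_g = max_capacity_g),
            class = "chair_geometry")
}

LOADCELL_CHANNELS <- c("F_g", "LB_g", "RB_g", "button")
ECG_CHANNELS <- c("ecg_exp", "ecg_ref")

#' Multichannel session recording
#'
#' Container for one chair session: weight streams from the three load cells
#' (grams), the pushbutton channel marking bout boundaries, and optional
#' single-lead ECG channels at their own sampling rate.
#'
#' @param channels named list of numeric vectors. Recognised names:
#'   `F_g`, `LB_g`, `RB_g`, `button` (load-cell block, one sampling rate)
#'   and `ecg_exp`, `ecg_ref` (ECG block, its own rate). Any subset may be
#'   present, but the three load-cell channels must have equal length, as
#'   must all ECG channels.
#' @param fs_loadcell load-cell sampling rate in Hz.
#' @param fs_ecg ECG sampling rate in Hz (required when ECG channels exist).
#' @param start_time optional acquisition start timestamp.
#' @param meta free-form named list of annotations.
#'
#' @return An object of class `session_stream`.
#' @export
session_stream <- function(channels, fs_loadcell, fs_ecg = NULL,
                           start_time = NULL, meta = list()) {
  stopifnot(is.list(channels))
  unknown <- setdiff(names(channels), c(LOADCELL_CHANNELS, ECG_CHANNELS))
  if (length(unknown)) {
    stop_sc("unknown channel(s): %s", paste(unknown, collapse = ", "))
  }
  lc <- intersect(names(channels), LOADCELL_CHANNELS)
  ec <- intersect(names(channels), ECG_CHANNELS)
  if (length(lc) && length(unique(lengths(channels[lc]))) != 1L) {
    stop_sc("load-cell channels must have equal length")
  }
  if (length(ec) && length(unique(lengths(channels[ec]))) != 1L) {
    stop_sc("ECG channels must have equal length")
  }
  if (!is.numeric(fs_loadcell) || fs_loadcell <= 0) {
    stop_sc("fs_loadcell must be > 0")
  }
  if (length(ec)) {
    if (is.null(fs_ecg) || fs_ecg <= 0) {
      stop_sc("fs_ecg must be > 0 when ECG channels are present")
    }
  }
  if ("button" %in% names(channels)) {
    b <- channels$button
    if (!all(b %in% c(0, 1))) stop_sc("button channel must contain only 0/1")
  }
  structure(list(channels = channels, fs_loadcell = fs_loadcell,
                 fs_ecg = fs_ecg, start_time = start_time, meta = meta),
            class = "session_stream")
}

#' @export
print.session_stream <- function(x, ...) {
  cat("<session_stream>\n")
  for (nm in names(x$channels)) {
    cat(sprintf("  %-8s n=%d\n", nm, length(x$channels[[nm]])))
  }
  cat(sprintf("  fs_loadcell=%g Hz%s\n", x$fs_loadcell,
              if (!is.null(x$fs_ecg)) sprintf(", fs_ecg=%g Hz", x$fs_ecg)
              else ""))
  invisible(x)
}

#' Read a session CSV
#'
#' Sessions are stored as comma-delimited UTF-8 text with one header row.
#' The load-cell block and the ECG block run at different rates; each block
#' is written in its own columns and padded with empty cells to the length
#' of the longer block, so a single file can carry both.
#'
#' @param path path to the CSV file.
#' @param schema named character vector mapping canonical channel names
#'   (`F_g`, `LB_g`, `RB_g`, `button`, `ecg_exp`, `ecg_ref`) to column
#'   names in the file.
#' @param fs_loadcell,fs_ecg sampling rates (Hz) to attach to the stream.
#' @param require channels whose columns must exist in the header (error
#'   otherwise); all other schema channels are optional and yield absent
#'   channels when their column is missing. Defaults to the three
#'   load-cell channels.
#'
#' @return A [session_stream()].
#' @export
read_session <- function(path, schema = default_schema(),
                         fs_loadcell = 20, fs_ecg = 500,
                         require = c("F_g", "LB_g", "RB_g")) {
  if (!file.exists(path)) stop_sc("session file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = "")
  if (nrow(raw) == 0L) stop_sc("empty session file: %s", path)
  missing_cols <- setdiff(unname(schema[intersect(require,
                                                  names(schema))]),
                          names(raw))
  if (length(missing_cols)) {
    stop_sc("column(s) %s named by schema absent from header of %s",
            paste(missing_cols, collapse = ", "), path)
  }
  channels <- list()
  for (ch in names(schema)) {
    col <- raw[[schema[[ch]]]]
    if (is.null(col)) next  # optional channel not in this file
    # strip the NA padding tail of the shorter block
    keep <- !is.na(col)
    if (!any(keep)) next
    col <- col[seq_len(max(which(keep)))]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_sc("unparseable value in column '%s' at data line %d of %s",
              schema[[ch]], bad[1], path)
    }
    channels[[ch]] <- v
  }
  if (!length(channels)) stop_sc("no channels parsed from %s", path)
  has_ecg <- any(ECG_CHANNELS %in% names(channels))
  sc_log("read_session: %s -> %d channels", path, length(channels))
  session_stream(channels, fs_loadcell = fs_loadcell,
                 fs_ecg = if (has_ecg) fs_ecg else NULL,
                 meta = list(source = path))
}

#' Default channel-to-column schema
#' @return named character vector used by [read_session()].
#' @export
default_schema <- function() {
  c(F_g = "F_g", LB_g = "LB_g", RB_g = "RB_g", button = "button",
    ecg_exp = "ecg_exp", ecg_ref = "ecg_ref")
}

#' Write a session CSV
#'
#' Inverse of [read_session()]: blocks of unequal length are padded with
#' empty cells; numeric values keep enough digits for a round trip within
#' 1e-9 relative error.
#'
#' @param stream a [session_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(stream, path) {
  stopifnot(inherits(stream, "session_stream"))
  chans <- stream$channels
  n <- if (length(chans)) max(lengths(chans)) else 0L
  df <- as.data.frame(lapply(chans, function(v) {
    c(format(v, digits = 15, trim = TRUE, scientific = FALSE),
      rep(NA_character_, n - length(v)))
  }), check.names = FALSE, optional = TRUE)
  if (n == 0L) df <- as.data.frame(setNames(rep(list(character(0)),
                                                length(chans)), names(chans)))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop_sc("cannot write session to %s", path)
  sc_log("write_session: %d channels -> %s", length(chans), path)
  invisible(path)
}

default_config <- function() {
  list(
    geometry = list(dRL = 30.3, dRF = 15.15, dBF = 26.1,
                    max_capacity_g = 50000),
    processing = list(
      fs_loadcell = 20, fs_ecg = 500,
      fir_order = 150, fir_band = c(3, 45),
      beat_window_ms = c(200, 400), match_tol_ms = 100,
      hamilton = list(threshold_coef = 0.3125, refractory_ms = 200,
                      searchback_factor = 1.5, buffer_len = 8),
      outliers = list(
        dbscan = list(epsilon = 0.45, min_pts = 10, metric = "cosine"),
        dmean = list(c1 = 1.5, c2 = 2.0, c3 = 2.0),
        nccc = list(init_size = 20, theta = 0.8))),
    grids = list(
      knn_k = c(250, 500, 750, 1000, 2000, 3000),
      nc = list(metric = c("euclidean", "cityblock")),
      svm = list(kernel = c("linear", "rbf"),
                 C = c(1e-3, 1e-2, 1e-1, 1, 10),
                 gamma = c(0.05, 0.1, 0.5, 1)),
      gmm = list(covariance = c("tied", "full", "diagonal", "spherical"))),
    seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a YAML configuration and fills every absent key with the package
#' default (chair geometry, processing parameters, hyperparameter grids).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return list with elements `geometry` (a [chair_geometry()]),
#'   `processing`, `grids` and `seed`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_sc("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg$geometry <- chair_geometry(dRL = cfg$geometry$dRL,
                                 dRF = cfg$geometry$dRF,
                                 dBF = cfg$geometry$dBF,
                                 max_capacity_g = cfg$geometry$max_capacity_g)
  cfg
}
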