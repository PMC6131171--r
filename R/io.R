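events_col_types <- function() {
  readr::cols(onset = readr::col_double(),
              duration = readr::col_double(),
              event_type = readr::col_character(),
              trial_index = readr::col_integer(),
              block = readr::col_integer(),
              congruency = readr::col_character(),
              target_class = readr::col_character(),
              n_vertices = readr::col_integer(),
              response = readr::col_character(),
              rt_ms = readr::col_double(),
              correct = readr::col_logical())
}

#' Write / read an events table
#'
#' Tab-separated, BIDS-events-style dialect (onset and duration in seconds,
#' plus the trial metadata columns). Round-trips losslessly.
#'
#' @param events Tibble from [export_events()].
#' @param path File path.
#' @return `write_events`: `path` invisibly. `read_events`: the events tibble
#'   (empty, with a warning, for an empty file).
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such events file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty events file: ", path, call. = FALSE)
    return(tibble::tibble())
  }
  out <- suppressWarnings(readr::read_tsv(path, col_types = events_col_types(),
                                          progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed events file ", path, ": row ", probs$row[1], ", ",
         probs$expected[1], " expected, got '", probs$actual[1], "'",
         call. = FALSE)
  }
  out
}

#' Write an EEG session to disk
#'
#' Two containers: `"fbin"` (default) stores samples as little-endian float32
#' with a JSON sidecar holding sampling rate, channel labels, units and event
#' markers -- bit-faithful at single precision; `"edf"` writes a minimal
#' 16-bit EDF (one data record per second, physical range set from the data)
#' alongside the same JSON sidecar (EDF carries the signals; markers live in
#' the sidecar). Responses and events are also embedded in the sidecar so a
#' session round-trips through one base path.
#'
#' @param session A `psicat_session`.
#' @param path Base path; `.json` sidecar and `.fbin`/`.edf` signal files are
#'   derived from it.
#' @param format `"fbin"` or `"edf"`.
#' @return Base path, invisibly.
#' @export
write_eeg <- function(session, path, format = c("fbin", "edf")) {
  format <- match.arg(format)
  base <- sub("\\.(fbin|edf|json)$", "", path)
  sidecar <- list(
    format = format,
    sampling_rate_hz = session$fs,
    n_channels = length(session$channels),
    n_samples = ncol(session$eeg),
    channel_labels = session$channels,
    units = "uV",
    participant_id = session$participant_id,
    seed = session$seed,
    events = session$events,
    responses = session$responses
  )
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (format == "fbin") {
    con <- file(paste0(base, ".fbin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(session$eeg), con, size = 4, endian = "little")
  } else {
    write_edf_signals(session, paste0(base, ".edf"))
  }
  invisible(base)
}

#' @rdname write_eeg
#' @return `read_eeg`: a `psicat_session` (without the schedule object; the
#'   events table carries the realized timeline).
#' @export
read_eeg <- function(path) {
  base <- sub("\\.(fbin|edf|json)$", "", path)
  sc_path <- paste0(base, ".json")
  if (!file.exists(sc_path)) stop("missing sidecar ", sc_path, call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  eeg <- if (identical(sc$format, "edf")) {
    read_edf_signals(paste0(base, ".edf"))
  } else {
    con <- file(paste0(base, ".fbin"), "rb")
    on.exit(close(con))
    matrix(readBin(con, "numeric", n = sc$n_channels * sc$n_samples,
                   size = 4, endian = "little"),
           nrow = sc$n_channels)
  }
  rownames(eeg) <- sc$channel_labels
  known <- biosemi128_montage()$label
  unknown <- setdiff(sc$channel_labels, known)
  if (length(unknown) > 0) {
    warning("channel labels not in the montage: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(eeg = eeg, fs = sc$sampling_rate_hz,
                 channels = sc$channel_labels,
                 events = tibble::as_tibble(sc$events),
                 responses = tibble::as_tibble(sc$responses),
                 schedule = NULL,
                 participant_id = sc$participant_id, seed = sc$seed),
            class = "psicat_session")
}

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf_signals <- function(session, path) {
  ns <- length(session$channels)
  fs <- session$fs
  n_rec <- floor(ncol(session$eeg) / fs)
  x <- session$eeg[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- floor(min(x)); pmax_ <- ceiling(max(x))
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("session", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4),
    paste0(pad_field(session$channels, 16), collapse = ""),
    paste0(rep(pad_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste0(rep(pad_field("uV", 8), ns), collapse = ""),
    paste0(rep(pad_field(pmin_, 8), ns), collapse = ""),
    paste0(rep(pad_field(pmax_, 8), ns), collapse = ""),
    paste0(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste0(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),       # prefiltering
    paste0(rep(pad_field(fs, 8), ns), collapse = ""),
    paste0(rep(pad_field("", 32), ns), collapse = "")        # reserved
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_signals <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8 + 80 + 80 + 8 + 8, useBytes = TRUE)
  hdr_bytes <- as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  readChar(con, 44, useBytes = TRUE)
  n_rec <- as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  readChar(con, 8, useBytes = TRUE)
  ns <- as.integer(trimws(readChar(con, 4, useBytes = TRUE)))
  labels <- trimws(vapply(seq_len(ns), function(i)
    readChar(con, 16, useBytes = TRUE), character(1)))
  readChar(con, ns * 80 + ns * 8, useBytes = TRUE)
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), character(1))))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), character(1))))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), character(1))))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), character(1))))
  readChar(con, ns * 80, useBytes = TRUE)                    # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), character(1))))
  readChar(con, ns * 32, useBytes = TRUE)                    # reserved
  stopifnot(256 + ns * 256 == hdr_bytes, length(unique(spr)) == 1)
  fs <- spr[1]
  out <- matrix(0, ns, n_rec * fs)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * fs, size = 2, endian = "little",
                     signed = TRUE)
    out[, ((r - 1) * fs + 1):(r * fs)] <-
      t(matrix(block, nrow = fs))
  }
  out <- (out - dmin[1]) / (dmax[1] - dmin[1]) * (pmax_[1] - pmin_[1]) +
    pmin_[1]
  rownames(out) <- labels
  out
}
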