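# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32),
# sufficient for the mono and stereo stimulus files this pipeline exchanges.
# Written here because no WAV codec ships with the package's R dependencies.

#' Read a WAV file
#'
#' Supports uncompressed PCM (16- or 24-bit) and IEEE float32, any channel
#' count. Integer samples are scaled to `[-1, 1)`.
#'
#' @param path Path to a `.wav` file.
#' @return For mono files, a [waveform()]; otherwise a list of one
#'   [waveform()] per channel.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      bytes <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(bytes[1:2], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(bytes[3:4], "integer", 1, 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(bytes[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(bytes[15:16], "integer", 1, 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  x <- switch(as.character(fmt$audio_format),
    "1" = {
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                endian = "little") / 32768
      } else if (fmt$bits == 24) {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "numeric", length(data_raw) / 4, 4,
                  endian = "little"),
    stop("unsupported WAV audio format code: ", fmt$audio_format,
         call. = FALSE))
  nc <- fmt$n_channels
  if (nc == 1L) return(waveform(x, fmt$sample_rate))
  lapply(seq_len(nc), function(ch) {
    waveform(x[seq(ch, length(x), by = nc)], fmt$sample_rate)
  })
}

#' Write a WAV file
#'
#' @param w A [waveform()], or a list of equal-length waveforms written as
#'   interleaved channels.
#' @param path Output path.
#' @param bit_depth 16 or 24 (PCM) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = 16) {
  chans <- if (inherits(w, "waveform")) list(w) else w
  stopifnot(all(vapply(chans, inherits, logical(1), "waveform")))
  fs <- chans[[1]]$rate_hz
  n <- length(chans[[1]]$samples)
  stopifnot(all(vapply(chans, function(c) length(c$samples) == n,
                       logical(1))))
  nc <- length(chans)
  inter <- as.vector(rbind(do.call(rbind, lapply(chans, `[[`, "samples"))))
  float <- identical(bit_depth, "float32")
  bits <- if (float) 32L else as.integer(bit_depth)
  if (!float && !bits %in% c(16L, 24L)) {
    stop("bit_depth must be 16, 24 or 'float32'", call. = FALSE)
  }
  bytes_per <- bits / 8
  data_size <- n * nc * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (float) 3L else 1L, con, 2, endian = "little")
  writeBin(as.integer(nc), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nc * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nc * bytes_per), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (float) {
    writeBin(inter, con, 4, endian = "little")
  } else if (bits == 16L) {
    v <- as.integer(pmax(pmin(round(inter * 32768), 32767), -32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    v <- round(pmax(pmin(inter, 1 - 1 / 8388608), -1) * 8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Envelope and EEG matrix CSV formats
#'
#' Signals travel as delimited text with a one-line metadata header. An
#' envelope file looks like
#' \preformatted{rate_hz=64,trial_id=t01
#' envelope
#' 0.1234
#' ...}
#' and an EEG file stores samples in rows and channels in columns after a
#' `rate_hz=...` header line and a line of channel labels.
#'
#' @param env An [envelope()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rate_hz=%.10g,trial_id=%s", env$rate_hz, env$trial_id),
             con)
  writeLines("envelope", con)
  writeLines(sprintf("%.12g", env$samples), con)
  invisible(path)
}

parse_kv_header <- function(line) {
  kv <- strsplit(strsplit(line, ",")[[1]], "=")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  lines <- readLines(path)
  hdr <- parse_kv_header(lines[1])
  envelope(as.numeric(lines[-(1:2)]), as.numeric(hdr$rate_hz),
           hdr$trial_id)
}

#' @rdname write_envelope_csv
#' @param eeg An [eeg_record()].
#' @export
write_eeg_csv <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rate_hz=%.10g,n_channels=%d", eeg$rate_hz,
                     nrow(eeg$data)), con)
  writeLines(paste(eeg$channel_labels, collapse = ","), con)
  utils::write.table(t(eeg$data), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_eeg_csv <- function(path) {
  lines <- readLines(path, n = 2)
  hdr <- parse_kv_header(lines[1])
  labels <- strsplit(lines[2], ",")[[1]]
  m <- utils::read.table(path, sep = ",", skip = 2)
  eeg_record(t(as.matrix(m)), as.numeric(hdr$rate_hz), labels)
}

#' Keyword/response event tables
#'
#' Events are exchanged as plain CSV with columns `trial_id`,
#' `window_index`, `stream`, `onset_s`, `offset_s`, `response`: one row per
#' keyword (two per response window), the row's `response` being the
#' participant's answer for that window.
#'
#' @param windows A [make_windows()] result.
#' @param trial_id Trial identifier written into the table.
#' @param path File path.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns a list with `windows` per trial id.
#' @export
write_events_csv <- function(windows, trial_id, path) {
  stopifnot(inherits(windows, "response_windows"))
  rows <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    data.frame(trial_id = trial_id,
               window_index = windows$index[i],
               stream = c("target", "masker"),
               onset_s = c(windows$target_onset_s[i],
                           windows$masker_onset_s[i]),
               offset_s = c(windows$target_offset_s[i],
                            windows$masker_offset_s[i]),
               response = windows$response[i])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "window_index", "stream", "onset_s", "offset_s",
            "response")
  if (!all(need %in% names(tab))) {
    stop("events table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$trial_id), function(tt) {
    tt <- tt[order(tt$window_index, tt$stream, method = "radix"), ]
    tks <- mks <- vector("list", 3)
    resp <- character(3)
    for (i in 1:3) {
      ti <- tt[tt$window_index == i & tt$stream == "target", ]
      mi <- tt[tt$window_index == i & tt$stream == "masker", ]
      tks[[i]] <- keyword_interval(ti$onset_s, ti$offset_s, "target")
      mks[[i]] <- keyword_interval(mi$onset_s, mi$offset_s, "masker")
      resp[i] <- ti$response
    }
    make_windows(tks, mks, resp)
  })
  out
}

#' Decoder weight serialization
#'
#' @param d A `"trf_decoder"`.
#' @param path File path.
#' @return The decoder (reader) or `path` (writer, invisibly).
#' @export
write_decoder_csv <- function(d, path) {
  stopifnot(inherits(d, "trf_decoder"))
  spec <- d$lagspec
  n_lags <- length(spec$lag_samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "n_channels=%d,n_lags=%d,lambda=%.12g,rate_hz=%.10g,min_lag_ms=%.10g,max_lag_ms=%.10g",
    length(d$weights) / n_lags, n_lags, d$lambda, spec$rate_hz,
    spec$min_lag_ms, spec$max_lag_ms), con)
  writeLines("weight", con)
  writeLines(sprintf("%.17g", d$weights), con)
  invisible(path)
}

#' @rdname write_decoder_csv
#' @export
read_decoder_csv <- function(path) {
  lines <- readLines(path)
  hdr <- parse_kv_header(lines[1])
  spec <- lag_spec(as.numeric(hdr$min_lag_ms), as.numeric(hdr$max_lag_ms),
                   as.numeric(hdr$rate_hz))
  structure(list(weights = as.numeric(lines[-(1:2)]),
                 lambda = as.numeric(hdr$lambda), lagspec = spec),
            class = "trf_decoder")
}

#' Load and validate a trial manifest
#'
#' A manifest is a CSV with one row per trial and columns `subject`,
#' `condition`, `trial_id`, `target_path`, `masker_path`, `eeg_path`,
#' `events_path`, `seed`. Paths are resolved relative to the manifest's
#' directory; every referenced file must exist and trial ids must be unique.
#'
#' @param path Path to the manifest CSV.
#' @return Data frame of validated rows with absolute paths, class
#'   `"trial_manifest"`.
#' @export
load_manifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "trial_id", "target_path", "masker_path",
            "eeg_path", "events_path", "seed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$trial_id)) {
    stop("manifest trial_id values must be unique", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  path_cols <- c("target_path", "masker_path", "eeg_path", "events_path")
  offenders <- character(0)
  for (col in path_cols) {
    p <- ifelse(grepl("^/", tab[[col]]), tab[[col]],
                file.path(base, tab[[col]]))
    ok <- file.exists(p)
    if (any(!ok)) {
      offenders <- c(offenders, sprintf("row %d: missing %s '%s'",
                                        which(!ok), col, tab[[col]][!ok]))
    }
    tab[[col]] <- p
  }
  if (length(offenders) > 0) {
    stop("manifest references absent files:\n  ",
         paste(offenders, collapse = "\n  "), call. = FALSE)
  }
  class(tab) <- c("trial_manifest", "data.frame")
  tab
}
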