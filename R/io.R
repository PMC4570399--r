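#' Write a recording as raw int16 with a JSON sidecar
#'
#' Stores the traces as little-endian signed 16-bit integers in
#' channel-multiplexed frames (sample 1 of channels 1..M, then sample 2, ...),
#' with a JSON sidecar `<path>.json` holding the sampling rate, channel
#' count, the amplitude scale factor (`int16 = round(value * scale)`), the
#' endianness and the generator seed.
#'
#' @param recording a `spike_recording`.
#' @param path output path for the raw binary; the sidecar is `<path>.json`.
#' @param scale int16 units per signal unit; the default uses 90% of the
#'   int16 range for the largest absolute amplitude.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, scale = NULL) {
  traces <- recording$traces
  if (is.null(scale)) {
    peak <- max(abs(traces))
    scale <- if (peak > 0) floor(0.9 * 32767 / peak) else 1
  }
  ints <- as.integer(round(t(traces) * scale))   # channel-multiplexed frames
  stopifnot(all(abs(ints) <= 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(ints, con, size = 2L, endian = "little")
  sidecar <- list(rs = recording$rs, M = ncol(traces),
                  n_samples = nrow(traces), scale = scale,
                  endianness = "little", format = "int16",
                  seed = recording$seed, m = recording$m)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw int16 recording written by [write_recording()]
#'
#' @param path path to the raw binary; `<path>.json` must exist.
#' @return a `spike_recording`.
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_vals <- sidecar$M * sidecar$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = n_vals, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(ints) != n_vals) {
    stop("truncated recording: expected ", n_vals, " int16 values (",
         2 * n_vals, " bytes), read ", length(ints), " (byte offset ",
         2 * length(ints), ")")
  }
  traces <- t(matrix(ints / sidecar$scale, nrow = sidecar$M))
  structure(list(traces = traces, rs = as.numeric(sidecar$rs),
                 m = sidecar$m %||% 64L, seed = sidecar$seed %||% NA_integer_,
                 scale = sidecar$scale),
            class = "spike_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @return `path` (write) or a `ground_truth` (read), invisibly for write.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(events = truth$events,
                  refractory_samples = truth$refractory_samples,
                  templates = lapply(truth$templates, function(tp) {
                    list(template_id = tp$template_id,
                         peak_index = tp$peak_index,
                         waveform = tp$waveform)
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- lapply(seq_len(nrow(payload$templates)), function(i) {
    list(template_id = payload$templates$template_id[i],
         peak_index = payload$templates$peak_index[i],
         waveform = payload$templates$waveform[[i]])
  })
  m <- length(templates[[1]]$waveform)
  structure(list(events = as.data.frame(payload$events),
                 templates = structure(templates, class = "spike_templates",
                                       m = m),
                 refractory_samples = payload$refractory_samples),
            class = "ground_truth")
}

#' Write templates as CSV (one row per sample)
#'
#' @param templates a `spike_templates` object.
#' @param path output CSV path.
#' @export
write_templates <- function(templates, path) {
  df <- as.data.frame(lapply(templates, `[[`, "waveform"))
  names(df) <- paste0("neuron", vapply(templates, `[[`, 1L, "template_id"))
  df <- cbind(sample = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted GHA model as CSV weights plus JSON metadata
#'
#' The weight matrix goes to `<path>` as CSV (p rows by m columns); training
#' metadata (backend, update count, normalization scale, seed) goes to
#' `<path>.json`.
#'
#' @param fit a [gha()] model.
#' @param path output CSV path.
#' @param channel channel id recorded in the metadata.
#' @export
write_weights <- function(fit, path, channel = 1L) {
  utils::write.table(fit$weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(channel = channel, n_updates = fit$n_updates,
               backend = fit$backend, p = fit$p, m = fit$m,
               eta = fit$eta, epochs = fit$epochs, scale = fit$scale,
               seed = fit$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write detected spikes as CSV
#'
#' One row per spike: channel, peak index, detect time, then the m waveform
#' samples.
#'
#' @param spikes a `spike_set`.
#' @param path output CSV path.
#' @export
write_spikes <- function(spikes, path) {
  wf <- as.data.frame(spikes$waveforms)
  names(wf) <- paste0("s", seq_len(ncol(wf)))
  df <- cbind(data.frame(channel = spikes$channel,
                         peak_index = spikes$peak_index,
                         detect_time = spikes$detect_time), wf)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write feature vectors as CSV
#'
#' @param features n-by-p feature matrix.
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  if (is.null(colnames(features))) names(df) <- paste0("PC", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
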