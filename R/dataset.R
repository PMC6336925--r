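#' One subject's multi-channel synthetic recording
#'
#' @param subject_id integer subject index
#' @param channels list of `list(hbo2 = <channel_series>, hbr =
#'   <channel_series>)` pairs, one per measurement channel
#' @param excluded_channels integer channel indices to exclude from
#'   group statistics
#' @param seed the seed this recording was generated with
#' @return a `subject_recording`
#' @export
subject_recording <- function(subject_id, channels,
                              excluded_channels = integer(0), seed = NA) {
  fs <- channels[[1]]$hbo2$fs
  n <- length(channels[[1]]$hbo2$values)
  for (ch in channels) {
    if (ch$hbo2$fs != fs || ch$hbr$fs != fs ||
        length(ch$hbo2$values) != n || length(ch$hbr$values) != n)
      stop("all channels must share fs and length")
  }
  if (length(excluded_channels) &&
      any(excluded_channels < 1 | excluded_channels > length(channels)))
    stop("excluded_channels out of range")
  structure(
    list(subject_id = subject_id, channels = channels,
         excluded_channels = as.integer(excluded_channels), seed = seed),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> id=%s  channels=%d  fs=%g Hz  n=%d\n",
              x$subject_id, length(x$channels), x$channels[[1]]$hbo2$fs,
              length(x$channels[[1]]$hbo2$values)))
  invisible(x)
}

#' Assemble the full synthetic study: one dataset per amplitude preset
#'
#' For each amplitude preset, generates `n_subjects` recordings of
#' `n_channels` (HbO2, HbR) pairs: per-channel resting noise plus the
#' task component, which is identical across all channels of a subject.
#' Per-subject and per-channel seeds are derived deterministically from
#' `master_seed`, and the noise realizations are shared across amplitude
#' presets (the presets differ only in the injected task amplitude, as when
#' the same resting recordings are reused with different added components).
#'
#' @param n_subjects number of subjects (>= 2)
#' @param n_channels number of measurement channels
#' @param protocol a [protocol_spec()]
#' @param hrf an [hrf_spec()]
#' @param amplitudes list of [amplitude_spec()]; default the three presets
#' @param noise a [noise_spec()]
#' @param master_seed integer master seed
#' @param fs sampling rate, Hz
#' @return named list (by amplitude label) of lists of
#'   [subject_recording()] objects
#' @export
assemble_dataset <- function(n_subjects = 18, n_channels = 16,
                             protocol = protocol_spec(),
                             hrf = hrf_spec(),
                             amplitudes = amplitude_presets(),
                             noise = noise_spec(),
                             master_seed = 1, fs = 5) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  boxcar <- build_boxcar(protocol, fs)
  kernel <- sample_hrf(hrf, fs)
  task_unit <- make_task_component(boxcar, kernel, 1)$values
  duration <- protocol$total_dur

  # per-subject correlated multi-channel noise, shared across amplitude
  # presets (the presets differ only in the injected task amplitude)
  noise_bank <- lapply(seq_len(n_subjects), function(s)
    simulate_subject_channels(noise, n_channels, duration, fs,
                              derive_seed(master_seed, s, 0)))

  out <- list()
  for (amp in amplitudes) {
    recs <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      chans <- lapply(noise_bank[[s]], function(pair) {
        list(
          hbo2 = series_with_values(
            pair$hbo2, pair$hbo2$values + amp$hbo2_amp * task_unit),
          hbr = series_with_values(
            pair$hbr, pair$hbr$values + amp$hbr_amp * task_unit)
        )
      })
      recs[[s]] <- subject_recording(s, chans,
                                     seed = derive_seed(master_seed, s, 0))
    }
    out[[amp$label]] <- recs
  }
  out
}

# deterministic 31-bit seed stream from (master, subject, channel)
derive_seed <- function(master_seed, subject, channel) {
  x <- (as.double(master_seed) %% 2147483647) + 1
  for (k in c(subject, channel)) {
    x <- (x * 48271 + k * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

#' Write a subject recording as delimited text plus a JSON sidecar
#'
#' Tab-separated columns: `time_s`, then `chNN_HbO2`, `chNN_HbR` per
#' channel (Molar). The sidecar `<path>.json` records fs, seed and any
#' metadata passed in `meta`.
#'
#' @param rec a [subject_recording()]
#' @param path output file path for the table
#' @param meta named list of extra metadata for the sidecar
#' @export
write_subject_recording <- function(rec, path, meta = list()) {
  stopifnot(inherits(rec, "subject_recording"))
  fs <- rec$channels[[1]]$hbo2$fs
  n <- length(rec$channels[[1]]$hbo2$values)
  cols <- list(time_s = (seq_len(n) - 1) / fs)
  for (i in seq_along(rec$channels)) {
    cols[[sprintf("ch%02d_HbO2", i)]] <- rec$channels[[i]]$hbo2$values
    cols[[sprintf("ch%02d_HbR", i)]] <- rec$channels[[i]]$hbr$values
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sidecar <- c(list(subject_id = rec$subject_id, fs = fs, seed = rec$seed,
                    n_channels = length(rec$channels),
                    excluded_channels = rec$excluded_channels), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a subject recording written by [write_subject_recording()]
#'
#' @param path path to the table file (sidecar `<path>.json` must exist)
#' @return a [subject_recording()]
#' @export
read_subject_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- side$fs
  n_ch <- side$n_channels
  chans <- lapply(seq_len(n_ch), function(i) {
    list(hbo2 = channel_series(tab[[sprintf("ch%02d_HbO2", i)]], fs, "HbO2"),
         hbr = channel_series(tab[[sprintf("ch%02d_HbR", i)]], fs, "HbR"))
  })
  subject_recording(side$subject_id, chans,
                    excluded_channels = side$excluded_channels %||% integer(0),
                    seed = side$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
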