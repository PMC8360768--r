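# Spike-triggered averaging of rod/L/S contrast sequences from
# white-noise runs.

#' Spike-triggered averages of white-noise contrast sequences
#'
#' For each opsin channel, the mean stimulus contrast in the frames
#' preceding each spike (lags at the frame resolution, no upsampling).
#' Amplitude is peak minus trough of the lag trace; polarity is the sign
#' of the trace at the lag of largest absolute deviation within the
#' 0--300 ms immediately preceding the spike. A shuffled floor is the
#' 95th percentile of amplitudes obtained from randomized spike times.
#'
#' @param spike_times Numeric spike times (s) within the sequence
#'   duration; >= 100 spikes recommended.
#' @param sequences Matrix frames x opsins of contrast values (columns
#'   named, e.g. `L`, `S`, `rod`).
#' @param frame_rate Frames per second (default 10).
#' @param window STA window, s (default 1).
#' @param n_shuffles Shuffle repeats for the floor (default 100).
#' @param seed Integer seed.
#' @param polarity_window Lag range used for polarity, s (default 0.3).
#' @return Object of class `sta_result`: `sta` (lags x opsins matrix),
#'   `lags_s`, per-opsin `amplitude`, `polarity`, `shuffle_floor`,
#'   `n_spikes`; `empty = TRUE` when there are no usable spikes.
#' @export
compute_sta <- function(spike_times, sequences, frame_rate = 10, window = 1,
                        n_shuffles = 100, seed = 1, polarity_window = 0.3) {
  stopifnot(is.matrix(sequences), !is.null(colnames(sequences)))
  n_frames <- nrow(sequences)
  n_lag <- round(window * frame_rate)
  duration <- n_frames / frame_rate
  frames <- floor(spike_times * frame_rate) + 1L
  frames <- frames[frames >= n_lag & frames <= n_frames]
  if (length(frames) == 0) {
    return(structure(list(empty = TRUE, n_spikes = 0L), class = "sta_result"))
  }
  sta_of <- function(fr) {
    # rows: lag 0 .. n_lag-1 before the spike frame
    idx <- outer(fr, 0:(n_lag - 1), `-`)
    m <- vapply(colnames(sequences), function(cn) {
      colMeans(matrix(sequences[idx, cn], nrow = length(fr)))
    }, numeric(n_lag))
    colnames(m) <- colnames(sequences)
    m
  }
  sta <- sta_of(frames)
  amp <- apply(sta, 2, function(v) max(v) - min(v))
  np <- max(1L, round(polarity_window * frame_rate))
  polarity <- apply(sta, 2, function(v) {
    w <- v[seq_len(np)]
    if (w[which.max(abs(w))] >= 0) "ON" else "OFF"
  })
  floor_amp <- with_seed(seed, {
    amps <- vapply(seq_len(n_shuffles), function(s) {
      fr <- sample.int(n_frames - n_lag + 1L, length(frames), replace = TRUE) +
        n_lag - 1L
      apply(sta_of(fr), 2, function(v) max(v) - min(v))
    }, numeric(ncol(sequences)))
    if (is.null(dim(amps))) amps <- matrix(amps, nrow = ncol(sequences))
    apply(amps, 1, stats::quantile, 0.95, names = FALSE)
  })
  names(floor_amp) <- colnames(sequences)
  structure(list(empty = FALSE, sta = sta,
                 lags_s = (0:(n_lag - 1)) / frame_rate,
                 amplitude = amp, polarity = polarity,
                 shuffle_floor = floor_amp, n_spikes = length(frames)),
            class = "sta_result")
}

#' Export STA traces and summaries as CSV
#'
#' @param results Named list (by unit id) of `sta_result`s.
#' @param trace_path,summary_path Output CSVs (either may be `NULL`).
#' @return Invisibly, the summary data.frame.
#' @export
write_sta_csv <- function(results, trace_path = NULL, summary_path = NULL) {
  traces <- list(); summaries <- list()
  for (uid in names(results)) {
    r <- results[[uid]]
    if (isTRUE(r$empty)) next
    for (cn in colnames(r$sta)) {
      traces[[paste(uid, cn)]] <- data.frame(
        unit_id = uid, opsin = cn, lag_s = r$lags_s,
        mean_contrast = r$sta[, cn])
      summaries[[paste(uid, cn)]] <- data.frame(
        unit_id = uid, opsin = cn, amplitude = r$amplitude[[cn]],
        polarity = r$polarity[[cn]], shuffle_floor = r$shuffle_floor[[cn]],
        n_spikes = r$n_spikes)
    }
  }
  tr <- do.call(rbind, traces); sm <- do.call(rbind, summaries)
  if (!is.null(trace_path)) utils::write.csv(tr, trace_path, row.names = FALSE)
  if (!is.null(summary_path)) utils::write.csv(sm, summary_path, row.names = FALSE)
  invisible(sm)
}
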