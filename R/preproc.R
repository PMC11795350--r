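#' Artifact rejection criteria
#'
#' The four semi-automatic screening thresholds applied to every epoch:
#' (a) absolute amplitude, (b) voltage step between adjacent samples
#' expressed in uV/ms, (c) maximal peak-to-peak difference within any
#' sliding 200-ms window, and (d) minimal activity (peak-to-peak) within
#' any sliding 100-ms window.
#'
#' @param max_abs_amplitude uV; default 70.
#' @param max_step uV per ms; default 50.
#' @param max_diff_200ms uV; default 50.
#' @param min_activity_100ms uV; default 0.5.
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(max_abs_amplitude = 70, max_step = 50,
                               max_diff_200ms = 50, min_activity_100ms = 0.5) {
  vals <- c(max_abs_amplitude, max_step, max_diff_200ms, min_activity_100ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rejection criteria must be strictly positive")
  }
  structure(list(max_abs_amplitude = max_abs_amplitude, max_step = max_step,
                 max_diff_200ms = max_diff_200ms,
                 min_activity_100ms = min_activity_100ms),
            class = "rejection_criteria")
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts stimulus-locked epochs out of a continuous multichannel recording:
#' epoch k covers samples `[event_k, event_k + n_samples - 1]` (1-based,
#' inclusive), where `n_samples = srate * epoch_len_ms / 1000`. Events too
#' close to the end of the recording to fit a whole epoch are skipped with
#' a warning.
#'
#' @param continuous numeric matrix channels x samples (uV).
#' @param event_samples 1-based sample indices of epoch onsets.
#' @param epoch_len_ms epoch length in ms (default 1000).
#' @param srate sampling rate in Hz (default 256).
#' @param subject_id,condition metadata for the resulting epoch array.
#' @param montage channel labels; must match `nrow(continuous)`.
#' @return An [epoch_array()] with one epoch per usable event, in order.
#' @export
segment_epochs <- function(continuous, event_samples, epoch_len_ms = 1000,
                           srate = 256, subject_id = "S000",
                           condition = "shape", montage = montage_1020()) {
  stopifnot(is.matrix(continuous))
  ns <- round(srate * epoch_len_ms / 1000)
  total <- ncol(continuous)
  ok <- event_samples >= 1 & (event_samples + ns - 1) <= total
  if (any(!ok)) {
    warning(sum(!ok), " event(s) beyond recording end skipped")
  }
  ev <- event_samples[ok]
  dat <- array(0, dim = c(length(ev), nrow(continuous), ns))
  for (k in seq_along(ev)) {
    dat[k, , ] <- continuous[, ev[k]:(ev[k] + ns - 1)]
  }
  epoch_array(dat, subject_id = subject_id, condition = condition,
              srate = srate, montage = montage)
}

# per-row sliding-window peak-to-peak range (dense, one-sample stride);
# x: rows x samples, w: window length in samples
sliding_range <- function(x, w) {
  s <- sliding_min_max(x, as.integer(w))
  s$max - s$min
}

# fast per-row maximum via max.col (C level)
row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

#' Reject epochs violating the artifact criteria
#'
#' Applies the four criteria of [rejection_criteria()] to every channel of
#' every epoch. An epoch is rejected as a whole as soon as any channel
#' violates any criterion (no channel interpolation). Criterion (b) is
#' evaluated on adjacent-sample differences converted to uV/ms (at 256 Hz
#' one sample spans 3.906 ms); the window lengths of (c) and (d) are
#' rounded to the nearest sample count (51 and 26 samples at 256 Hz) and
#' slide one sample at a time.
#'
#' @param epochs an [epoch_array()].
#' @param criteria a [rejection_criteria()].
#' @return A list with `epochs` (the surviving epochs, unmodified and in
#'   order) and `log`, a list with `per_epoch` (data.frame: epoch, kept,
#'   violations as a semicolon-separated `channel:criterion` string),
#'   `violations` (long data.frame: epoch, channel, criterion) and
#'   `summary` (named counts per criterion a-d).
#'   Errors if no epoch survives.
#' @export
reject_epochs <- function(epochs, criteria = rejection_criteria()) {
  stopifnot(inherits(epochs, "epoch_array"),
            inherits(criteria, "rejection_criteria"))
  ne <- n_epochs(epochs)
  nchan <- dim(epochs$data)[2]
  labels <- dimnames(epochs$data)[[2]]
  srate <- epochs$srate
  ms_per_sample <- 1000 / srate
  w200 <- max(2, round(0.200 * srate))
  w100 <- max(2, round(0.100 * srate))

  ns <- dim(epochs$data)[3]
  if (ns < max(w200, w100)) {
    stop("epoch shorter than the longest criterion window")
  }
  # rows of `m` index (epoch, channel) pairs in column-major order
  m <- matrix(epochs$data, ne * nchan, ns)
  a <- row_max(abs(m)) > criteria$max_abs_amplitude
  step_uv_ms <- row_max(abs(m[, -1, drop = FALSE] -
                              m[, -ns, drop = FALSE])) / ms_per_sample
  b <- step_uv_ms > criteria$max_step
  c_ <- row_max(sliding_range(m, w200)) > criteria$max_diff_200ms
  d <- -row_max(-sliding_range(m, w100)) < criteria$min_activity_100ms
  hit <- which(a | b | c_ | d)
  viol <- lapply(hit, function(rc) {
    e <- (rc - 1) %% ne + 1
    ch <- (rc - 1) %/% ne + 1
    crits <- c("a", "b", "c", "d")[c(a[rc], b[rc], c_[rc], d[rc])]
    data.frame(epoch = e, channel = labels[ch], criterion = crits,
               stringsAsFactors = FALSE)
  })
  vdf <- if (length(viol)) do.call(rbind, viol) else
    data.frame(epoch = integer(), channel = character(),
               criterion = character(), stringsAsFactors = FALSE)
  vdf <- vdf[order(vdf$epoch), , drop = FALSE]
  kept <- !(seq_len(ne) %in% vdf$epoch)
  if (!any(kept)) {
    stop("no epoch survives artifact rejection for subject ",
         epochs$subject_id, ", condition ", epochs$condition)
  }
  per_epoch <- data.frame(
    epoch = seq_len(ne), kept = kept,
    violations = vapply(seq_len(ne), function(e) {
      v <- vdf[vdf$epoch == e, ]
      if (nrow(v) == 0) "" else
        paste(paste0(v$channel, ":", v$criterion), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  summary_counts <- vapply(c("a", "b", "c", "d"),
                           function(k) sum(vdf$criterion == k), integer(1))
  out <- epochs
  out$data <- epochs$data[kept, , , drop = FALSE]
  dimnames(out$data) <- list(NULL, labels, NULL)
  list(epochs = out,
       log = list(per_epoch = per_epoch, violations = vdf,
                  summary = summary_counts))
}
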