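#' Narrowband weighted phase lag index (wPLI)
#'
#' Estimates the wPLI between all channel pairs in a narrow band around a
#' center frequency. Each epoch is band-pass filtered with a zero-phase
#' filter (the squared magnitude response of a 4th-order Butterworth
#' band-pass of width `bandwidth`, applied in the frequency domain), the
#' analytic signal is taken, and the estimator
#' \deqn{wPLI_{ij} = |E[\mathrm{Im}(X_{ij})]| / E[|\mathrm{Im}(X_{ij})|]}
#' is formed from the cross-spectrum \eqn{X_{ij} = a_i \bar a_j}, pooling
#' the expectation over all time points and epochs (default) or over one
#' time-averaged cross-spectral value per epoch. A `trim` fraction of
#' samples is discarded at each epoch edge before pooling. Pairs with
#' identically zero `E[|Im|]` are assigned 0 with a note.
#'
#' The estimator is insensitive to zero-lag (volume-conduction) coupling:
#' identical signals give wPLI near 0, a constant quarter-cycle lag gives
#' wPLI 1.
#'
#' @param epochs an [epoch_array()] (>= 8 epochs).
#' @param f0 center frequency in Hz; `f0 - bandwidth/2` must be positive
#'   and `f0 + bandwidth/2` below the Nyquist frequency.
#' @param bandwidth band width in Hz (default 1).
#' @param trim fraction of samples discarded per epoch edge (default 0.25).
#' @param pooling `"time"` (pool Im over all samples and epochs) or
#'   `"epoch"` (one cross-spectral value per epoch).
#' @return A symmetric channels x channels matrix with zero diagonal and
#'   entries in \[0, 1\], dimnames set to the montage labels.
#' @examples
#' ep <- simulate_epochs(list(age = 30), "shape",
#'                       default_coupling_profile(), n_epochs = 12, seed = 1)
#' w <- narrowband_wpli(ep, 10)
#' w["O1", "O2"]
#' @export
narrowband_wpli <- function(epochs, f0, bandwidth = 1, trim = 0.25,
                            pooling = c("time", "epoch")) {
  out <- wpli_spectrum(epochs, freqs = f0, bandwidth = bandwidth,
                       trim = trim, pooling = pooling)
  out$w[1, , ]
}

#' Narrowband wPLI spectrum
#'
#' Applies [narrowband_wpli()] on a grid of center frequencies (default
#' the integer grid 1..48 Hz with 1-Hz bandwidth) and collects the
#' resulting matrices.
#'
#' @inheritParams narrowband_wpli
#' @param freqs center frequencies in Hz (default `1:48`).
#' @return An object of class `connectivity_spectrum`: a list with `freqs`,
#'   `w` (array `length(freqs)` x channels x channels), `labels`, and the
#'   estimation parameters.
#' @export
wpli_spectrum <- function(epochs, freqs = 1:48, bandwidth = 1, trim = 0.25,
                          pooling = c("time", "epoch")) {
  stopifnot(inherits(epochs, "epoch_array"))
  pooling <- match.arg(pooling)
  ne <- n_epochs(epochs)
  if (ne < 8) stop("need >= 8 epochs for wPLI estimation (got ", ne, ")")
  nyq <- epochs$srate / 2
  if (any(freqs - bandwidth / 2 <= 0)) {
    stop("center frequency too low: f0 - bandwidth/2 must be > 0")
  }
  if (any(freqs + bandwidth / 2 >= nyq)) {
    stop("center frequency too high: f0 + bandwidth/2 must be < ", nyq, " Hz")
  }
  if (any(freqs <= 3)) {
    message("note: at f0 <= 3 Hz a 1-s epoch holds under 4 cycles; ",
            "the estimate relies on pooling across epochs")
  }
  x <- aperm(epochs$data, c(3, 2, 1))  # samples x channels x epochs
  w <- wpli_core(x, as.numeric(freqs), bandwidth, epochs$srate, trim,
                 if (pooling == "time") 0L else 1L)
  labels <- dimnames(epochs$data)[[2]]
  warr <- aperm(w, c(3, 1, 2))
  dimnames(warr) <- list(NULL, labels, labels)
  nch <- length(labels)
  nz <- (sum(warr == 0) - length(freqs) * nch) / 2  # off-diagonal zeros
  if (nz > 0) {
    message("note: ", nz, " pair-frequency value(s) had zero E[|Im|] ",
            "and were defined as 0")
  }
  structure(list(freqs = as.numeric(freqs), w = warr, labels = labels,
                 bandwidth = bandwidth, trim = trim, pooling = pooling,
                 subject_id = epochs$subject_id, condition = epochs$condition,
                 n_epochs = ne),
            class = "connectivity_spectrum")
}

#' @export
print.connectivity_spectrum <- function(x, ...) {
  cat(sprintf("connectivity_spectrum: %s / %s - %d center frequencies (%g-%g Hz), %d channels, %d epochs\n",
              x$subject_id, x$condition, length(x$freqs), min(x$freqs),
              max(x$freqs), length(x$labels), x$n_epochs))
  invisible(x)
}

#' Aggregate a wPLI spectrum into a canonical band matrix
#'
#' Entrywise arithmetic mean of the narrowband matrices whose center
#' frequency lies within the band's nominal edges (delta 0.5-3.5, theta
#' 4-7.5, alpha 8-13.5, beta 14-29.5, gamma 30-48.5 Hz).
#'
#' @param spectrum a [wpli_spectrum()] result.
#' @param band band name (delta, theta, alpha, beta, gamma).
#' @return A symmetric channels x channels matrix of class `band_matrix`
#'   with attributes `band` and `centers`.
#' @export
aggregate_band <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "connectivity_spectrum"))
  centers <- band_centers(band)
  idx <- match(centers, spectrum$freqs)
  if (anyNA(idx)) {
    stop("spectrum lacks center frequencies for band ", band, ": ",
         paste(centers[is.na(idx)], collapse = ", "))
  }
  nch <- length(spectrum$labels)
  m <- matrix(colMeans(matrix(spectrum$w[idx, , , drop = FALSE],
                              length(idx), nch * nch)), nch, nch)
  dimnames(m) <- list(spectrum$labels, spectrum$labels)
  structure(m, band = band, centers = centers, class = c("band_matrix", "matrix"))
}
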