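#' Construct an epoch array
#'
#' The pipeline's raw material: a stack of fixed-length multichannel
#' voltage epochs for one subject and condition. Data are stored as a
#' 3-d array `epochs x channels x samples` in microvolts.
#'
#' @param data numeric array `n_epochs x n_channels x n_samples` (uV).
#' @param subject_id subject identifier.
#' @param condition condition label (e.g. "shape" or "binding").
#' @param srate sampling rate in Hz (default 256).
#' @param montage channel labels; default the 30-channel 10-20 montage.
#'   Its length must equal `dim(data)[2]`.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, subject_id = "S000", condition = "shape",
                        srate = 256, montage = montage_1020()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(montage)) {
    stop("channel dimension (", dim(data)[2], ") does not match montage (",
         length(montage), ")")
  }
  if (!all(is.finite(data))) stop("epoch data must be finite")
  dimnames(data) <- list(NULL, as.character(montage), NULL)
  structure(list(data = data, subject_id = subject_id, condition = condition,
                 srate = srate, epoch_len_ms = 1000 * dim(data)[3] / srate,
                 montage = montage),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_array: %s / %s - %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, d[1], d[2], d[3], x$srate))
  invisible(x)
}

#' Number of epochs
#' @param x an `epoch_array`.
#' @return integer epoch count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Draw a per-condition epoch count
#'
#' Artifact-free test-epoch counts are drawn from a truncated normal
#' (rounded), emulating the variability of usable epochs after recording:
#' mean 38.05 / SD 6.24 for the shape condition and 39.28 / 6.60 for
#' binding, truncated to \[20, 48\] (a subject cannot contribute more test
#' epochs than trials).
#'
#' @param condition "shape" or "binding".
#' @return Integer epoch count (uses the current RNG stream).
#' @export
draw_epoch_count <- function(condition = c("shape", "binding")) {
  condition <- match.arg(condition)
  mu <- if (condition == "shape") 38.05 else 39.28
  s <- if (condition == "shape") 6.24 else 6.60
  repeat {
    n <- round(rnorm(1, mu, s))
    if (n >= 20 && n <= 48) return(as.integer(n))
  }
}

# 1/f^a noise, one column per channel-epoch; n samples at srate Hz
pink_noise <- function(n, n_cols, srate, exponent = 1, sd_target = 5) {
  half <- n %/% 2
  k <- 1:half
  amp <- 1 / k^(exponent / 2)
  ph <- matrix(runif(half * n_cols, 0, 2 * pi), half, n_cols)
  # build Hermitian spectra: DC = 0, Nyquist real
  spec <- matrix(0 + 0i, n, n_cols)
  spec[2:(half + 1), ] <- amp * exp(1i * ph)
  spec[half + 1, ] <- Mod(spec[half + 1, ])  # Nyquist bin real
  spec[(half + 2):n, ] <- Conj(spec[half:2, , drop = FALSE])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  # scale each column to the target SD (vectorized moment-based SD)
  mu <- colMeans(x)
  sds <- sqrt(pmax(0, colMeans(x^2) - mu^2) * n / (n - 1))
  sds[sds == 0] <- 1
  sweep(x, 2, sd_target / sds, "*")
}

#' Simulate phase-coupled multichannel epochs
#'
#' Generates one subject-condition epoch array under the phase-resetting
#' oscillator model: every channel is a sum of five band-limited
#' oscillations (per-band carrier frequency, slowly drifting random phase)
#' plus 1/f noise. For each coupled pair of a band, the target channel's
#' band component copies the source's phase shifted by the band's lag on a
#' randomly chosen fraction `g(age)` of epochs and is independent on the
#' rest, which makes the expected downstream wPLI of the pair increase from
#' the null level (g = 0) towards 1 (g = 1).
#'
#' @param subject a list or single-row data.frame with at least `age`
#'   (years) and optionally `subject_id`, as produced by
#'   [simulate_cohort()]; a bare numeric age is also accepted.
#' @param condition condition label.
#' @param profile a [coupling_profile()].
#' @param n_epochs number of epochs (>= 8); when `NULL`, drawn with
#'   [draw_epoch_count()].
#' @param seed integer seed (required).
#' @param n_samples samples per epoch (default 256 = 1000 ms at 256 Hz).
#' @param srate sampling rate (Hz).
#' @return An [epoch_array()].
#' @examples
#' ep <- simulate_epochs(list(age = 30), "shape",
#'                       default_coupling_profile(), n_epochs = 10, seed = 1)
#' dim(ep$data)  # 10 x 30 x 256
#' @export
simulate_epochs <- function(subject, condition = "shape",
                            profile = default_coupling_profile(),
                            n_epochs = NULL, seed,
                            n_samples = 256, srate = 256) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(profile, "coupling_profile"))
  if (is.numeric(subject)) subject <- list(age = subject)
  age <- as.numeric(subject$age)
  subject_id <- as.character(subject$subject_id %||% "S000")

  set.seed(seed)
  if (is.null(n_epochs)) n_epochs <- draw_epoch_count(condition)
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 8) stop("n_epochs must be >= 8 for spectral estimation")

  mont <- montage_1020()
  nch <- length(mont)
  n <- n_samples
  t <- (seq_len(n) - 1) / srate
  ncols <- nch * n_epochs  # column = (epoch-1)*nch + channel

  # start from 1/f noise
  x <- pink_noise(n, ncols, srate, profile$noise$exponent, profile$noise$sd)

  for (band in names(profile$band_freqs)) {
    f <- profile$band_freqs[[band]]
    A <- profile$amplitudes[[band]]
    if (A <= 0) next
    # independent base phase per channel-epoch: offset + slow random-walk
    # drift, sampled on a coarse knot grid (one knot per `step` samples,
    # matching variance) and linearly interpolated to sample resolution
    offs <- matrix(runif(ncols, 0, 2 * pi), n, ncols, byrow = TRUE)
    step <- 8L
    nk <- ceiling(n / step) + 1L
    cs <- matrix(cumsum(rnorm(nk * ncols, 0, profile$drift_sd * sqrt(step))),
                 nk, ncols)
    walk <- rbind(0, sweep(cs, 2, c(0, cs[nk, -ncols])))
    tt <- (seq_len(n) - 1) / step
    i0 <- floor(tt) + 1L
    fr <- tt - floor(tt)
    drift <- walk[i0, , drop = FALSE] * (1 - fr) +
      walk[i0 + 1L, , drop = FALSE] * fr
    phase <- offs + drift

    spec <- profile$bands[[band]]
    if (!is.null(spec)) {
      g <- coupling_strength(profile, band, age)
      n_coupled <- round(g * n_epochs)
      coupled <- sample(n_epochs, n_coupled)
      for (p in spec$pairs) {
        src <- montage_index(p[1], mont)
        tgt <- montage_index(p[2], mont)
        for (e in coupled) {
          cs <- (e - 1) * nch + src
          ct <- (e - 1) * nch + tgt
          phase[, ct] <- phase[, cs] + spec$lag
        }
      }
    }
    x <- x + A * cos(2 * pi * f * t + phase)
  }

  dat <- aperm(array(x, dim = c(n, nch, n_epochs)), c(3, 2, 1))
  epoch_array(dat, subject_id = subject_id, condition = condition,
              srate = srate, montage = mont)
}

#' Inject artifacts into selected epochs
#'
#' Deterministic artifact fixtures for testing the rejection stage. Three
#' kinds are supported, matched to the four rejection criteria:
#' `"amplitude"` adds a half-sine deflection whose sign follows the local
#' signal so the epoch's absolute maximum is guaranteed to reach at least
#' `magnitude` uV; `"step"` adds a DC offset of `magnitude` uV from a
#' random sample onward (a jump between adjacent samples); `"flatline"`
#' rescales a 100-ms window so its peak-to-peak amplitude falls below
#' `magnitude` uV. Untouched epochs are bit-identical to the input.
#'
#' @param epochs an [epoch_array()].
#' @param kind one of "amplitude", "step", "flatline".
#' @param epoch_indices 1-based epoch indices to contaminate.
#' @param magnitude artifact size in uV (> 0).
#' @param seed integer seed for the random channel/time placement.
#' @return A new `epoch_array` with the artifacts injected.
#' @export
inject_artifacts <- function(epochs, kind = c("amplitude", "step", "flatline"),
                             epoch_indices, magnitude, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(epochs, "epoch_array"))
  if (!is.numeric(magnitude) || magnitude <= 0) stop("magnitude must be > 0")
  ne <- n_epochs(epochs)
  if (length(epoch_indices) == 0) return(epochs)
  if (any(epoch_indices < 1 | epoch_indices > ne)) {
    stop("epoch index out of range 1..", ne)
  }
  set.seed(seed)
  dat <- epochs$data
  n <- dim(dat)[3]
  srate <- epochs$srate
  w100 <- max(2, round(0.100 * srate))  # 100-ms window in samples

  for (e in epoch_indices) {
    ch <- sample(dim(dat)[2], 1)
    v <- dat[e, ch, ]
    if (kind == "amplitude") {
      len <- max(5, round(0.150 * srate))
      if (len %% 2 == 0) len <- len + 1  # odd length: bump peak is exactly `magnitude`
      s0 <- sample(n - len, 1)
      idx <- s0:(s0 + len - 1)
      peak <- idx[which.max(abs(v[idx]))]
      sgn <- if (v[peak] >= 0) 1 else -1
      bump <- magnitude * sin(pi * seq(0, 1, length.out = len))
      # center the bump on the local extremum so |v| >= magnitude there
      shift <- idx + (peak - idx[ceiling(len / 2)])
      keep <- shift >= 1 & shift <= n
      v[shift[keep]] <- v[shift[keep]] + sgn * bump[keep]
    } else if (kind == "step") {
      s0 <- sample(2:(n - 1), 1)
      v[s0:n] <- v[s0:n] + magnitude
    } else { # flatline
      s0 <- sample(n - w100, 1)
      idx <- s0:(s0 + w100 - 1)
      ptp <- diff(range(v[idx]))
      scale <- if (ptp > 0) 0.9 * magnitude / ptp else 0
      v[idx] <- mean(v[idx]) + (v[idx] - mean(v[idx])) * min(1, scale)
    }
    dat[e, ch, ] <- v
  }
  out <- epochs
  out$data <- dat
  out
}
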