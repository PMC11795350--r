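# Signal fixtures built in code. Two-channel epoch arrays keep the wPLI
# estimator tests fast; they bypass the cohort generator entirely so the
# estimator is exercised on signals with known, hand-built phase structure.

# two channels: ch2 lags ch1 by `lag` radians at frequency f; iid Gaussian
# noise added per channel
pair_epochs <- function(n_ep, lag, f = 10, amp = 10, noise = 0,
                        srate = 256, n = 256, seed = 1, random_phase = TRUE) {
  set.seed(seed)
  t <- (0:(n - 1)) / srate
  dat <- array(0, dim = c(n_ep, 2, n))
  for (e in seq_len(n_ep)) {
    ph <- if (random_phase) runif(1, 0, 2 * pi) else 0
    dat[e, 1, ] <- amp * cos(2 * pi * f * t + ph) + rnorm(n, 0, noise)
    dat[e, 2, ] <- amp * cos(2 * pi * f * t + ph - lag) + rnorm(n, 0, noise)
  }
  epoch_array(dat, subject_id = "TEST", condition = "shape",
              srate = srate, montage = c("ch1", "ch2"))
}

# two independent white-noise channels
noise_pair_epochs <- function(n_ep, sd = 1, srate = 256, n = 256, seed = 1) {
  set.seed(seed)
  dat <- array(rnorm(n_ep * 2 * n, 0, sd), dim = c(n_ep, 2, n))
  epoch_array(dat, subject_id = "TEST", condition = "shape",
              srate = srate, montage = c("ch1", "ch2"))
}

# clean sinusoidal 30-channel epochs that pass every rejection criterion
clean_epochs <- function(n_ep = 6, amp = 20, f = 10, srate = 256, n = 256,
                         seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / srate
  dat <- array(0, dim = c(n_ep, 30, n))
  for (e in seq_len(n_ep)) for (ch in 1:30) {
    dat[e, ch, ] <- amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  epoch_array(dat, subject_id = "CLEAN", condition = "shape", srate = srate)
}

# single-pair coupling profile for generator-level estimator checks
single_pair_profile <- function(g, lag = pi / 2) {
  coupling_profile(
    bands = list(alpha = list(pairs = list(c("O1", "O2")), lag = lag,
                              strength = list(type = "constant", g = g))),
    amplitudes = c(delta = 0, theta = 0, alpha = 5, beta = 0, gamma = 0)
  )
}

# exact epoch-shuffle permutation null for a 2-channel epoch array.
# Filtering and trimming are per-epoch operations, so shuffling the
# epochs of channel 2 only recombines per-epoch cross terms: with
# S_im[e,f] = sum_t Im(a1_e conj(a2_f)) and S_abs likewise, the wPLI of
# permutation pi is |sum_e S_im[e, pi(e)]| / sum_e S_abs[e, pi(e)].
# This reproduces the estimator on shuffled data exactly, at O(n_ep)
# per permutation.
perm_null_wpli <- function(epochs, f0, n_perm = 200, bw = 1, trim = 0.25,
                           seed = 1) {
  dat <- epochs$data
  ne <- dim(dat)[1]; n <- dim(dat)[3]
  srate <- epochs$srate
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * srate / n
  fl <- f0 - bw / 2; fh <- f0 + bw / 2
  r <- ifelse(f == 0, Inf, (abs(f)^2 - fl * fh) / (abs(f) * (fh - fl)))
  gain <- ifelse(is.finite(r), 1 / (1 + r^4), 0)
  mask <- numeric(n); mask[1] <- 1; mask[n / 2 + 1] <- 1; mask[2:(n / 2)] <- 2
  G <- gain * mask
  keep <- (floor(n * trim) + 1):(n - floor(n * trim))
  A1 <- vapply(seq_len(ne), function(e)
    fft(G * fft(dat[e, 1, ]), inverse = TRUE)[keep] / n,
    complex(length(keep)))
  A2 <- vapply(seq_len(ne), function(e)
    fft(G * fft(dat[e, 2, ]), inverse = TRUE)[keep] / n,
    complex(length(keep)))
  S_im <- matrix(0, ne, ne); S_abs <- matrix(0, ne, ne)
  for (e in seq_len(ne)) {
    x <- Im(A1[, e] * Conj(A2))        # keep x ne matrix
    S_im[e, ] <- colSums(x)
    S_abs[e, ] <- colSums(abs(x))
  }
  wpli_of <- function(pi_) {
    idx <- cbind(seq_len(ne), pi_)
    den <- sum(S_abs[idx])
    if (den == 0) 0 else abs(sum(S_im[idx])) / den
  }
  obs <- wpli_of(seq_len(ne))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) wpli_of(sample(ne)),
                 numeric(1))
  list(obs = obs, null = null)
}

# plain-R reference implementation of the narrowband wPLI estimator
# (full-precision gain, no bin truncation); mirrors the documented
# definition rather than the compiled code path
wpli_pair_R <- function(epochs, f0, bw = 1, trim = 0.25) {
  dat <- epochs$data
  n <- dim(dat)[3]
  srate <- epochs$srate
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * srate / n
  fl <- f0 - bw / 2; fh <- f0 + bw / 2
  r <- ifelse(f == 0, Inf, (abs(f)^2 - fl * fh) / (abs(f) * (fh - fl)))
  gain <- ifelse(is.finite(r), 1 / (1 + r^4), 0)
  mask <- numeric(n); mask[1] <- 1; mask[n / 2 + 1] <- 1; mask[2:(n / 2)] <- 2
  G <- gain * mask
  t0 <- floor(n * trim)
  keep <- (t0 + 1):(n - t0)
  sIm <- sAbs <- 0
  for (e in seq_len(dim(dat)[1])) {
    a1 <- fft(G * fft(dat[e, 1, ]), inverse = TRUE)[keep] / n
    a2 <- fft(G * fft(dat[e, 2, ]), inverse = TRUE)[keep] / n
    im <- Im(a1 * Conj(a2))
    sIm <- sIm + sum(im)
    sAbs <- sAbs + sum(abs(im))
  }
  if (sAbs == 0) 0 else abs(sIm) / sAbs
}
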