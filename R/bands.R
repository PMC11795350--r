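#' Canonical EEG frequency bands
#'
#' The five canonical bands with their nominal edges and the 1-Hz-spaced
#' center frequencies falling strictly inside each band. Narrowband wPLI is
#' estimated on the integer center-frequency grid 1..48 Hz and averaged into
#' these bands.
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` and a list column
#'   `centers` of integer center frequencies.
#' @examples
#' canonical_bands()
#' band_centers("alpha")  # 8..13
#' @export
canonical_bands <- function() {
  b <- data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 14, 30),
    f_hi = c(3.5, 7.5, 13.5, 29.5, 48.5),
    stringsAsFactors = FALSE
  )
  # integer centers strictly contained in [f_lo, f_hi]
  b$centers <- lapply(seq_len(nrow(b)), function(i) {
    k <- 1:48
    k[k >= b$f_lo[i] & k <= b$f_hi[i]]
  })
  b
}

#' @rdname canonical_bands
#' @param band band name, one of delta, theta, alpha, beta, gamma.
#' @export
band_centers <- function(band) {
  tab <- canonical_bands()
  i <- match(band, tab$band)
  if (is.na(i)) stop("unknown band: ", band)
  tab$centers[[i]]
}
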