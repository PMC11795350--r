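#' Construct a phase-coupling profile for the epoch generator
#'
#' A coupling profile is the ground truth behind a synthetic cohort: for
#' each frequency band it names the channel pairs that are phase-coupled,
#' the phase lag between them, and how the coupling strength `g` depends on
#' age. Coupling is directional in the generator (the second channel of a
#' pair copies the band-limited phase of the first, shifted by the lag) and
#' acts on a fraction `g` of epochs, so the downstream wPLI of a coupled
#' pair rises from the estimator's null level at `g = 0` towards 1 at
#' `g = 1`.
#'
#' @param bands named list (names among delta/theta/alpha/beta/gamma); each
#'   element a list with `pairs` (list of length-2 character vectors of
#'   montage labels, source first), `lag` (phase lag in radians, must avoid
#'   0 and pi where the imaginary cross-spectrum vanishes), and `strength`,
#'   one of
#'   `list(type = "constant", g = ...)`,
#'   `list(type = "linear", g_young = ..., g_old = ...)` (linear in age
#'   between `age_range`), or
#'   `list(type = "changepoint", age0 = ..., g_before = ..., slope = ...)`
#'   (constant until `age0`, then linear with `slope` per year).
#' @param amplitudes named numeric: oscillation amplitude per band (uV).
#' @param band_freqs named numeric: carrier frequency per band (Hz).
#' @param noise list with `exponent` (spectral 1/f^a exponent) and `sd`
#'   (broadband noise SD in uV).
#' @param drift_sd per-sample SD of the random-walk phase drift (radians).
#' @param age_range age range the strength curves are defined over.
#' @return An object of class `coupling_profile`.
#' @seealso [default_coupling_profile()], [coupling_strength()]
#' @export
coupling_profile <- function(bands = list(),
                             amplitudes = c(delta = 2, theta = 2, alpha = 5,
                                            beta = 1.5, gamma = 0.8),
                             band_freqs = c(delta = 2, theta = 6, alpha = 10,
                                            beta = 20, gamma = 40),
                             noise = list(exponent = 1, sd = 2.5),
                             drift_sd = 0.02,
                             age_range = c(20, 81)) {
  known <- canonical_bands()$band
  mont <- montage_1020()
  if (length(bands)) {
    if (is.null(names(bands)) || !all(names(bands) %in% known)) {
      stop("bands must be named with canonical band labels")
    }
    for (nm in names(bands)) {
      b <- bands[[nm]]
      seen <- character()
      for (p in b$pairs) {
        if (length(p) != 2) stop("coupled pairs must have length 2")
        montage_index(p, mont)  # errors on unknown labels
        # a target already used earlier in this band would overwrite (and
        # silently undo) the earlier coupling; stars and ordered chains are ok
        if (p[2] %in% seen) {
          stop("band ", nm, ": channel ", p[2],
               " is a coupling target after already appearing in an earlier ",
               "pair; reorder pairs or pick a distinct target")
        }
        seen <- union(seen, p)
      }
      lag <- b$lag
      if (!is.finite(lag) || abs(lag) <= 0 || abs(lag) >= pi) {
        stop("band ", nm, ": phase lag must satisfy 0 < |lag| < pi")
      }
      if (!b$strength$type %in% c("constant", "linear", "changepoint")) {
        stop("unknown strength type: ", b$strength$type)
      }
    }
  }
  structure(list(bands = bands, amplitudes = amplitudes,
                 band_freqs = band_freqs, noise = noise,
                 drift_sd = drift_sd, age_range = age_range),
            class = "coupling_profile")
}

#' Age-dependent coupling strength of a band
#'
#' @param profile a [coupling_profile()].
#' @param band band name.
#' @param age age in years.
#' @return Coupling strength `g` clipped to \[0, 1\]; 0 for bands without a
#'   coupling entry.
#' @export
coupling_strength <- function(profile, band, age) {
  stopifnot(inherits(profile, "coupling_profile"))
  b <- profile$bands[[band]]
  if (is.null(b)) return(0)
  s <- b$strength
  g <- switch(s$type,
    constant = s$g,
    linear = {
      ar <- profile$age_range
      s$g_young + (s$g_old - s$g_young) * (age - ar[1]) / (ar[2] - ar[1])
    },
    changepoint = s$g_before + s$slope * pmax(0, age - s$age0)
  )
  pmin(1, pmax(0, g))
}

#' Default study coupling profile
#'
#' The reference synthetic-cohort conditions: a posterior alpha chain
#' whose coupling declines after midlife (the age effect the pipeline is
#' built to detect), a stable frontal-midline theta star, and weaker
#' stable delta, beta and gamma couplings. Within each band the coupled
#' pairs form a star or ordered chain (distinct targets), so every listed
#' pair carries a well-defined phase lag. Effect sizes are calibration
#' choices of the generator, not estimates of any real cohort.
#'
#' @return A [coupling_profile()].
#' @export
default_coupling_profile <- function() {
  coupling_profile(bands = list(
    delta = list(pairs = list(c("Fp1", "Fp2")),
                 lag = pi / 4,
                 strength = list(type = "constant", g = 0.3)),
    theta = list(pairs = list(c("Fz", "F3"), c("Fz", "F4"), c("Fz", "FCz"),
                              c("Fz", "Cz")),
                 lag = pi / 4,
                 strength = list(type = "constant", g = 0.5)),
    # ordered chain: on coupled epochs every chain member locks to the
    # previous one, so all pairs k steps apart carry lag k * 2pi/7 (never
    # 0 or pi for k <= 5) and the six nodes form a full wPLI clique with
    # triangles - the substrate of the alpha clustering decline
    alpha = list(pairs = list(c("Pz", "P3"), c("P3", "P4"), c("P4", "O1"),
                              c("O1", "O2"), c("O2", "Oz")),
                 lag = 2 * pi / 7,
                 strength = list(type = "changepoint", age0 = 50,
                                 g_before = 0.7, slope = -0.01)),
    beta = list(pairs = list(c("Cz", "C3"), c("Cz", "C4")),
                lag = pi / 3,
                strength = list(type = "constant", g = 0.4)),
    gamma = list(pairs = list(c("FC3", "FC4")),
                 lag = pi / 2,
                 strength = list(type = "constant", g = 0.25))
  ))
}
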