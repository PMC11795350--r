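#' Coupling profile for the parameter-recovery study
#'
#' Ground truth with one true age effect and one true null: a posterior
#' alpha chain (Pz - P3 - P4 - O1 - O2 - Oz, lag 2pi/7 per link, so all 15
#' pairs of the six chain members are phase-locked at lags away from 0 and
#' pi and form a full wPLI clique with triangles) whose coupling declines
#' linearly from 0.85 at age 20 to 0.15 at age 81, and a frontal-midline
#' theta star (Fz to F3, F4, FCz, Cz; a star has no triangles) with
#' constant coupling 0.5. Only these two bands carry oscillations (the
#' remaining band amplitudes are zero), so the recovery study isolates the
#' contrast between an age-declining and an age-stable clustering
#' coefficient.
#'
#' @return A [coupling_profile()].
#' @export
recovery_profile <- function() {
  coupling_profile(
    bands = list(
      theta = list(pairs = list(c("Fz", "F3"), c("Fz", "F4"), c("Fz", "FCz"),
                                c("Fz", "Cz")),
                   lag = pi / 4,
                   strength = list(type = "constant", g = 0.5)),
      alpha = list(pairs = list(c("Pz", "P3"), c("P3", "P4"), c("P4", "O1"),
                                c("O1", "O2"), c("O2", "Oz")),
                   lag = 2 * pi / 7,
                   strength = list(type = "linear", g_young = 0.85,
                                   g_old = 0.15))
    ),
    amplitudes = c(delta = 0, theta = 2, alpha = 5, beta = 0, gamma = 0),
    # alpha carrier at 12 Hz: far enough from the 7-Hz theta-band edge that
    # band-pass leakage of the (age-varying) alpha coupling cannot induce a
    # spurious age trend in the theta-band null metric
    band_freqs = c(delta = 2, theta = 6, alpha = 12, beta = 20, gamma = 40)
  )
}

#' One replicate of the end-to-end parameter-recovery study
#'
#' Runs the full in-memory pipeline on a fresh synthetic cohort under
#' [recovery_profile()]: simulate epochs per subject, apply artifact
#' rejection, estimate the wPLI spectrum on the theta and alpha centers,
#' aggregate both bands, threshold at 55%, take the mean clustering
#' coefficient, and fit the age additive model (k = 12) to the alpha
#' (true effect) and theta (true null) clustering outcomes.
#'
#' @param seed replicate seed.
#' @param n_subjects cohort size (default 100).
#' @param n_epochs epochs per subject (default 16; well above the
#'   spectral-estimation minimum while keeping a replicate inexpensive).
#' @param proportion threshold proportion (default 0.55).
#' @param alpha significance level for flagging an age effect.
#' @return A list: `alpha_p`, `theta_p` (smooth-term p-values),
#'   `alpha_flagged`, `theta_flagged`, `success` (effect flagged and null
#'   not), and the per-subject metric data.frame.
#' @export
run_recovery_replicate <- function(seed, n_subjects = 100, n_epochs = 16,
                                   proportion = 0.55, alpha = 0.05) {
  profile <- recovery_profile()
  cohort <- simulate_cohort(n_subjects, 20, 81, seed = seed)
  freqs <- c(band_centers("theta"), band_centers("alpha"))
  cc_alpha <- cc_theta <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    ep <- simulate_epochs(cohort[i, ], "shape", profile,
                          n_epochs = n_epochs,
                          seed = sub_seed(seed, i, 1, 3))
    ep <- reject_epochs(ep)$epochs
    spec <- suppressMessages(wpli_spectrum(ep, freqs = freqs))
    ga <- threshold_proportional(aggregate_band(spec, "alpha"), proportion)
    gt <- threshold_proportional(aggregate_band(spec, "theta"), proportion)
    cc_alpha[i] <- clustering_onnela(ga)$C
    cc_theta[i] <- clustering_onnela(gt)$C
  }
  df <- data.frame(subject_id = cohort$subject_id, age = cohort$age,
                   cc_alpha = cc_alpha, cc_theta = cc_theta)
  fa <- fit_age_gam(df$cc_alpha, df$age, k = 12, outcome = "cc_alpha")
  ft <- fit_age_gam(df$cc_theta, df$age, k = 12, outcome = "cc_theta")
  alpha_p <- fa$smooth[["p"]]
  theta_p <- ft$smooth[["p"]]
  list(alpha_p = alpha_p, theta_p = theta_p,
       alpha_flagged = alpha_p < alpha,
       theta_flagged = theta_p < alpha,
       success = (alpha_p < alpha) && !(theta_p < alpha),
       metrics = df)
}
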