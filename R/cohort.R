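#' Mean age-response curves for cognitive and behavioural outcomes
#'
#' The deterministic mean curves used by [simulate_cognition()]. Each curve
#' is a piecewise-linear function of age chosen to emulate the qualitative
#' lifespan trajectories the pipeline is designed to detect: accuracy
#' declining after midlife, reaction time rising late, language skills
#' peaking around age 45, visuospatial ability dropping sharply after 70.
#' Exposing the curves lets recovery tests compare generated scores against
#' exact ground truth.
#'
#' @return A named list of functions of age (years). Accuracy curves return
#'   percent correct, reaction-time curves milliseconds, domain curves
#'   z-scores, and `mmse`/`bdi` raw questionnaire scores.
#' @export
cognition_curves <- function() {
  hinge <- function(a, a0) pmax(0, a - a0)
  list(
    acc_shape      = function(a) 95 - 0.06 * (a - 20) - 0.45 * hinge(a, 50),
    acc_binding    = function(a) 88 - 0.10 * (a - 20) - 0.25 * hinge(a, 45),
    rt_shape       = function(a) 850 + 3.0 * (a - 20) + 8.0 * hinge(a, 65),
    rt_binding     = function(a) 950 + 4.0 * (a - 20) + 12.0 * hinge(a, 70),
    episodic       = function(a) 0.6 - 0.012 * (a - 20) - 0.020 * hinge(a, 50),
    visual         = function(a) 0.7 - 0.015 * (a - 20) - 0.025 * hinge(a, 60),
    attention      = function(a) 0.5 - 0.010 * (a - 20) - 0.020 * hinge(a, 50),
    executive      = function(a) 0.4 - 0.002 * (a - 20) - 0.020 * hinge(a, 50),
    language       = function(a) 0.2 + 0.02 * (pmin(a, 45) - 20) -
                                 0.015 * hinge(a, 45),
    visuospatial   = function(a) 0.5 - 0.005 * (a - 20) - 0.060 * hinge(a, 70),
    mmse           = function(a) 29.6 - 0.015 * hinge(a, 50),
    bdi            = function(a) 7 + 0 * a
  )
}

# default per-outcome noise standard deviations (same units as the curves)
cognition_noise_defaults <- function() {
  c(acc_shape = 4, acc_binding = 5, rt_shape = 80, rt_binding = 90,
    episodic = 0.8, visual = 0.8, attention = 0.8, executive = 0.8,
    language = 0.8, visuospatial = 0.8, mmse = 0.8, bdi = 4)
}

#' Simulate cognitive, behavioural and screening scores for one subject
#'
#' Draws every outcome as its mean age curve (see [cognition_curves()]) plus
#' Gaussian noise. Accuracy is clipped to \[0, 100\], reaction times to at
#' least 200 ms, MMSE rounded and clipped to the inclusion range \[27, 30\],
#' BDI rounded and clipped to \[0, 17\] (the cohort generator emulates
#' already-screened participants). Domain z-scores are left unclipped and
#' unrounded so that, at zero noise, they reproduce the mean curves exactly.
#'
#' @param age age in years; must lie within `age_range`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as when called from [simulate_cohort()]).
#' @param noise_sd named numeric vector of noise standard deviations; any
#'   subset of the names of `cognition_noise_defaults()` may be overridden.
#'   Setting all to 0 yields the exact mean curves for the domain scores.
#' @param age_range permissible age range (years).
#' @return A list with elements `mmse`, `bdi`, `domain_scores` (named numeric
#'   of length 6), `accuracy` (named: shape, binding; percent correct), and
#'   `rt` (named: shape, binding; ms).
#' @export
simulate_cognition <- function(age, seed = NULL,
                               noise_sd = NULL,
                               age_range = c(20, 81)) {
  if (!is.finite(age) || age < age_range[1] || age > age_range[2]) {
    stop("age ", age, " outside configured range [",
         age_range[1], ", ", age_range[2], "]")
  }
  if (!is.null(seed)) set.seed(seed)
  sds <- cognition_noise_defaults()
  if (!is.null(noise_sd)) {
    stopifnot(all(names(noise_sd) %in% names(sds)))
    sds[names(noise_sd)] <- noise_sd
  }
  cur <- cognition_curves()
  draw <- function(nm) cur[[nm]](age) + rnorm(1, 0, sds[[nm]])

  acc <- c(shape = draw("acc_shape"), binding = draw("acc_binding"))
  acc <- pmin(pmax(acc, 0), 100)   # argument order keeps the names
  rt <- c(shape = draw("rt_shape"), binding = draw("rt_binding"))
  rt <- pmax(rt, 200)
  dom <- c(episodic = draw("episodic"), visual = draw("visual"),
           attention = draw("attention"), executive = draw("executive"),
           language = draw("language"), visuospatial = draw("visuospatial"))
  mmse <- round(pmin(30, pmax(27, draw("mmse"))))
  bdi <- round(pmin(17, pmax(0, draw("bdi"))))
  list(mmse = mmse, bdi = bdi, domain_scores = dom, accuracy = acc, rt = rt)
}

#' Simulate a screened cross-sectional cohort
#'
#' Generates `n_subjects` subject records with ages stratified-uniform over
#' the configured range (one uniform draw per equal-width stratum, so even a
#' small cohort covers the whole lifespan), demographics matching a
#' screened community sample (MMSE >= 27, BDI <= 17), and cognitive /
#' behavioural scores from [simulate_cognition()].
#'
#' @param n_subjects number of subjects (>= 2); default 39.
#' @param age_min,age_max age range in years; defaults 20 and 81.
#' @param seed integer seed (required; the cohort is a pure function of it).
#' @param noise_sd passed to [simulate_cognition()].
#' @return A data.frame with one row per subject: `subject_id`, `age`, `sex`,
#'   `education`, `mmse`, `bdi`, the six domain z-scores (`z_episodic` ..
#'   `z_visuospatial`), `acc_shape`, `acc_binding`, `rt_shape`, `rt_binding`.
#' @examples
#' coh <- simulate_cohort(10, seed = 1)
#' range(coh$age)
#' @export
simulate_cohort <- function(n_subjects = 39, age_min = 20, age_max = 81,
                            seed, noise_sd = NULL) {
  if (missing(seed)) stop("seed is required")
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be >= 2")
  }
  if (age_min >= age_max) stop("age_min must be < age_max")
  n <- as.integer(n_subjects)
  set.seed(seed)

  # stratified uniform ages over [age_min, age_max]
  breaks <- seq(age_min, age_max, length.out = n + 1)
  age <- runif(n, breaks[-(n + 1)], breaks[-1])

  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(24, 15) / 39)
  education <- round(pmin(22, pmax(8, rnorm(n, 16.15, 2.88))))

  cog <- lapply(age, function(a) simulate_cognition(a, noise_sd = noise_sd,
                                                    age_range = c(age_min, age_max)))
  dom <- do.call(rbind, lapply(cog, function(z) z$domain_scores))
  colnames(dom) <- paste0("z_", colnames(dom))

  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, sex = sex, education = education,
    mmse = vapply(cog, `[[`, numeric(1), "mmse"),
    bdi = vapply(cog, `[[`, numeric(1), "bdi"),
    dom,
    acc_shape = vapply(cog, function(z) z$accuracy[["shape"]], numeric(1)),
    acc_binding = vapply(cog, function(z) z$accuracy[["binding"]], numeric(1)),
    rt_shape = vapply(cog, function(z) z$rt[["shape"]], numeric(1)),
    rt_binding = vapply(cog, function(z) z$rt[["binding"]], numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate one paradigm trial sequence
#'
#' Builds the 96-trial test sequence of the change-detection paradigm:
#' 48 trials per condition (shape, binding), presented in counterbalanced
#' blocks of 12 trials whose starting condition is randomized, with the
#' probe display drawn 'same' or 'different' independently with probability
#' 0.5 on every trial. Study display duration is 1000 ms and the
#' study-test delay 1200 ms on all trials.
#'
#' @param seed integer seed (required).
#' @param block_len trials per condition block; must divide 48.
#' @return An object of class `trial_sequence`: a data.frame with columns
#'   `trial`, `condition`, `probe_type`, `study_duration_ms`, `delay_ms`,
#'   plus a `counts` attribute (trials per condition).
#' @examples
#' tr <- simulate_trials(seed = 1)
#' table(tr$condition)  # 48 / 48
#' @export
simulate_trials <- function(seed, block_len = 12) {
  if (missing(seed)) stop("seed is required")
  stopifnot(48 %% block_len == 0)
  set.seed(seed)
  n_blocks_per_cond <- 48 %/% block_len
  first <- sample(c("shape", "binding"), 1)
  second <- setdiff(c("shape", "binding"), first)
  block_order <- rep(c(first, second), n_blocks_per_cond)
  condition <- rep(block_order, each = block_len)
  probe <- ifelse(rbinom(96, 1, 0.5) == 1, "same", "different")
  out <- data.frame(
    trial = 1:96,
    condition = condition,
    probe_type = probe,
    study_duration_ms = 1000,
    delay_ms = 1200,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- table(out$condition)
  class(out) <- c("trial_sequence", "data.frame")
  out
}
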