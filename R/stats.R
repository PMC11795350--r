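#' Penalized-spline additive model of an age effect
#'
#' Fits `y = b0 + f(age) + e` with `f` a penalized cubic regression spline
#' of basis dimension `k`, smoothing parameter chosen by restricted
#' maximum likelihood (mgcv). Returns the quantities reported for every
#' outcome: intercept estimate / SE / t / p and the smooth term's
#' effective degrees of freedom (EDF), reference df, F and approximate
#' p-value. With nothing to explain, the penalty shrinks the smooth
#' towards a straight line (EDF near 1).
#'
#' @param y numeric outcome vector.
#' @param age age in years, same length as `y`.
#' @param k spline basis dimension: 10 for cognitive/behavioural outcomes,
#'   12 for graph-theoretical outcomes.
#' @param outcome optional outcome name carried into the result.
#' @param sp optional fixed smoothing parameter; overrides REML selection
#'   (a very large value forces the smooth to its linear null space,
#'   reproducing ordinary least squares).
#' @return An object of class `gam_fit`: list with `outcome`, `intercept`
#'   (estimate, se, t, p), `smooth` (edf, ref_df, F, p), `k`, `method`,
#'   `n`, and the underlying `model`.
#' @export
fit_age_gam <- function(y, age, k, outcome = "y", sp = NULL) {
  stopifnot(length(y) == length(age))
  keep <- stats::complete.cases(y, age)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    y <- y[keep]; age <- age[keep]
  }
  n <- length(y)
  if (n < k) stop("need n >= k (n = ", n, ", k = ", k, ")")
  if (sd(y) == 0) stop("constant outcome: degenerate fit")
  dat <- data.frame(y = y, age = age)
  model <- mgcv::gam(y ~ s(age, bs = "cr", k = k), data = dat,
                     method = "REML", sp = sp)
  sm <- summary(model)
  structure(list(
    outcome = outcome,
    intercept = c(estimate = unname(sm$p.table[1, 1]),
                  se = unname(sm$p.table[1, 2]),
                  t = unname(sm$p.table[1, 3]),
                  p = unname(sm$p.table[1, 4])),
    smooth = c(edf = unname(sm$s.table[1, "edf"]),
               ref_df = unname(sm$s.table[1, "Ref.df"]),
               F = unname(sm$s.table[1, "F"]),
               p = unname(sm$s.table[1, "p-value"])),
    k = k, method = "REML", n = n, model = model),
    class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("gam_fit '%s' (n=%d, k=%d, %s)\n", x$outcome, x$n, x$k,
              x$method))
  cat(sprintf("  intercept %.3f (SE %.3f, t=%.2f, p=%.3g)\n",
              x$intercept["estimate"], x$intercept["se"], x$intercept["t"],
              x$intercept["p"]))
  cat(sprintf("  smooth EDF=%.2f Ref.df=%.2f F=%.2f p=%.3g\n",
              x$smooth["edf"], x$smooth["ref_df"], x$smooth["F"],
              x$smooth["p"]))
  invisible(x)
}

#' Partial Pearson correlation controlling for a covariate
#'
#' Correlation of the residuals from separate linear regressions of `x`
#' and `y` on the covariate (age, in this pipeline), with the p-value from
#' `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector (e.g. age).
#' @param x_name,y_name optional names carried into the result.
#' @return A one-row data.frame: `x`, `y`, `r`, `p`, `n`.
#' @export
partial_corr <- function(x, y, covariate, x_name = "x", y_name = "y") {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n)
  if (n < 4) stop("need n >= 4 for a partial correlation")
  if (!all(is.finite(c(x, y, covariate)))) stop("inputs must be finite")
  rx <- residuals(lm(x ~ covariate))
  ry <- residuals(lm(y ~ covariate))
  if (sd(rx) <= 1e-10 * max(1, sd(x)) || sd(ry) <= 1e-10 * max(1, sd(y))) {
    stop("zero residual variance: partial correlation undefined")
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 3) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 3)
  }
  data.frame(x = x_name, y = y_name, r = r, p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate control: adjusted p-values (capped at
#' 1, order-preserving) and the step-up rejection flags at level `q`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return A list: `adjusted` (same order as input), `reject` (logical).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Age-partialled correlation screen
#'
#' The reporting rule applied to metric-cognition associations: metrics
#' are first restricted to those with a significant additive-model age
#' effect (smooth p < `alpha`), all candidate (metric, score) partial
#' correlations controlling for age are computed, BH adjustment is applied
#' within each metric family, and a pair is reported when both
#' `|r| > min_abs_r` and the BH-adjusted p is below `q`. The output is
#' sorted by `|r|` descending.
#'
#' @param data data.frame holding metrics, scores and the age column.
#' @param metrics character vector of metric column names.
#' @param scores character vector of score column names.
#' @param family named character vector mapping each metric to its family
#'   (e.g. integration / segregation / global); defaults to one family.
#' @param age_col name of the age column (default "age").
#' @param k spline basis dimension for the age-effect pre-filter
#'   (default 12, the graph-metric setting).
#' @param alpha significance level of the pre-filter (default 0.05).
#' @param min_abs_r moderate-effect threshold (default 0.400).
#' @param q FDR level (default 0.05).
#' @return A data.frame with one row per candidate pair: `metric`,
#'   `family`, `score`, `r`, `p`, `n`, `q_bh`, `reported`, sorted by `|r|`
#'   descending. Zero rows when no metric passes the pre-filter.
#' @export
screen_correlations <- function(data, metrics, scores, family = NULL,
                                age_col = "age", k = 12, alpha = 0.05,
                                min_abs_r = 0.400, q = 0.05) {
  stopifnot(all(c(metrics, scores, age_col) %in% names(data)))
  if (is.null(family)) {
    family <- stats::setNames(rep("all", length(metrics)), metrics)
  }
  stopifnot(all(metrics %in% names(family)))
  age <- data[[age_col]]

  gam_p <- vapply(metrics, function(m) {
    fit_age_gam(data[[m]], age, k = k, outcome = m)$smooth[["p"]]
  }, numeric(1))
  candidates <- metrics[gam_p < alpha]
  empty <- data.frame(metric = character(), family = character(),
                      score = character(), r = numeric(), p = numeric(),
                      n = integer(), q_bh = numeric(), reported = logical(),
                      stringsAsFactors = FALSE)
  if (length(candidates) == 0) return(empty)

  rows <- list()
  for (m in candidates) {
    for (s in scores) {
      pc <- partial_corr(data[[m]], data[[s]], age, m, s)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, family = unname(family[m]), score = s,
        r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- NA_real_
  for (fam in unique(out$family)) {
    i <- out$family == fam
    out$q_bh[i] <- bh_adjust(out$p[i], q)$adjusted
  }
  out$reported <- abs(out$r) > min_abs_r & out$q_bh < q
  out[order(-abs(out$r)), , drop = FALSE]
}
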