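#' Accuracy metrics from score moments
#'
#' `score_r2()` is the squared correlation between the polygenic score and
#' the tested trait; `score_mse()` the prediction mean square error;
#' `score_ncp()` the non-centrality parameter of the 1-df chi-squared
#' association test of the score in a replication sample of `n2` subjects.
#' The NCP is the Wald non-centrality of the score regression,
#' `n2 * r2 / (1 - r2)`, whose residual variance shrinks as the score
#' explains more of the trait.
#'
#' @param moments a [score_moments()] object.
#' @param n2 replication sample size.
#' @return A non-negative number.
#' @export
score_r2 <- function(moments) {
  stopifnot(inherits(moments, "score_moments"))
  if (moments$covSy == 0) return(0)
  moments$covSy^2 / (moments$varS * moments$varY2)
}

#' @rdname score_r2
#' @export
score_mse <- function(moments) {
  stopifnot(inherits(moments, "score_moments"))
  moments$varY2 - 2 * moments$covSy + moments$varS
}

#' @rdname score_r2
#' @export
score_ncp <- function(moments, n2) {
  stopifnot(is.numeric(n2), n2 >= 1)
  r2 <- score_r2(moments)
  n2 * r2 / (1 - r2)
}

#' Power of the two-tailed chi-squared association test
#'
#' Tail probability of the non-central 1-df chi-squared distribution beyond
#' the central critical value at level `alpha`.
#'
#' @param ncp non-centrality parameter.
#' @param alpha two-tailed significance level.
#' @return Power, in `[alpha, 1]`.
#' @examples
#' chisq_power(7.849)  # 0.80
#' @export
chisq_power <- function(ncp, alpha = 0.05) {
  stopifnot(is.numeric(ncp), all(ncp >= 0), alpha > 0, alpha < 1)
  out <- rep(1, length(ncp))
  fin <- is.finite(ncp)
  out[fin] <- stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1,
                            ncp = ncp[fin], lower.tail = FALSE)
  out
}

#' Expected significance of the score association
#'
#' The -log10 two-sided P-value of the 1-df chi-squared statistic evaluated
#' at its expectation, `1 + ncp`.  Used to draw curves of expected
#' significance against the marker selection threshold.
#'
#' @param ncp non-centrality parameter.
#' @param at either `"mean"` (default; statistic at its mean `1 + ncp`) or
#'   `"median"` (statistic at its median).
#' @return Expected `-log10(P)`.
#' @export
expected_neglog10p <- function(ncp, at = c("mean", "median")) {
  at <- match.arg(at)
  stopifnot(is.numeric(ncp), all(ncp >= 0))
  stat <- switch(at,
                 mean = 1 + ncp,
                 median = stats::qchisq(0.5, df = 1, ncp = ncp))
  out <- rep(Inf, length(ncp))
  fin <- is.finite(stat)
  out[fin] <- -stats::pchisq(stat[fin], df = 1, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
  out
}

#' Full accuracy and power report for a design
#'
#' Evaluates every accuracy and association metric of the estimated polygenic
#' score for a given architecture and design: observed-scale R-squared (and
#' liability-scale R-squared for a binary trait 2), mean square error,
#' non-centrality parameter and power of the association test, AUC (binary
#' trait 2), and the expected `-log10(P)` of the score association.
#'
#' The mean square error is not reported for the allele-count estimator,
#' whose score scale is arbitrary.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()].
#' @return An object of class `"accuracy_report"` with fields `r2_obs`,
#'   `r2_liab`, `mse`, `ncp`, `power`, `auc`, `exp_neglog10p`, plus the
#'   moments and inputs.
#' @examples
#' fr <- accuracy_report(polygenic_model(m = 1e5, vg1 = 1),
#'                       study_design(n1 = 1575, n2 = 175, q0 = 0.4, q1 = 0.5))
#' fr$power  # 0.068
#' @export
accuracy_report <- function(model, design) {
  mo <- score_moments(model, design)
  r2 <- score_r2(mo)
  ncp <- design$n2 * r2 / (1 - r2)
  binary2 <- design$trait2$kind == "binary"
  r2l <- if (binary2) liability_r2(r2, design$trait2$K, design$trait2$P)
         else NA_real_
  auc <- if (binary2) {
    rho2 <- if (mo$varS > 0) mo$covS_liab^2 / mo$varS else 0
    auc_from_liability_r2(rho2, design$trait2$K)
  } else NA_real_
  mse <- if (design$estimator == "allele_count") NA_real_ else score_mse(mo)
  structure(list(r2_obs = r2, r2_liab = r2l, mse = mse, ncp = ncp,
                 power = chisq_power(ncp, design$alpha),
                 auc = auc, exp_neglog10p = expected_neglog10p(ncp),
                 alpha = design$alpha, moments = mo,
                 model = model, design = design),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Polygenic score accuracy report\n")
  cat(sprintf("  R^2 (observed scale):  %.6g\n", x$r2_obs))
  if (!is.na(x$r2_liab))
    cat(sprintf("  R^2 (liability scale): %.6g\n", x$r2_liab))
  if (!is.na(x$mse))
    cat(sprintf("  prediction MSE:        %.6g\n", x$mse))
  cat(sprintf("  association NCP:       %.6g\n", x$ncp))
  cat(sprintf("  power (alpha = %g):    %.4g\n", x$alpha, x$power))
  if (!is.na(x$auc))
    cat(sprintf("  AUC:                   %.6g\n", x$auc))
  cat(sprintf("  expected -log10(P):    %.4g\n", x$exp_neglog10p))
  invisible(x)
}

#' Metric as a function of the selection threshold
#'
#' Evaluates a metric over a grid of upper P-value thresholds `q1`, holding
#' the rest of the design fixed.  Used to draw expected-significance or AUC
#' curves against the inclusion threshold.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()]; its `q1` is replaced by each grid value.
#' @param metric one of `"exp_neglog10p"`, `"ncp"`, `"r2"`, `"auc"`,
#'   `"power"`.
#' @param q1_grid thresholds to evaluate (default: 50 log-spaced points from
#'   1e-6 to 1).
#' @return A data frame with columns `q1` and `value`.
#' @export
threshold_curve <- function(model, design,
                            metric = c("exp_neglog10p", "ncp", "r2", "auc", "power"),
                            q1_grid = 10^seq(-6, 0, length.out = 50)) {
  metric <- match.arg(metric)
  vals <- vapply(q1_grid, function(q1) {
    d <- design
    d$q1 <- q1
    if (d$q0 >= q1) return(NA_real_)
    rep <- accuracy_report(model, d)
    switch(metric, exp_neglog10p = rep$exp_neglog10p, ncp = rep$ncp,
           r2 = rep$r2_obs, auc = rep$auc, power = rep$power)
  }, numeric(1))
  data.frame(q1 = q1_grid, value = vals)
}
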