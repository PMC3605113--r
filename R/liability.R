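#' Liability threshold for a binary trait
#'
#' Under the liability threshold model a subject exhibits the trait when a
#' standard-normal latent liability exceeds the threshold set by the
#' population prevalence.
#'
#' @param K population prevalence, in (0, 1).
#' @return A list with `T`, the upper-`K` quantile of the standard normal,
#'   and `z`, the normal density at `T`.
#' @examples
#' liability_threshold(0.01)  # T = 2.326, z = 0.0267
#' @export
liability_threshold <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0, K < 1)
  T <- stats::qnorm(1 - K)
  list(T = T, z = stats::dnorm(T))
}

# Scale factor taking a per-marker effect on liability to the corresponding
# effect on the 0/1 trait regressed on a standardised genotype.  Prospective
# sampling (P = K) gives the density z at the threshold; case/control
# ascertainment multiplies by P(1-P)/(K(1-K)), assuming the genotype variance
# remains approximately 1 in the ascertained sample.
liability_obs_factor <- function(K, P = K) {
  lt <- liability_threshold(K)
  lt$z * P * (1 - P) / (K * (1 - K))
}

#' Transform a liability-scale effect to the observed 0/1 scale
#'
#' Small genetic effects on liability map linearly onto the observed (0/1)
#' trait.  In a prospective sample the factor is the normal density at the
#' liability threshold; under case/control ascertainment with case fraction
#' `P` it is multiplied by `P(1-P) / (K(1-K))`, so the two transforms agree
#' when `P = K`.  The genotype variance is taken as 1 in the ascertained
#' sample, an approximation that degrades for very rare diseases.
#'
#' @param effect per-marker effect on the liability scale (vectorised).
#' @param K population prevalence.
#' @param P case sampling fraction; defaults to `K` (prospective).
#' @return The effect(s) on the observed 0/1 scale.
#' @export
liability_to_observed <- function(effect, K, P = K) {
  effect * liability_obs_factor(K, P)
}

#' Transform an observed-scale R-squared to the liability scale
#'
#' The coefficient of determination of a polygenic score on a 0/1 trait
#' depends on the prevalence and the case sampling fraction.  Re-expressing
#' it on the latent liability removes both dependencies: genetic effects are
#' rescaled by the inverse of the liability-to-observed transform and the
#' binomial trait variance is replaced by the unit liability variance.
#'
#' @param r2_obs coefficient of determination on the observed scale.
#' @param K population prevalence of the tested trait.
#' @param P case sampling fraction in the replication sample.
#' @return R-squared on the liability scale.  A warning is issued if the
#'   approximation exceeds 1 (the value is returned unclipped).
#' @export
liability_r2 <- function(r2_obs, K, P = K) {
  stopifnot(is.numeric(r2_obs), r2_obs >= 0)
  C <- liability_obs_factor(K, P)
  out <- r2_obs * P * (1 - P) / C^2
  if (any(out > 1))
    warning("liability-scale R^2 exceeds 1; the linear liability transform ",
            "is outside its small-effect regime")
  out
}

# Inverse transform, used to verify the observed <-> liability round trip.
observed_r2 <- function(r2_liab, K, P = K) {
  C <- liability_obs_factor(K, P)
  r2_liab * C^2 / (P * (1 - P))
}

# AUC from the proportion of liability variance explained by a
# normally distributed predictor: the probability that a random case's score
# exceeds a random control's, with conditional case/control moments from
# truncated-normal theory.
auc_from_liability_r2 <- function(rho2, K) {
  stopifnot(rho2 >= 0, rho2 <= 1)
  if (rho2 == 0) return(0.5)
  lt <- liability_threshold(K)
  i_case <- lt$z / K
  i_ctrl <- lt$z / (1 - K)
  num <- sqrt(rho2) * (i_case + i_ctrl)
  den <- sqrt(2 - rho2 * (i_case * (i_case - lt$T) + i_ctrl * (i_ctrl + lt$T)))
  stats::pnorm(num / den)
}

#' Expected AUC of a polygenic score
#'
#' Probability that a randomly chosen case has a higher score than a randomly
#' chosen control, for a binary trait 2.  The score is asymptotically normal,
#' so the AUC follows from its case/control conditional means and variances
#' on the liability scale, which are functions of the proportion of liability
#' variance explained by the estimated score.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()] whose `trait2` is binary.
#' @return The expected AUC, in `[0.5, 1]` for non-negative score-trait
#'   covariance.
#' @examples
#' bc <- binary_trait(K = 0.036, P = 0.5)
#' pgs_auc(polygenic_model(m = 161702, vg1 = 0.44),
#'         study_design(n1 = 2058, n2 = 229, trait1 = bc, trait2 = bc))
#' @export
pgs_auc <- function(model, design) {
  if (design$trait2$kind != "binary")
    stop("AUC requires a binary trait 2")
  mo <- score_moments(model, design)
  rho2 <- if (mo$varS > 0) mo$covS_liab^2 / mo$varS else 0
  auc_from_liability_r2(rho2, design$trait2$K)
}

#' Heritability of liability implied by the sibling recurrence risk
#'
#' Inverts the liability threshold model: siblings share half the additive
#' genetic liability, so their liabilities are bivariate normal with
#' correlation `h2 / 2`, and the probability that both members of a sibling
#' pair are affected is `lambda_s * K^2`.  The implied narrow-sense
#' heritability of liability is found by solving the bivariate normal tail
#' probability exactly (numerical quadrature).  This classical conversion
#' ignores shared environment and non-additive variance, so it should be read
#' as an upper bound on the additive heritability.
#'
#' @param K population prevalence.
#' @param lambda_s sibling relative recurrence risk, at least 1.
#' @return Heritability of liability, in `[0, 1]`.
#' @examples
#' h2_from_sibling_rr(K = 0.036, lambda_s = 2.5)  # about 0.44
#' @export
h2_from_sibling_rr <- function(K, lambda_s) {
  stopifnot(is.numeric(K), K > 0, K < 1, is.numeric(lambda_s), lambda_s >= 1)
  if (lambda_s * K >= 1)
    stop("lambda_s * K must be below 1 (sibling recurrence risk is a probability)")
  if (lambda_s == 1) return(0)
  T <- stats::qnorm(1 - K)
  both_affected <- function(rho) {
    if (rho == 0) return(K^2)
    stats::integrate(function(x)
      stats::dnorm(x) * stats::pnorm((rho * x - T) / sqrt(1 - rho^2)),
      T, Inf, rel.tol = 1e-11, abs.tol = 0)$value
  }
  f <- function(h2) both_affected(h2 / 2) - lambda_s * K^2
  if (f(1) < 0)
    stop("sibling recurrence risk ", lambda_s, " exceeds what heritability 1 ",
         "can produce at prevalence ", K)
  stats::uniroot(f, c(0, 1), tol = 1e-10)$root
}

#' AUC under the log-risk model
#'
#' For rare diseases an alternative to the liability threshold model takes
#' the polygenic score to estimate the log risk of disease, normally
#' distributed in the population.  The mean log risk among cases exceeds the
#' population mean by the log-risk variance, while the variance is the same
#' in cases and controls, giving `AUC = pnorm(sqrt(v / 2))` for a score with
#' log-risk-scale variance `v`.
#'
#' @param score_variance variance of the polygenic score on the log-risk
#'   scale.
#' @return The expected AUC.
#' @seealso [logrisk_variance()] to obtain the total log-risk variance from a
#'   sibling recurrence risk.
#' @export
logrisk_auc <- function(score_variance) {
  stopifnot(is.numeric(score_variance), score_variance >= 0)
  stats::pnorm(sqrt(score_variance / 2))
}

#' @rdname logrisk_auc
#' @param lambda_s sibling relative recurrence risk.  Under the log-risk
#'   model with normally distributed log risk, `lambda_s = exp(v / 2)` where
#'   `v` is the total log-risk variance, so `v = 2 * log(lambda_s)`.
#' @export
logrisk_variance <- function(lambda_s) {
  stopifnot(is.numeric(lambda_s), lambda_s >= 1)
  2 * log(lambda_s)
}
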