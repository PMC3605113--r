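#' Selection bounds on the estimated coefficient
#'
#' Markers enter the polygenic score when their two-sided training P-value
#' lies in the window `(q0, q1]`.  Asymptotically the Wald statistic converts
#' this into bounds on the absolute value of the estimated coefficient:
#' `|b| >= c0` corresponds to `P <= q1` and `|b| <= c1` to `P > q0`, where the
#' null standard error of the estimate sets the scale.
#'
#' @param q0,q1 P-value window bounds, `q0 < q1`.
#' @param n1 training sample size.
#' @param marginal_sd standard error of the estimate under the null;
#'   defaults to `sqrt(1 / n1)`, the value for a standardised trait and
#'   genotype.
#' @return Numeric vector `c(c0, c1)`; `c0 = 0` when `q1 = 1` and `c1 = Inf`
#'   when `q0 = 0`.
#' @examples
#' selection_bounds(0, 0.05, n1 = 10000)  # c0 = 1.96 / 100
#' @export
selection_bounds <- function(q0, q1, n1, marginal_sd = sqrt(1 / n1)) {
  stopifnot(is.numeric(q0), is.numeric(q1), length(q0) == 1, length(q1) == 1,
            q0 >= 0, q1 <= 1, is.numeric(n1), length(n1) == 1, n1 > 0,
            is.numeric(marginal_sd), marginal_sd >= 0)
  if (q0 >= q1) stop("selection window requires q0 < q1")
  c0 <- if (q1 >= 1) 0 else stats::qnorm(1 - q1 / 2) * marginal_sd
  c1 <- if (q0 <= 0) Inf else stats::qnorm(1 - q0 / 2) * marginal_sd
  c(c0 = c0, c1 = c1)
}

#' Second moment of a two-sided truncated standard normal
#'
#' Returns `E[Z^2 | a <= |Z| <= b]` for standard normal `Z`, the kernel of
#' the conditional variance of an effect estimate given selection into the
#' score.  Tail truncation (`a > 0`, `b = Inf`) inflates the second moment
#' above 1 (winner's curse); window truncation deflates it.
#'
#' @param a,b truncation bounds, `0 <= a < b` (`b` may be `Inf`).
#' @return The conditional second moment, a non-negative number.
#' @examples
#' truncated_second_moment(0, Inf)  # 1, no truncation
#' @export
truncated_second_moment <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1,
            a >= 0)
  if (a >= b) stop("truncation bounds require a < b")
  if (a == 0 && is.infinite(b)) return(1)
  den <- stats::pnorm(b) - stats::pnorm(a)
  if (den <= 0) {
    # deep in the tail: asymptotic E[Z^2 | Z > a] ~ a^2 + 2
    return(a^2 + 2)
  }
  bphib <- if (is.infinite(b)) 0 else b * stats::dnorm(b)
  1 + (a * stats::dnorm(a) - bphib) / den
}

# Per-trait analysis-scale constants: the factor taking a liability/trait
# scale effect to the scale the regression is run on, and the trait variance
# on that scale.
trait_scale <- function(trait) {
  if (trait$kind == "binary") {
    list(C = liability_obs_factor(trait$K, trait$P),
         varY = trait$P * (1 - trait$P))
  } else {
    list(C = 1, varY = 1)
  }
}

#' First two moments of the estimated polygenic score
#'
#' Computes the variance of the polygenic score per replication subject and
#' its covariance with the tested trait, on the analysis scale of trait 2.
#' These two moments determine every downstream accuracy and power metric.
#' The training estimates are taken as normal around the true effects with
#' sampling variance `varY1 / n1` (conservatively ignoring the variance
#' explained by the marker itself); binary-trait effects are mapped from the
#' liability scale to the observed 0/1 scale, with the case/control
#' adjustment when the sample is ascertained.
#'
#' For the `"linear"` estimator the score variance mixes a null component
#' (selection probability `q1 - q0`, truncated variance of a pure-noise
#' estimate) and a non-null component (selection probability and truncated
#' variance under the marginal effect-plus-noise distribution).  The
#' `"shrinkage"` estimator multiplies all coefficients by the common
#' posterior factor, leaving correlation-based metrics unchanged.  The
#' `"allele_count"` estimator gives every selected marker the same magnitude
#' with the sign of its estimate; its covariance with the trait is a
#' one-dimensional integral over the effect distribution, evaluated by
#' adaptive quadrature.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()].
#' @return An object of class `"score_moments"`: a list with elements
#'   `varS`, `covSy` (analysis scale of trait 2), `covS_liab` (covariance
#'   with trait 2 on its liability/trait scale, used for the AUC and
#'   liability R-squared), `varY2`, the shrinkage factor `shrink`, and the
#'   expected number of selected markers `n_selected`.
#' @export
score_moments <- function(model, design) {
  stopifnot(inherits(model, "polygenic_model"), inherits(design, "study_design"))
  s1 <- trait_scale(design$trait1)
  s2 <- trait_scale(design$trait2)
  m <- model$m; pi0 <- model$pi0
  # per-marker non-null variances on the trait (liability) scale
  sig1l2 <- model$vg1 / (m * (1 - pi0))
  sig2l2 <- model$vg2 / (m * (1 - pi0))
  sig12l <- model$rho12 * sqrt(sig1l2 * sig2l2)
  sig1o2 <- s1$C^2 * sig1l2              # observed (analysis) scale, trait 1
  v1 <- s1$varY / design$n1              # sampling variance of the estimate
  shrink <- if (is.infinite(design$n1)) 1 else sig1o2 / (sig1o2 + v1)

  if (is.infinite(design$n1)) {
    # analytic limit: estimates equal true effects; non-null markers have
    # P-value 0 and are selected iff q0 = 0, null markers contribute nothing
    sel <- as.numeric(design$q0 == 0)
    out <- list(varS = m * (1 - pi0) * sig1o2 * sel,
                covSy = m * (1 - pi0) * s1$C * s2$C * sig12l * sel,
                covS_liab = m * (1 - pi0) * s1$C * sig12l * sel,
                varY2 = s2$varY, shrink = 1,
                n_selected = m * (1 - pi0) * sel + m * pi0 * (design$q1 - design$q0))
    if (design$estimator == "allele_count") {
      # fixed magnitude c with sign(beta); E|beta| = sd * sqrt(2/pi)
      cmag <- s1$C * sqrt(model$vg1 / m)
      nsel <- m * (1 - pi0) * sel
      kap <- if (sig1l2 > 0) sig12l / (s1$C * sig1l2) else 0
      eabs <- sqrt(sig1o2) * sqrt(2 / pi)
      out$varS <- cmag^2 * nsel
      out$covS_liab <- nsel * cmag * kap * eabs * sel
      out$covSy <- out$covS_liab * s2$C
    }
    class(out) <- "score_moments"
    return(out)
  }

  bounds <- selection_bounds(design$q0, design$q1, design$n1, sqrt(v1))
  zq1 <- bounds["c0"] / sqrt(v1)         # null-scale truncation points
  zq0 <- bounds["c1"] / sqrt(v1)
  p_null <- design$q1 - design$q0        # exact: P-values are uniform
  t_null <- truncated_second_moment(zq1, zq0)
  sd1 <- sqrt(sig1o2 + v1)               # marginal sd of a non-null estimate
  a <- bounds["c0"] / sd1
  b <- bounds["c1"] / sd1
  p_sel <- 2 * (stats::pnorm(b) - stats::pnorm(a))
  t_sel <- truncated_second_moment(a, b)

  varS <- m * pi0 * p_null * v1 * t_null +
    m * (1 - pi0) * p_sel * (sig1o2 + v1) * t_sel
  # regression coefficient of the trait-2 effect on the estimate is
  # unaffected by selection on the estimate
  covS_liab <- m * (1 - pi0) * p_sel * s1$C * sig12l * t_sel
  covSy <- covS_liab * s2$C
  n_selected <- m * pi0 * p_null + m * (1 - pi0) * p_sel

  if (design$estimator == "shrinkage") {
    varS <- shrink^2 * varS
    covSy <- shrink * covSy
    covS_liab <- shrink * covS_liab
  } else if (design$estimator == "allele_count") {
    cmag <- s1$C * sqrt(model$vg1 / m)   # same proportion of variance per marker
    varS <- cmag^2 * n_selected
    if (model$rho12 == 0 || sig1l2 == 0) {
      covS_liab <- 0
    } else {
      I <- allele_count_integral(sqrt(sig1o2), sqrt(v1), bounds["c0"], bounds["c1"])
      kap <- sig12l / (s1$C * sig1l2)    # regression of liability effect on obs effect
      covS_liab <- m * (1 - pi0) * cmag * kap * I
    }
    covSy <- covS_liab * s2$C
  }

  structure(list(varS = unname(varS), covSy = unname(covSy),
                 covS_liab = unname(covS_liab), varY2 = s2$varY,
                 shrink = unname(shrink), n_selected = unname(n_selected)),
            class = "score_moments")
}

# E[ sign(bhat) * beta ; selected ] for a non-null marker, where
# beta ~ N(0, sig^2) on the observed scale and bhat | beta ~ N(beta, se^2),
# selection meaning c0 <= |bhat| <= c1.  Standardised so the integrand is O(1):
# I = sig * int t phi(t) [P(+,sel | sig t) - P(-,sel | sig t)] dt.
allele_count_integral <- function(sig, se, c0, c1, tol = 1e-8) {
  f <- function(t) {
    x <- sig * t
    up <- if (is.infinite(c1)) 1 else stats::pnorm((c1 - x) / se)
    pp <- up - stats::pnorm((c0 - x) / se)
    um <- stats::pnorm((-c0 - x) / se)
    pm <- um - if (is.infinite(c1)) 0 else stats::pnorm((-c1 - x) / se)
    t * stats::dnorm(t) * (pp - pm)
  }
  # integrand is even in t; integrate over |t| <= 8 (mass beyond < 1e-15)
  q <- stats::integrate(f, 0, 8, rel.tol = tol, abs.tol = tol,
                        stop.on.error = FALSE)
  if (q$message != "OK" && q$abs.error > tol * max(1, abs(q$value)))
    stop("allele-count covariance quadrature did not converge: ",
         q$message, " (achieved tolerance ", signif(q$abs.error, 3), ")")
  2 * sig * q$value
}

#' @export
print.score_moments <- function(x, ...) {
  cat("Polygenic score moments (analysis scale of trait 2)\n")
  cat(sprintf("  Var(S)            = %.6g\n", x$varS))
  cat(sprintf("  Cov(S, y2)        = %.6g\n", x$covSy))
  cat(sprintf("  Cov(S, liability) = %.6g\n", x$covS_liab))
  cat(sprintf("  Var(y2)           = %.6g\n", x$varY2))
  cat(sprintf("  expected markers selected = %.4g\n", x$n_selected))
  invisible(x)
}
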