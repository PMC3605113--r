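#' Estimate an architecture parameter from an observed score association
#'
#' Inverts the non-centrality parameter of the score association test: the
#' observed 1-df chi-squared statistic for the regression of trait 2 on the
#' polygenic score has a signed root that is approximately normal with mean
#' `sqrt(ncp(theta))` and unit variance, where `theta` is the free parameter
#' of the polygenic model.  The point estimate solves
#' `sqrt(ncp(theta)) = sqrt(S)`, and the 95% confidence bounds solve
#' `sqrt(ncp(theta)) = sqrt(S) -/+ z_{0.975}`.  The NCP must be monotone in
#' the free parameter over its domain, which is checked numerically.
#'
#' The free parameter may be the explained variance shared by both samples
#' (`"vg"`, which sets `vg1 = vg2 = theta`), either sample's explained
#' variance (`"vg1"`, `"vg2"`), the effect correlation (`"rho12"`, searched
#' on `[0, 1]`; the chi-squared statistic carries no sign), or the null
#' proportion (`"pi0"`).
#'
#' @param model a [polygenic_model()] supplying the fixed parameters; the
#'   free parameter's value in `model` is ignored.
#' @param design a [study_design()].
#' @param param which parameter to estimate.
#' @param chisq observed 1-df chi-squared association statistic.  Exactly one
#'   of `chisq`, `p`, `neglog10p` must be given.
#' @param p observed two-sided P-value, converted through the 1-df
#'   chi-squared quantile.
#' @param neglog10p `-log10` of the observed P-value, for P-values below
#'   representable precision.
#' @param conf confidence level for the interval.
#' @return An object of class `"pgs_estimate"`: a list with `param`,
#'   `estimate`, `ci` (length-2 vector), `observed_chisq`, and `boundary`
#'   flags indicating bounds clamped to the parameter domain.
#' @examples
#' sz1 <- binary_trait(K = 0.01, P = 3322 / 6909)
#' sz2 <- binary_trait(K = 0.01, P = 2687 / 5343)
#' estimate_parameter(polygenic_model(m = 74062, vg1 = NA, pi0 = 0),
#'                    study_design(6909, 5343, sz1, sz2, q1 = 0.5),
#'                    param = "vg", p = 2e-28)
#' @export
estimate_parameter <- function(model, design,
                               param = c("vg", "vg1", "vg2", "rho12", "pi0"),
                               chisq = NULL, p = NULL, neglog10p = NULL,
                               conf = 0.95) {
  param <- match.arg(param)
  ngiven <- sum(!is.null(chisq), !is.null(p), !is.null(neglog10p))
  if (ngiven != 1)
    stop("supply exactly one of `chisq`, `p`, `neglog10p`")
  if (!is.null(neglog10p)) p <- 10^(-neglog10p)
  if (!is.null(p)) {
    stopifnot(p > 0, p < 1)
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  stopifnot(is.numeric(chisq), length(chisq) == 1, chisq >= 0)

  dom <- switch(param,
                vg = , vg1 = , vg2 = c(0, 1),
                rho12 = c(0, 1),
                pi0 = c(0, 1 - 1e-9))
  ncp_at <- function(theta) {
    mod <- model
    if (param == "vg") {
      mod$vg1 <- theta; mod$vg2 <- theta
    } else mod[[param]] <- theta
    mo <- score_moments(mod, design)
    r2 <- score_r2(mo)
    design$n2 * r2 / (1 - r2)
  }
  # monotonicity check over the domain
  eps <- 1e-9
  grid <- seq(dom[1] + eps, dom[2] - eps, length.out = 21)
  vals <- vapply(grid, ncp_at, numeric(1))
  d <- diff(vals)
  if (all(d >= -1e-12)) {
    increasing <- TRUE
  } else if (all(d <= 1e-12)) {
    increasing <- FALSE
  } else {
    stop("NCP is not monotone in `", param, "` over [", dom[1], ", ", dom[2],
         "]; cannot invert the estimating equation")
  }
  lo_val <- if (increasing) vals[1] else vals[length(vals)]
  hi_val <- if (increasing) vals[length(vals)] else vals[1]

  zc <- stats::qnorm(1 - (1 - conf) / 2)
  solve_root <- function(target_sqrt) {
    # solves sqrt(ncp(theta)) = target_sqrt; returns list(value, boundary)
    if (target_sqrt <= sqrt(max(lo_val, 0))) {
      return(list(value = if (increasing) dom[1] else dom[2], boundary = TRUE))
    }
    if (target_sqrt >= sqrt(hi_val)) {
      return(list(value = if (increasing) dom[2] else dom[1], boundary = TRUE))
    }
    f <- function(theta) sqrt(ncp_at(theta)) - target_sqrt
    r <- stats::uniroot(f, c(dom[1] + eps, dom[2] - eps), tol = 1e-10,
                        extendInt = "no")
    list(value = r$root, boundary = FALSE)
  }

  est <- solve_root(sqrt(chisq))
  lo <- solve_root(sqrt(chisq) - zc)
  hi <- solve_root(sqrt(chisq) + zc)
  ci <- sort(c(lo$value, hi$value))
  structure(list(param = param, estimate = est$value, ci = ci,
                 observed_chisq = chisq, conf = conf,
                 boundary = c(estimate = est$boundary,
                              ci = lo$boundary || hi$boundary)),
            class = "pgs_estimate")
}

#' @export
print.pgs_estimate <- function(x, ...) {
  cat(sprintf("Estimated %s = %.4g (%g%% CI: %.4g - %.4g)\n", x$param,
              x$estimate, 100 * x$conf, x$ci[1], x$ci[2]))
  cat(sprintf("  from observed chi-squared %.4g (P = %.3g)\n",
              x$observed_chisq,
              stats::pchisq(x$observed_chisq, 1, lower.tail = FALSE)))
  if (any(x$boundary))
    cat("  note: estimate and/or bound clamped to the parameter domain\n")
  invisible(x)
}
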