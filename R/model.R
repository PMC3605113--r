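#' Specify a polygenic architecture
#'
#' Describes the joint distribution of per-marker effects on two traits for a
#' panel of `m` independent, standardised markers.  Effects are exchangeable
#' across markers: a proportion `pi0` of markers has no effect on either
#' trait, and the remaining markers have effects drawn from a bivariate normal
#' distribution whose per-marker variances are `vg1 / (m * (1 - pi0))` and
#' `vg2 / (m * (1 - pi0))` with cross-trait correlation `rho12`.  Under this
#' parameterisation the total variance explained by the panel is `vg1`
#' (resp. `vg2`) regardless of `pi0`.
#'
#' For binary traits the effects act on the liability scale; `vg1` and `vg2`
#' are then explained variances in liability, bounded above by the
#' heritability of liability.
#'
#' @param m number of independent markers in the panel.  Linkage
#'   disequilibrium is not modelled: `m` should be an *effective* number of
#'   independent markers.
#' @param vg1 total variance of trait 1 explained by the panel, in `[0, 1]`.
#' @param vg2 total variance of trait 2 explained by the panel; defaults to
#'   `vg1` (same trait in both samples).
#' @param rho12 correlation between per-marker effects on the two traits, in
#'   `[-1, 1]`.  Use 1 when the same trait is analysed in both samples.
#' @param pi0 proportion of markers with no effect on either trait, in
#'   `[0, 1)`.
#'
#' @return An object of class `"polygenic_model"`.
#' @examples
#' polygenic_model(m = 74062, vg1 = 0.287, pi0 = 0)
#' @export
polygenic_model <- function(m, vg1, vg2 = vg1, rho12 = 1, pi0 = 0) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1,
            is.numeric(vg1), length(vg1) == 1, vg1 >= 0, vg1 <= 1,
            is.numeric(vg2), length(vg2) == 1, vg2 >= 0, vg2 <= 1,
            is.numeric(rho12), length(rho12) == 1, abs(rho12) <= 1,
            is.numeric(pi0), length(pi0) == 1, pi0 >= 0, pi0 < 1)
  structure(list(m = m, vg1 = vg1, vg2 = vg2, rho12 = rho12, pi0 = pi0),
            class = "polygenic_model")
}

#' @export
print.polygenic_model <- function(x, ...) {
  cat("Polygenic architecture\n")
  cat(sprintf("  markers (effective):       %g\n", x$m))
  cat(sprintf("  explained variance, trait 1: %.4g\n", x$vg1))
  cat(sprintf("  explained variance, trait 2: %.4g\n", x$vg2))
  cat(sprintf("  effect correlation:          %.4g\n", x$rho12))
  cat(sprintf("  proportion of null markers:  %.4g\n", x$pi0))
  invisible(x)
}

#' Trait specifications
#'
#' `quantitative_trait()` declares a standardised, normally distributed trait.
#' `binary_trait()` declares a 0/1 disease trait arising from a liability
#' threshold model with population prevalence `K`; `P` is the proportion of
#' cases among sampled subjects.  When `P` differs from `K` the sample is
#' treated as case/control ascertained, and effect sizes on the 0/1 scale are
#' transformed accordingly.
#'
#' @param K population prevalence of the trait, in (0, 1).
#' @param P proportion of cases among sampled subjects, in (0, 1).  Defaults
#'   to `K` (prospective sampling).
#'
#' @return An object of class `"trait_spec"`.
#' @examples
#' binary_trait(K = 0.01, P = 0.5)  # case/control study of a 1% disease
#' @export
quantitative_trait <- function() {
  structure(list(kind = "quantitative", K = NA_real_, P = NA_real_,
                 ascertained = FALSE), class = "trait_spec")
}

#' @rdname quantitative_trait
#' @export
binary_trait <- function(K, P = K) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0, K < 1,
            is.numeric(P), length(P) == 1, P > 0, P < 1)
  structure(list(kind = "binary", K = K, P = P, ascertained = (P != K)),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  if (x$kind == "quantitative") {
    cat("Quantitative trait (standardised)\n")
  } else {
    cat(sprintf("Binary trait: prevalence %g, case fraction %g (%s)\n",
                x$K, x$P, if (x$ascertained) "case/control" else "prospective"))
  }
  invisible(x)
}

#' Specify a two-sample study design
#'
#' A polygenic score analysis uses a training sample of `n1` subjects to
#' estimate per-marker effects on trait 1, selects markers whose two-sided
#' training P-values lie in the window `(q0, q1]`, and tests the resulting
#' score against trait 2 in an independent replication sample of `n2`
#' subjects.
#'
#' @param n1 training sample size (subjects).  May be `Inf` for the
#'   infinite-training-sample limit.
#' @param n2 replication sample size (subjects).
#' @param trait1,trait2 trait specifications from [quantitative_trait()] or
#'   [binary_trait()].  `trait2` defaults to `trait1`.
#' @param q0,q1 lower and upper bounds of the P-value selection window;
#'   markers enter the score iff their two-sided training P-value lies in
#'   `(q0, q1]`.  Defaults include the whole panel.
#' @param estimator how marker effects are weighted in the score: `"linear"`
#'   (least-squares estimates), `"shrinkage"` (estimates multiplied by the
#'   common posterior shrinkage factor), or `"allele_count"` (fixed magnitude
#'   with the sign of the estimate, the unweighted score).
#' @param alpha two-tailed significance level for the association test of the
#'   score.
#'
#' @return An object of class `"study_design"`.
#' @examples
#' sz <- binary_trait(K = 0.01, P = 3322 / 6909)
#' study_design(n1 = 6909, n2 = 5343, trait1 = sz,
#'              trait2 = binary_trait(K = 0.01, P = 2687 / 5343), q1 = 0.5)
#' @export
study_design <- function(n1, n2, trait1 = quantitative_trait(), trait2 = trait1,
                         q0 = 0, q1 = 1,
                         estimator = c("linear", "shrinkage", "allele_count"),
                         alpha = 0.05) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(n1), length(n1) == 1, n1 >= 1,
            is.numeric(n2), length(n2) == 1, n2 >= 1, is.finite(n2),
            inherits(trait1, "trait_spec"), inherits(trait2, "trait_spec"),
            is.numeric(q0), length(q0) == 1, q0 >= 0, q0 < 1,
            is.numeric(q1), length(q1) == 1, q1 > 0, q1 <= 1,
            is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  if (q0 >= q1)
    stop("selection window requires q0 < q1 (got q0 = ", q0, ", q1 = ", q1, ")")
  structure(list(n1 = n1, n2 = n2, trait1 = trait1, trait2 = trait2,
                 q0 = q0, q1 = q1, estimator = estimator, alpha = alpha),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Two-sample polygenic score design\n")
  cat(sprintf("  training n1 = %g, replication n2 = %g\n", x$n1, x$n2))
  cat("  trait 1: "); print(x$trait1)
  cat("  trait 2: "); print(x$trait2)
  cat(sprintf("  selection window: P-value in (%g, %g]\n", x$q0, x$q1))
  cat(sprintf("  estimator: %s, alpha = %g\n", x$estimator, x$alpha))
  invisible(x)
}
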