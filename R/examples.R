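#' Recompute headline worked examples from published polygenic score studies
#'
#' Reconstructs, from their published design parameters and association
#' statistics, the quantities reported for several landmark two-sample
#' polygenic score analyses: the schizophrenia training/replication study of
#' the International Schizophrenia Consortium (ISC; 74,062 nearly independent
#' SNPs, score association P = 2e-28 at inclusion threshold 0.5), its
#' cross-trait test against WTCCC bipolar disorder (P = 1e-12), the
#' multiple-sclerosis all-SNP score (59,470 SNPs, P = 6e-21), the split-sample
#' breast and prostate cancer analyses of Machiela et al., and the Framingham
#' Risk Score cross-validation analysis.  Each row is recomputed from scratch
#' by the package's analytic machinery.
#'
#' @return A data frame with columns `example`, `value`, and `units`.
#'   Percentages are on the 0-100 scale.
#' @examples
#' \donttest{published_examples()}
#' @export
published_examples <- function() {
  z <- list()

  ## --- ISC schizophrenia: association testing ---
  isc_des <- study_design(n1 = 6909, n2 = 5343,
                          trait1 = binary_trait(0.01, 3322 / 6909),
                          trait2 = binary_trait(0.01, 2687 / 5343),
                          q1 = 0.5)
  isc_mod <- function(vg, pi0 = 0) polygenic_model(74062, vg, pi0 = pi0)
  # explained variance in liability giving 80% power at alpha = 0.05
  vg80 <- stats::uniroot(function(vg)
    accuracy_report(isc_mod(vg), isc_des)$power - 0.8,
    c(0.01, 0.5), tol = 1e-10)$root
  z$isc_vg_for_power80 <- c(100 * vg80, "% liability variance")
  # inversion of the observed association statistic
  est <- estimate_parameter(isc_mod(0.5), isc_des, "vg", p = 2e-28)
  z$isc_vg_estimate <- c(100 * est$estimate, "% liability variance")
  z$isc_vg_ci_lower <- c(100 * est$ci[1], "% liability variance")
  z$isc_vg_ci_upper <- c(100 * est$ci[2], "% liability variance")
  est99 <- estimate_parameter(isc_mod(0.5, pi0 = 0.99), isc_des, "vg", p = 2e-28)
  z$isc_vg_estimate_99null <- c(100 * est99$estimate, "% liability variance")
  # sufficient cases and controls per sample at the estimated architecture
  tr <- binary_trait(0.01, 0.5)
  req <- required_n(polygenic_model(74062, 0.287),
                    study_design(2, 2, tr, tr), "power", 0.8)
  z$isc_sufficient_n <- c(req$n, "cases (and controls) per sample")

  ## --- schizophrenia -> bipolar cross-trait correlation ---
  bd_des <- study_design(n1 = 6909, n2 = 4764,
                         trait1 = binary_trait(0.01, 3322 / 6909),
                         trait2 = binary_trait(0.01, 1829 / 4764),
                         q1 = 0.5)
  bd_mod <- polygenic_model(74062, 0.287, 0.287, rho12 = 0.5)
  estr <- estimate_parameter(bd_mod, bd_des, "rho12", p = 1e-12)
  z$bd_rho_estimate <- c(100 * estr$estimate, "% effect correlation")

  ## --- multiple sclerosis all-SNP score ---
  ms_des <- study_design(n1 = 3362, n2 = 2953,
                         trait1 = binary_trait(0.001, 931 / 3362),
                         trait2 = binary_trait(0.001, 876 / 2953))
  estm <- estimate_parameter(polygenic_model(59470, 0.5), ms_des, "vg", p = 6e-21)
  z$ms_vg_estimate <- c(100 * estm$estimate, "% liability variance")

  ## --- Machiela split-sample cancers ---
  h2_brca <- h2_from_sibling_rr(0.036, 2.5)
  h2_prca <- h2_from_sibling_rr(0.024, 2.8)
  brca_tr <- binary_trait(0.036, 0.5)
  brca_des <- study_design(0.9 * 2287, 0.1 * 2287, brca_tr, brca_tr)
  z$brca_power <- c(100 * accuracy_report(polygenic_model(161702, h2_brca),
                                          brca_des)$power, "% power")
  prca_tr <- binary_trait(0.024, 0.5)
  prca_des <- study_design(0.9 * 2277, 0.1 * 2277, prca_tr, prca_tr)
  z$prca_power <- c(100 * accuracy_report(polygenic_model(165508, h2_prca),
                                          prca_des)$power, "% power")
  z$brca_auc <- c(100 * pgs_auc(polygenic_model(161702, h2_brca), brca_des),
                  "% AUC")
  prca_inf <- prca_des; prca_inf$n1 <- Inf
  z$prca_auc_infinite <- c(100 * pgs_auc(polygenic_model(165508, h2_prca),
                                         prca_inf), "% AUC")

  ## --- Framingham Risk Score stratum 0.4 < P < 0.5 ---
  fr_des <- study_design(1575, 175, q0 = 0.4, q1 = 0.5)
  z$framingham_power <- c(100 * accuracy_report(polygenic_model(1e5, 1),
                                                fr_des)$power, "% power")

  ## --- fully tagged quantitative trait: training size for 90% of the
  ## --- maximum correlation, threshold optimised, 1000s of subjects
  reqc <- required_n(polygenic_model(1e6, 0.8, pi0 = 0.999),
                     study_design(2, 2), "correlation",
                     target = 0.9 * sqrt(0.8), optimize_threshold = TRUE,
                     rounding = 1000)
  z$quant_required_n <- c(reqc$n, "subjects")

  data.frame(example = names(z),
             value = as.numeric(vapply(z, `[`, character(1), 1)),
             units = vapply(z, `[`, character(1), 2),
             row.names = NULL)
}
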