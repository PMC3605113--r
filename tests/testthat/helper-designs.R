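# Shared fixtures: published study designs used across tests.

# International Schizophrenia Consortium: training 3322 cases / 3587
# controls, replication (MGS) 2687 / 2656; 74,062 nearly independent SNPs,
# prevalence 1%, score built from SNPs with training P <= 0.5.
isc_design <- function(q1 = 0.5, estimator = "linear") {
  study_design(n1 = 6909, n2 = 5343,
               trait1 = binary_trait(K = 0.01, P = 3322 / 6909),
               trait2 = binary_trait(K = 0.01, P = 2687 / 5343),
               q1 = q1, estimator = estimator)
}
isc_model <- function(vg = 0.287, pi0 = 0) polygenic_model(74062, vg, pi0 = pi0)

# Machiela et al. breast-cancer design: 2287 subjects, half cases, 9:1
# training:testing split, 161,702 markers, prevalence 3.6%.
brca_design <- function(split = 0.9) {
  tr <- binary_trait(K = 0.036, P = 0.5)
  study_design(n1 = split * 2287, n2 = (1 - split) * 2287,
               trait1 = tr, trait2 = tr)
}

# baseline simulation architecture (scaled down): explained variances
# 0.4 / 0.3, effect correlation 0.65
baseline_model <- function(m = 2000, pi0 = 0.95)
  polygenic_model(m, vg1 = 0.4, vg2 = 0.3, rho12 = 0.65, pi0 = pi0)

expect_within_se <- function(emp, se, analytic, k = 3) {
  expect_lt(abs(emp - analytic), k * se + 1e-12)
}
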