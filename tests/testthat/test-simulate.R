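test_that("simulated effects realise the configured architecture", {
  set.seed(1)
  mod <- polygenic_model(1e5, 0.4, 0.3, 0.65, pi0 = 0.99)
  cfg <- sim_config(mod, study_design(100, 100), seed = 1)
  B <- simulate_effects(cfg)
  expect_equal(sum(B[, 1] != 0), 1000)  # exactly (1 - pi0) * m non-null
  expect_equal(sum(B[, 2] != 0), 1000)
  # realised totals near their targets (relative SE ~ sqrt(2/1000))
  expect_lt(abs(sum(B[, 1]^2) - 0.4) / 0.4, 3 * sqrt(2 / 1000))
  expect_lt(abs(sum(B[, 2]^2) - 0.3) / 0.3, 3 * sqrt(2 / 1000))
  nn <- B[, 1] != 0
  expect_lt(abs(cor(B[nn, 1], B[nn, 2]) - 0.65), 0.08)
})

test_that("Laplace effects match variance, correlation, and kurtosis", {
  set.seed(2)
  mod <- polygenic_model(4e4, 0.4, 0.3, 0.65, pi0 = 0)
  cfg <- sim_config(mod, study_design(100, 100), seed = 2,
                    effect_dist = "laplace")
  B <- simulate_effects(cfg)
  expect_lt(abs(sum(B[, 1]^2) - 0.4) / 0.4, 0.05)
  expect_lt(abs(cor(B[, 1], B[, 2]) - 0.65), 0.02)
  z <- B[, 1] / sd(B[, 1])
  kurt <- mean(z^4) - 3
  expect_gt(kurt, 2)  # Laplace excess kurtosis is 3
  expect_lt(kurt, 4.5)
  # copula calibration is exact at the distribution level
  expect_equal(pgspower:::laplace_copula_corr(
    pgspower:::calibrate_laplace_copula(0.65)), 0.65, tolerance = 1e-7)
})

test_that("simulated genotypes are standardised and traits have unit variance", {
  set.seed(3)
  mod <- polygenic_model(300, 0.4, 0.3, 0.65, pi0 = 0.5)
  cfg <- sim_config(mod, study_design(3000, 500), seed = 3)
  st <- simulate_study(cfg)
  mu <- colMeans(st$s1$X)
  v <- apply(st$s1$X, 2, var)
  expect_lt(max(abs(mu)), 4 / sqrt(3000) * 1.6)
  expect_lt(abs(mean(v) - 1), 0.02)
  expect_lt(abs(var(st$s1$y) - 1), 0.1)
})

test_that("prospective binary sampling hits the prevalence", {
  set.seed(4)
  tr <- binary_trait(0.2)
  mod <- polygenic_model(200, 0.3)
  cfg <- sim_config(mod, study_design(5000, 100, tr, tr), seed = 4)
  st <- simulate_study(cfg)
  expect_within_se(mean(st$s1$y), sqrt(0.2 * 0.8 / 5000), 0.2)
})

test_that("conditional case/control scheme matches rejection sampling", {
  # at K = 0.2 both schemes are feasible; compare genotype moments in cases
  set.seed(5)
  m <- 300
  mod <- polygenic_model(m, 0.5, pi0 = 0)
  tr <- binary_trait(0.2, 0.5)
  maf <- runif(m, 0.01, 0.5)
  cfg <- sim_config(mod, study_design(4000, 100, tr, tr), seed = 5)
  B <- simulate_effects(cfg)
  cond <- pgspower:::simulate_sample(4000, maf, B[, 1], 0.5, tr)
  rej <- pgspower:::simulate_sample_rejection(4000, maf, B[, 1], 0.5, tr)
  # mean genotype among cases is proportional to the marker effect
  mc <- colMeans(cond$X[cond$y == 1, ])
  mr <- colMeans(rej$X[rej$y == 1, ])
  se <- 1 / sqrt(2000)
  expect_lt(mean(abs(mc - mr)) / se, 1.3)    # same signal, same noise level
  expect_gt(cor(mc, B[, 1]), 0.5)
  expect_gt(cor(mr, B[, 1]), 0.5)
  # realised aggregate genetic liabilities match in mean and spread too
  gc_ <- as.vector(cond$X %*% B[, 1]); gr <- as.vector(rej$X %*% B[, 1])
  for (cls in 0:1) {
    expect_lt(abs(mean(gc_[cond$y == cls]) - mean(gr[rej$y == cls])), 0.07)
    expect_lt(abs(sd(gc_[cond$y == cls]) - sd(gr[rej$y == cls])), 0.07)
  }
})

test_that("ascertained status regresses on genotype as the transform predicts", {
  # rare disease, heavily ascertained: slope of 0/1 status on a non-null
  # genotype should match liability_to_observed within Monte-Carlo error
  set.seed(6)
  m <- 40
  mod <- polygenic_model(m, 0.4, pi0 = 0)
  tr <- binary_trait(0.001, 0.5)
  maf <- runif(m, 0.1, 0.5)
  beta <- sqrt(rep(0.4 / m, m)) * sample(c(-1, 1), m, replace = TRUE)
  slopes <- replicate(60, {
    s <- pgspower:::simulate_sample(2000, maf, beta, 0.4, tr)
    as.vector(crossprod(s$X, s$y - mean(s$y)) / 2000)
  })
  emp <- rowMeans(slopes)
  se <- apply(slopes, 1, sd) / sqrt(60)
  pred <- liability_to_observed(beta, 0.001, 0.5)
  expect_lt(mean(abs(emp - pred) / se), 2)
  expect_true(all(abs(emp - pred) < 4.5 * se))
})

test_that("replicate evaluation agrees with analytic values at small scale", {
  mod <- baseline_model(m = 2000, pi0 = 0.95)
  des <- study_design(1000, 1000, q1 = 0.1)
  sr <- evaluate_replicates(sim_config(mod, des, replicates = 30, seed = 17))
  a <- sr$analytic; s <- sr$summary
  expect_within_se(s$ncp_emp, s$ncp_se, a$ncp)
  expect_within_se(s$r2_emp, s$r2_se, a$r2_obs)
  expect_within_se(s$mse_emp, s$mse_se, a$mse)
  expect_equal(nrow(sr$replicates), 30)
  expect_true(all(is.finite(c(s$ncp_se, s$r2_se, s$mse_se))))
})

test_that("simulation streams are reproducible and seed-dependent", {
  mod <- baseline_model(m = 500, pi0 = 0.9)
  des <- study_design(300, 300, q1 = 0.5)
  a <- evaluate_replicates(sim_config(mod, des, replicates = 3, seed = 5))
  b <- evaluate_replicates(sim_config(mod, des, replicates = 3, seed = 5))
  c <- evaluate_replicates(sim_config(mod, des, replicates = 3, seed = 6))
  expect_identical(a$replicates, b$replicates)
  expect_false(identical(a$replicates, c$replicates))
})

test_that("normality of effects only matters inside a selection window", {
  # full inclusion: variance-matched Laplace effects give the same moments
  mod <- polygenic_model(4000, 0.4, 0.3, 0.65, pi0 = 0)
  des <- study_design(1500, 1500)
  sr <- evaluate_replicates(sim_config(mod, des, replicates = 40, seed = 71,
                                       effect_dist = "laplace", est_param = NA))
  s <- sr$summary; a <- sr$analytic
  expect_within_se(s$ncp_emp, s$ncp_se, a$ncp)
  expect_within_se(s$r2_emp, s$r2_se, a$r2_obs)
  # stringent selection: heavier tails put more large effects in the score,
  # so the normal-theory values should not overestimate the simulation
  mod2 <- polygenic_model(4000, 0.4, 0.3, 0.65, pi0 = 0.95)
  des2 <- study_design(1500, 1500, q1 = 0.01)
  sr2 <- evaluate_replicates(sim_config(mod2, des2, replicates = 40, seed = 72,
                                        effect_dist = "laplace", est_param = NA))
  expect_gt(sr2$summary$ncp_emp - sr2$analytic$ncp,
            -2 * sr2$summary$ncp_se)
})

test_that("logistic and linear marker scans agree for binary traits", {
  set.seed(9)
  mod <- polygenic_model(150, 0.4, pi0 = 0)
  tr <- binary_trait(0.3)
  des <- study_design(800, 600, tr, tr, q1 = 0.5)
  cfg <- sim_config(mod, des, seed = 9)
  st <- simulate_study(cfg)
  lin <- pgspower:::marker_scan(st$s1$X, st$s1$y, "linear")
  log <- pgspower:::marker_scan(st$s1$X, st$s1$y, "logistic")
  # Wald z-scores of the two fits track each other closely
  zl <- qnorm(lin$p / 2); zg <- qnorm(log$p / 2)
  expect_gt(cor(zl, zg), 0.98)
  expect_gt(cor(sign(lin$bhat), sign(log$bhat)), 0.9)
})
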