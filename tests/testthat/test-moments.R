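test_that("selection bounds reproduce the Wald window", {
  b <- selection_bounds(0, 1, n1 = 100)
  expect_equal(unname(b), c(0, Inf))

  b <- selection_bounds(0, 0.05, n1 = 10000, marginal_sd = 0.01)
  expect_equal(unname(b[1]), qnorm(0.975) * 0.01, tolerance = 1e-10)
  expect_equal(unname(round(b[1], 6)), 0.019600)

  expect_error(selection_bounds(0.5, 0.1, 100), "q0 < q1")
  expect_error(selection_bounds(0, 0.5, -5), "n1")

  # a null estimate falls inside the window with probability q1 - q0
  set.seed(11)
  n1 <- 400
  bh <- rnorm(1e5, 0, sqrt(1 / n1))
  for (w in list(c(0, 0.05), c(0.2, 0.7))) {
    bb <- selection_bounds(w[1], w[2], n1)
    frac <- mean(abs(bh) >= bb[1] & abs(bh) <= bb[2])
    expect_within_se(frac, sqrt((w[2] - w[1]) * (1 - w[2] + w[1]) / 1e5),
                     w[2] - w[1])
  }
})

test_that("truncated second moment matches an adaptive quadrature oracle", {
  expect_identical(truncated_second_moment(0, Inf), 1)
  expect_error(truncated_second_moment(2, 1), "a < b")
  expect_error(truncated_second_moment(-1, 1), "a >= 0")

  oracle <- function(a, b) {
    num <- integrate(function(z) z^2 * dnorm(z), a, b, rel.tol = 1e-12)$value
    den <- integrate(function(z) dnorm(z), a, b, rel.tol = 1e-12)$value
    num / den
  }
  for (ab in list(c(1, 2), c(0, 1), c(0.5, Inf), c(3, Inf), c(2.2, 2.3))) {
    expect_equal(truncated_second_moment(ab[1], ab[2]), oracle(ab[1], ab[2]),
                 tolerance = 1e-10)
  }
  # tail truncation inflates the second moment
  expect_gt(truncated_second_moment(2, Inf), truncated_second_moment(1, Inf))
  expect_gt(truncated_second_moment(1, Inf), 1)
})

test_that("score variance is invariant to pi0 at full inclusion", {
  des <- study_design(2000, 2000)
  for (pi0 in c(0, 0.5, 0.9)) {
    mo <- score_moments(polygenic_model(20000, 0.3, pi0 = pi0), des)
    mo0 <- score_moments(polygenic_model(20000, 0.3, pi0 = 0), des)
    expect_equal(mo$varS, mo0$varS, tolerance = 1e-10)
    expect_equal(mo$covSy, mo0$covSy, tolerance = 1e-10)
    # closed form: m * (sigma^2 + 1/n1)
    expect_equal(mo$varS, 0.3 + 20000 / 2000, tolerance = 1e-10)
  }
})

test_that("full-inclusion R2 matches the Daetwyler closed form on a grid", {
  grid <- expand.grid(vg = c(0.05, 0.2, 0.5, 0.8, 1),
                      n1 = c(500, 2000, 10000, 1e5),
                      m = c(1000, 20000, 1e5, 1e6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mo <- score_moments(polygenic_model(g$m, g$vg),
                        study_design(g$n1, 1000))
    expect_equal(score_r2(mo), g$vg^2 / (g$vg + g$m / g$n1), tolerance = 1e-10)
  }
})

test_that("moments satisfy Cauchy-Schwarz and vanish with the covariance", {
  set.seed(42)
  for (rep in 1:40) {
    mod <- polygenic_model(m = sample(c(1000, 5e4, 1e6), 1),
                           vg1 = runif(1), vg2 = runif(1),
                           rho12 = runif(1, -1, 1), pi0 = runif(1, 0, 0.99))
    tr1 <- if (runif(1) < 0.5) quantitative_trait() else
      binary_trait(runif(1, 0.001, 0.3), runif(1, 0.1, 0.9))
    tr2 <- if (runif(1) < 0.5) quantitative_trait() else
      binary_trait(runif(1, 0.001, 0.3), runif(1, 0.1, 0.9))
    q1 <- runif(1, 0.001, 1)
    des <- study_design(sample(c(500, 5000), 1), 1000, tr1, tr2,
                        q0 = runif(1, 0, q1 / 2), q1 = q1,
                        estimator = sample(c("linear", "shrinkage", "allele_count"), 1))
    mo <- score_moments(mod, des)
    expect_gte(mo$varS, 0)
    expect_lte(mo$covSy^2, mo$varS * mo$varY2 * (1 + 1e-12))
    if (mod$rho12 == 0) expect_equal(mo$covSy, 0)
  }
})

test_that("moments are monotone and continuous in the training sample size", {
  mod <- polygenic_model(5e4, 0.4, 0.3, 0.8, 0.5)
  des <- function(n1) study_design(n1, 1000)
  n1s <- c(100, 500, 2500, 1e4, 1e5, 1e9)
  mos <- lapply(n1s, function(n) score_moments(mod, des(n)))
  varS <- vapply(mos, `[[`, numeric(1), "varS")
  covSy <- vapply(mos, `[[`, numeric(1), "covSy")
  expect_true(all(diff(varS) < 0))
  expect_true(all(diff(covSy) >= -1e-12))
  lim <- score_moments(mod, des(Inf))
  expect_equal(varS[length(varS)], lim$varS, tolerance = 1e-3)
  expect_equal(covSy[length(covSy)], lim$covSy, tolerance = 1e-4)
})

test_that("shrinkage rescales moments without changing correlation metrics", {
  mod <- polygenic_model(2e4, 0.35, 0.25, 0.7, 0.9)
  for (q1 in c(1, 0.1)) {
    dl <- study_design(3000, 2000, q0 = 0, q1 = q1, estimator = "linear")
    ds <- study_design(3000, 2000, q0 = 0, q1 = q1, estimator = "shrinkage")
    ml <- score_moments(mod, dl); ms <- score_moments(mod, ds)
    expect_equal(score_r2(ms), score_r2(ml), tolerance = 1e-12)
    expect_lte(score_mse(ms), score_mse(ml))
    rl <- accuracy_report(mod, dl); rs <- accuracy_report(mod, ds)
    expect_equal(rs$ncp, rl$ncp, tolerance = 1e-10)
    expect_equal(rs$power, rl$power, tolerance = 1e-10)
  }
  # shrinkage factor tends to 1 as the training sample grows
  ds <- study_design(1e9, 2000, estimator = "shrinkage")
  expect_equal(score_moments(mod, ds)$shrink, 1, tolerance = 1e-3)
})

test_that("shrinkage beats linear MSE across a parameter grid", {
  set.seed(7)
  for (rep in 1:50) {
    mod <- polygenic_model(1e4, runif(1, 0.05, 0.9), runif(1, 0.05, 0.9),
                           runif(1), pi0 = runif(1, 0, 0.95))
    q1 <- runif(1, 0.01, 1)
    dl <- study_design(2000, 1000, q1 = q1, estimator = "linear")
    ds <- study_design(2000, 1000, q1 = q1, estimator = "shrinkage")
    expect_lte(score_mse(score_moments(mod, ds)),
               score_mse(score_moments(mod, dl)) + 1e-12)
  }
})

test_that("allele-count covariance quadrature matches a Monte-Carlo oracle", {
  set.seed(5)
  sig <- 0.02; se <- 0.01
  for (w in list(c(0.015, Inf), c(0, 0.03), c(0.01, 0.04))) {
    I <- pgspower:::allele_count_integral(sig, se, w[1], w[2])
    beta <- rnorm(1e6, 0, sig)
    bhat <- beta + rnorm(1e6, 0, se)
    sel <- abs(bhat) >= w[1] & abs(bhat) <= w[2]
    x <- sign(bhat) * beta * sel
    expect_within_se(mean(x), sd(x) / 1000, I)
  }
})

test_that("allele-count score has zero covariance under a null correlation", {
  mod <- polygenic_model(1e4, 0.3, 0.3, rho12 = 0, pi0 = 0.5)
  des <- study_design(2000, 1000, q1 = 0.2, estimator = "allele_count")
  mo <- score_moments(mod, des)
  expect_equal(mo$covSy, 0)
  expect_gt(mo$varS, 0)
})

test_that("infinite training sample gives the analytic limit", {
  mod <- polygenic_model(1e5, 0.5, 0.4, 0.9, 0.8)
  mo <- score_moments(mod, study_design(Inf, 1000))
  expect_equal(mo$varS, 0.5, tolerance = 1e-12)
  expect_equal(mo$covSy, 0.9 * sqrt(0.5 * 0.4), tolerance = 1e-12)
  # with q0 > 0 every non-null marker (P-value 0) is excluded
  mo0 <- score_moments(mod, study_design(Inf, 1000, q0 = 0.01, q1 = 0.5))
  expect_equal(mo0$covSy, 0)
})
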