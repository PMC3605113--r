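# Marker-level simulator of two-sample polygenic score studies.  This is the
# package's validation oracle: it generates genotype and trait data from the
# generative model and computes empirical counterparts of every analytic
# quantity.

#' Configure a simulation study
#'
#' @param model a [polygenic_model()]; truth for the simulated effects.
#' @param design a [study_design()] with finite `n1`.
#' @param replicates number of independent replicate studies.
#' @param seed RNG seed; all randomness flows from it.
#' @param maf_range range of the uniform minor allele frequency distribution.
#' @param effect_dist distribution of non-null effects: bivariate `"normal"`,
#'   or variance-matched `"laplace"` pairs coupled through a Gaussian copula
#'   calibrated to the target correlation.
#' @param est_param parameter re-estimated from each replicate's association
#'   statistic (see [estimate_parameter()]), or `NA` to skip.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(model, design, replicates = 200, seed = 1,
                       maf_range = c(0.01, 0.5),
                       effect_dist = c("normal", "laplace"),
                       est_param = "vg1") {
  effect_dist <- match.arg(effect_dist)
  stopifnot(inherits(model, "polygenic_model"), inherits(design, "study_design"),
            is.finite(design$n1), replicates >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] < maf_range[2], maf_range[2] <= 0.5)
  structure(list(model = model, design = design, replicates = replicates,
                 seed = seed, maf_range = maf_range, effect_dist = effect_dist,
                 est_param = est_param),
            class = "sim_config")
}

# quantile function of the standard (b = 1) Laplace distribution, variance 2
qlaplace <- function(u) {
  ifelse(u < 0.5, log(2 * u), -log(2 * (1 - u)))
}

# 40-point Gauss-Hermite rule (weight exp(-x^2)) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix; computed once per session
gauss_hermite_rule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      k <- 40
      off <- sqrt(seq_len(k - 1) / 2)
      J <- diag(0, k)
      J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
      J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
      e <- eigen(J, symmetric = TRUE)
      cache <<- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
    }
    cache
  }
})

# product-moment correlation of a Laplace pair induced by a Gaussian copula
# with correlation r, by Gauss-Hermite quadrature
laplace_copula_corr <- function(r) {
  gh <- gauss_hermite_rule()
  z <- gh$nodes * sqrt(2); w <- gh$weights / sqrt(pi)
  pn <- function(x) pmin(pmax(stats::pnorm(x), 1e-15), 1 - 1e-15)
  L <- qlaplace(pn(z))
  s <- sqrt(1 - r^2)
  inner <- vapply(z, function(z1) {
    sum(w * qlaplace(pn(r * z1 + s * z)))
  }, numeric(1))
  sum(w * L * inner) / 2  # Laplace variance is 2
}

# copula correlation achieving a target Laplace correlation
calibrate_laplace_copula <- function(rho) {
  if (rho == 0) return(0)
  if (abs(rho) >= 1) return(sign(rho))
  lim <- laplace_copula_corr(0.9999 * sign(rho))
  if (abs(rho) > abs(lim))
    stop("target correlation ", rho, " is not attainable for Laplace effects ",
         "(attainable range about +/-", signif(abs(lim), 4), ")")
  stats::uniroot(function(r) laplace_copula_corr(r) - rho,
                 sort(c(0, 0.9999 * sign(rho))), tol = 1e-9)$root
}

#' Draw per-marker effect sizes
#'
#' Exactly `round(m * pi0)` markers get zero effect on both traits; the rest
#' draw paired effects achieving the per-marker variances and correlation
#' implied by the model (bivariate normal, or Laplace marginals under a
#' calibrated Gaussian copula).
#'
#' @param config a [sim_config()].
#' @return A matrix with `m` rows and columns `beta1`, `beta2`, on the
#'   trait/liability scale.
#' @export
simulate_effects <- function(config) {
  mod <- config$model
  m <- mod$m
  n_null <- round(m * mod$pi0)
  n_eff <- m - n_null
  s1 <- sqrt(mod$vg1 / n_eff)
  s2 <- sqrt(mod$vg2 / n_eff)
  B <- matrix(0, m, 2, dimnames = list(NULL, c("beta1", "beta2")))
  if (n_eff > 0) {
    idx <- seq_len(n_eff)  # effect markers first; exchangeable anyway
    if (config$effect_dist == "normal") {
      z1 <- stats::rnorm(n_eff)
      z2 <- mod$rho12 * z1 + sqrt(1 - mod$rho12^2) * stats::rnorm(n_eff)
      B[idx, 1] <- s1 * z1
      B[idx, 2] <- s2 * z2
    } else {
      r <- calibrate_laplace_copula(mod$rho12)
      z1 <- stats::rnorm(n_eff)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_eff)
      B[idx, 1] <- s1 * qlaplace(stats::pnorm(z1)) / sqrt(2)
      B[idx, 2] <- s2 * qlaplace(stats::pnorm(z2)) / sqrt(2)
    }
  }
  B
}

# one sample for one trait: standardised HWE genotypes, trait values per the
# generative model.  For ascertained binary traits (P != K) a conditional
# scheme is used: the aggregate genetic liability is drawn given case status
# from its truncated-normal law, and genotypes follow their joint-normal
# approximation given the aggregate; this avoids rejection sampling for rare
# diseases at the cost of Gaussian (rather than Hardy-Weinberg) genotypes.
simulate_sample <- function(n, maf, beta, vg, trait) {
  m <- length(maf)
  if (trait$kind == "binary" && trait$ascertained) {
    lt <- liability_threshold(trait$K)
    n_case <- round(n * trait$P)
    y <- rep(c(1, 0), c(n_case, n - n_case))
    u <- stats::runif(n)
    liab <- ifelse(y == 1,
                   stats::qnorm(stats::pnorm(lt$T) + u * trait$K),
                   stats::qnorm(u * stats::pnorm(lt$T)))
    X <- cpp_norm_matrix(n, m)
    Sb2 <- sum(beta^2)
    if (vg > 0 && Sb2 > 0) {
      # aggregate genetic liability given case/control status, then genotypes
      # from their joint-normal law given the aggregate: the conditional
      # covariance is the rank-one downdate I - beta beta^T / sum(beta^2),
      # which pins the realised aggregate beta^T x exactly to G
      G <- stats::rnorm(n, vg * liab, sqrt(vg * (1 - vg)))
      t <- as.vector(X %*% beta)
      X <- X + outer((G - t) / Sb2, beta)
    }
    return(list(X = X, y = y, liab = liab))
  }
  X <- cpp_std_genotypes(n, maf)
  g <- if (any(beta != 0)) as.vector(X %*% beta) else numeric(n)
  liab <- g + stats::rnorm(n, 0, sqrt(max(0, 1 - vg)))
  if (trait$kind == "binary") {
    lt <- liability_threshold(trait$K)
    list(X = X, y = as.numeric(liab > lt$T), liab = liab)
  } else {
    list(X = X, y = liab, liab = liab)
  }
}

# Brute-force case/control sampling with real Hardy-Weinberg genotypes:
# simulate cohorts and keep cases/controls until the quotas are met.  Only
# feasible for common diseases; used to validate the conditional scheme.
simulate_sample_rejection <- function(n, maf, beta, vg, trait) {
  stopifnot(trait$kind == "binary")
  lt <- liability_threshold(trait$K)
  n_case <- round(n * trait$P)
  n_ctrl <- n - n_case
  Xc <- Xk <- list(); yc <- 0; yk <- 0
  batch <- max(200, ceiling(n / max(trait$K, 1 - trait$K)))
  while (yc < n_case || yk < n_ctrl) {
    X <- cpp_std_genotypes(batch, maf)
    liab <- as.vector(X %*% beta) + stats::rnorm(batch, 0, sqrt(max(0, 1 - vg)))
    case <- liab > lt$T
    if (yc < n_case && any(case)) {
      keep <- which(case)[seq_len(min(sum(case), n_case - yc))]
      Xc[[length(Xc) + 1]] <- X[keep, , drop = FALSE]
      yc <- yc + length(keep)
    }
    if (yk < n_ctrl && any(!case)) {
      keep <- which(!case)[seq_len(min(sum(!case), n_ctrl - yk))]
      Xk[[length(Xk) + 1]] <- X[keep, , drop = FALSE]
      yk <- yk + length(keep)
    }
  }
  list(X = rbind(do.call(rbind, Xc), do.call(rbind, Xk)),
       y = rep(c(1, 0), c(n_case, n_ctrl)))
}

#' Generate one replicate study
#'
#' Draws minor allele frequencies, effect sizes, and genotype/trait data for
#' the training and replication samples of one simulated study.
#'
#' @param config a [sim_config()].
#' @param effects optional effect matrix from [simulate_effects()]; drawn
#'   fresh when missing.
#' @return A list with `maf`, `effects`, and samples `s1`, `s2`, each holding
#'   a standardised genotype matrix `X`, the analysed trait `y`, and the
#'   underlying liability.
#' @export
simulate_study <- function(config, effects = NULL) {
  mod <- config$model; des <- config$design
  maf <- stats::runif(mod$m, config$maf_range[1], config$maf_range[2])
  if (is.null(effects)) effects <- simulate_effects(config)
  s1 <- simulate_sample(des$n1, maf, effects[, 1], mod$vg1, des$trait1)
  s2 <- simulate_sample(des$n2, maf, effects[, 2], mod$vg2, des$trait2)
  list(maf = maf, effects = effects, s1 = s1, s2 = s2)
}

# per-marker association scan: slopes, standard errors, two-sided P-values
marker_scan <- function(X, y, fit = c("linear", "logistic")) {
  fit <- match.arg(fit)
  n <- length(y)
  if (fit == "linear") {
    yc <- y - mean(y)
    bhat <- as.vector(crossprod(X, yc)) / n
    se <- sqrt(stats::var(y) / n)
    p <- 2 * stats::pnorm(-abs(bhat) / se)
    list(bhat = bhat, p = p)
  } else {
    m <- ncol(X)
    bhat <- p <- numeric(m)
    for (j in seq_len(m)) {
      f <- stats::glm.fit(cbind(1, X[, j]), y, family = stats::binomial())
      cf <- f$coefficients[2]
      # Wald from the unscaled covariance of the IRLS fit
      R <- chol2inv(f$qr$qr[1:2, 1:2, drop = FALSE])
      sej <- sqrt(R[2, 2])
      bhat[j] <- cf
      p[j] <- 2 * stats::pnorm(-abs(cf) / sej)
    }
    list(bhat = bhat, p = p)
  }
}

empirical_auc <- function(score, status) {
  ca <- score[status == 1]; co <- score[status == 0]
  if (!length(ca) || !length(co)) return(NA_real_)
  r <- rank(c(ca, co))
  (sum(r[seq_along(ca)]) - length(ca) * (length(ca) + 1) / 2) /
    (length(ca) * length(co))
}

#' Run replicate simulations and compare to analytic values
#'
#' For each replicate: fit per-marker regressions in sample 1, select markers
#' whose two-sided P-values fall in the design's window, build the score with
#' the configured estimator, and in sample 2 compute the empirical
#' chi-squared association statistic, R-squared, mean square error, and AUC
#' (binary trait 2).  Optionally re-estimates a model parameter from each
#' replicate's statistic and records whether its confidence interval covers
#' the truth.
#'
#' @param config a [sim_config()].
#' @param fit per-marker regression: `"linear"` (default) or `"logistic"`
#'   (binary traits, small panels; each marker is fit by IRLS).
#' @param progress print a dot every 10 replicates.
#' @return An object of class `"sim_result"`: `replicates` (per-replicate
#'   data frame), `summary` (means and Monte-Carlo SEs, empirical NCP, power,
#'   estimate medians and CI coverage), and `analytic` (the corresponding
#'   [accuracy_report()]).
#' @export
evaluate_replicates <- function(config, fit = "linear", progress = FALSE) {
  mod <- config$model; des <- config$design
  set.seed(config$seed)
  truth <- switch(config$est_param,
                  vg = , vg1 = mod$vg1, vg2 = mod$vg2,
                  rho12 = mod$rho12, pi0 = mod$pi0, NA_real_)
  est_model <- mod
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    st <- simulate_study(config)
    scan <- marker_scan(st$s1$X, st$s1$y, fit = fit)
    sel <- which(scan$p > des$q0 & scan$p <= des$q1)
    if (!length(sel)) {
      rows[[r]] <- data.frame(n_selected = 0, chisq = NA, r2 = NA, mse = NA,
                              auc = NA, est = NA, covered = NA)
      next
    }
    w <- scan$bhat
    if (des$estimator == "shrinkage") {
      s1sc <- trait_scale(des$trait1)
      sig1o2 <- s1sc$C^2 * mod$vg1 / (mod$m * (1 - mod$pi0))
      w <- w * sig1o2 / (sig1o2 + s1sc$varY / des$n1)
    } else if (des$estimator == "allele_count") {
      s1sc <- trait_scale(des$trait1)
      w <- s1sc$C * sqrt(mod$vg1 / mod$m) * sign(w)
    }
    wfull <- numeric(mod$m)
    wfull[sel] <- w[sel]
    S <- as.vector(st$s2$X %*% wfull)
    y2 <- st$s2$y
    rho <- suppressWarnings(stats::cor(S, y2))
    if (!is.finite(rho)) rho <- 0
    chisq <- des$n2 * rho^2 / (1 - rho^2)
    auc <- if (des$trait2$kind == "binary") empirical_auc(S, y2) else NA_real_
    est <- cov <- NA_real_
    if (!is.na(config$est_param) && !is.na(truth)) {
      e <- try(estimate_parameter(est_model, des, param = config$est_param,
                                  chisq = chisq), silent = TRUE)
      if (!inherits(e, "try-error")) {
        est <- e$estimate
        cov <- as.numeric(truth >= e$ci[1] && truth <= e$ci[2])
      }
    }
    rows[[r]] <- data.frame(n_selected = length(sel), chisq = chisq,
                            r2 = rho^2, mse = mean((S - y2)^2), auc = auc,
                            est = est, covered = cov)
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  sem <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summary <- list(
    ncp_emp = mean(reps$chisq, na.rm = TRUE) - 1,
    ncp_se = sem(reps$chisq),
    r2_emp = mean(reps$r2, na.rm = TRUE), r2_se = sem(reps$r2),
    mse_emp = mean(reps$mse, na.rm = TRUE), mse_se = sem(reps$mse),
    auc_emp = mean(reps$auc, na.rm = TRUE), auc_se = sem(reps$auc),
    power_emp = mean(stats::pchisq(reps$chisq, 1, lower.tail = FALSE) < des$alpha,
                     na.rm = TRUE),
    est_median = stats::median(reps$est, na.rm = TRUE),
    ci_coverage = mean(reps$covered, na.rm = TRUE),
    n_degenerate = sum(reps$n_selected == 0))
  structure(list(replicates = reps, summary = summary,
                 analytic = accuracy_report(mod, des), config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary; a <- x$analytic
  cat(sprintf("Simulation of %d replicates (seed %d)\n",
              x$config$replicates, x$config$seed))
  cat(sprintf("  NCP:   empirical %.4g +/- %.2g, analytic %.4g\n",
              s$ncp_emp, s$ncp_se, a$ncp))
  cat(sprintf("  R^2:   empirical %.4g +/- %.2g, analytic %.4g\n",
              s$r2_emp, s$r2_se, a$r2_obs))
  if (!is.na(a$mse))
    cat(sprintf("  MSE:   empirical %.4g +/- %.2g, analytic %.4g\n",
                s$mse_emp, s$mse_se, a$mse))
  if (!is.na(a$auc))
    cat(sprintf("  AUC:   empirical %.4g +/- %.2g, analytic %.4g\n",
                s$auc_emp, s$auc_se, a$auc))
  cat(sprintf("  power: empirical %.4g, analytic %.4g\n", s$power_emp, a$power))
  if (is.finite(s$est_median))
    cat(sprintf("  %s: median estimate %.4g, CI coverage %.3f\n",
                x$config$est_param, s$est_median, s$ci_coverage))
  if (s$n_degenerate > 0)
    cat(sprintf("  degenerate replicates (no markers selected): %d\n",
                s$n_degenerate))
  invisible(x)
}
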