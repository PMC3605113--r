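# Inverse design problems: required sample sizes, optimal training fraction,
# optimal P-value selection threshold, and regeneration of the summary tables.

design_metric <- function(model, design, objective) {
  switch(objective,
         power = accuracy_report(model, design)$power,
         auc = pgs_auc(model, design),
         correlation = sqrt(score_r2(score_moments(model, design))),
         ncp = {
           mo <- score_moments(model, design)
           r2 <- score_r2(mo)
           design$n2 * r2 / (1 - r2)
         },
         r2 = score_r2(score_moments(model, design)),
         stop("unknown objective: ", objective))
}

# rebuild the design at a given per-sample size n (cases for binary traits,
# subjects for quantitative).  For the power objective both samples scale;
# for prediction objectives only the training sample matters.
design_at_n <- function(design, n, objective) {
  d <- design
  subj <- function(trait, n) if (trait$kind == "binary") n / trait$P else n
  d$n1 <- subj(d$trait1, n)
  if (objective == "power") d$n2 <- subj(d$trait2, n)
  d
}

#' Required sample size for a target power, AUC, or correlation
#'
#' Finds the smallest per-sample size achieving a target value of the chosen
#' objective.  For binary traits the returned size counts *cases* per sample
#' (an equal number of controls is implied when the case fraction is 1/2);
#' for quantitative traits it counts subjects.  The `power` objective scales
#' both the training and replication samples together; the `auc` and
#' `correlation` objectives depend only on the training sample and scale
#' `n1` alone.
#'
#' Feasibility is checked first against the infinite-training-sample maximum
#' (`power` can always reach any target below 1 when the score-trait
#' covariance is positive).  When `optimize_threshold` is `TRUE` the upper
#' selection threshold `q1` is tuned to maximise the objective at each
#' candidate size, and the maximising threshold at the solution is reported.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()] template supplying traits, thresholds,
#'   estimator and alpha.
#' @param objective one of `"power"`, `"auc"`, `"correlation"`.
#' @param target target value of the objective.
#' @param optimize_threshold maximise over the upper selection threshold at
#'   each candidate size?
#' @param rounding granularity: the result is rounded up to a multiple of
#'   this (default 1, exact).
#' @return A list with `n` (required size), `achieved` (objective at `n`),
#'   and `q1` (threshold used at the solution).
#' @examples
#' sz <- binary_trait(K = 0.01, P = 0.5)
#' required_n(polygenic_model(m = 74062, vg1 = 0.287),
#'            study_design(2, 2, sz, sz), "power", 0.8)  # 735 cases+controls
#' @export
required_n <- function(model, design, objective = c("power", "auc", "correlation"),
                       target, optimize_threshold = FALSE, rounding = 1) {
  objective <- match.arg(objective)
  stopifnot(is.numeric(target), length(target) == 1, rounding >= 1)
  value_at <- function(n) {
    d <- design_at_n(design, n, objective)
    if (optimize_threshold) {
      obj <- if (objective == "power") "power" else if (objective == "auc") "auc" else "r2"
      opt <- optimal_threshold(model, d, objective = obj)
      d$q1 <- opt$q1
    }
    design_metric(model, d, objective)
  }
  # feasibility gate
  if (objective != "power") {
    dinf <- design_at_n(design, Inf, objective)
    dinf$q0 <- 0; dinf$q1 <- 1
    vmax <- design_metric(model, dinf, objective)
    if (target > vmax + 1e-12)
      stop("target ", target, " exceeds the infinite-training-sample maximum ",
           signif(vmax, 6))
  } else {
    mo <- score_moments(model, design_at_n(design, 1000, "power"))
    if (mo$covSy <= 0 && target > design$alpha)
      stop("score has no covariance with the tested trait; power cannot exceed alpha")
    if (target >= 1) stop("target power must be below 1")
  }
  # exponential bracketing on the monotone objective, then bisection
  lo <- 1; hi <- 2
  while (value_at(hi) < target) {
    lo <- hi
    hi <- hi * 2
    if (hi > 2^34) stop("required sample size exceeds search limit")
  }
  root <- stats::uniroot(function(n) value_at(n) - target, c(lo, hi),
                         tol = 0.25)$root
  n <- ceiling(root)
  while (n > 1 && value_at(n - 1) >= target) n <- n - 1
  if (value_at(n) < target) n <- n + 1
  n <- as.integer(ceiling(n / rounding) * rounding)
  d <- design_at_n(design, n, objective)
  q1 <- design$q1
  if (optimize_threshold) {
    obj <- if (objective == "power") "power" else if (objective == "auc") "auc" else "r2"
    q1 <- optimal_threshold(model, d, objective = obj)$q1
    d$q1 <- q1
  }
  list(n = n, achieved = design_metric(model, d, objective), q1 = q1)
}

#' Optimal split of a sample into training and replication subsets
#'
#' Maximises the non-centrality parameter of the score association test over
#' the fraction of subjects allocated to the training sample, holding the
#' case/control composition of each subset equal to the totals'.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()] template (its `n1`, `n2` are ignored).
#' @param total_cases,total_controls totals available for a binary trait; for
#'   quantitative traits give `total_subjects` instead.
#' @param total_subjects total sample size for quantitative traits.
#' @param grid_points number of grid fractions for the reported NCP curve.
#' @return A list with `fraction` (optimal training fraction), `ncp` at the
#'   optimum, and `curve`, a data frame of NCP over a fraction grid for
#'   symmetry inspection.
#' @examples
#' sz <- binary_trait(K = 0.01, P = 6009 / 12252)
#' optimal_split(polygenic_model(m = 74062, vg1 = 0.287),
#'               study_design(2, 2, sz, sz, q1 = 0.5),
#'               total_cases = 6009, total_controls = 6243)
#' @export
optimal_split <- function(model, design, total_cases = NULL,
                          total_controls = NULL, total_subjects = NULL,
                          grid_points = 41) {
  binary <- design$trait1$kind == "binary"
  if (binary) {
    stopifnot(!is.null(total_cases), !is.null(total_controls))
    total <- total_cases + total_controls
    P <- total_cases / total
  } else {
    stopifnot(!is.null(total_subjects))
    total <- total_subjects
  }
  ncp_at <- function(f) {
    d <- design
    d$n1 <- f * total
    d$n2 <- (1 - f) * total
    if (binary) {
      d$trait1 <- binary_trait(design$trait1$K, P)
      d$trait2 <- binary_trait(design$trait2$K, P)
    }
    design_metric(model, d, "ncp")
  }
  opt <- stats::optimize(ncp_at, c(0.01, 0.99), maximum = TRUE, tol = 1e-6)
  fr <- seq(0.05, 0.95, length.out = grid_points)
  curve <- data.frame(fraction = fr, ncp = vapply(fr, ncp_at, numeric(1)))
  list(fraction = opt$maximum, ncp = opt$objective, curve = curve)
}

#' Optimal upper selection threshold
#'
#' Maximises a metric over the upper P-value threshold `q1` (with `q0` fixed,
#' usually 0), using a 40-point log-spaced grid on `[1e-8, 1]` refined by a
#' local golden-section search around the best grid point.  For `pi0 = 0`
#' with the linear estimator the optimum is `q1 = 1`: every marker carries
#' signal.
#'
#' @param model a [polygenic_model()].
#' @param design a [study_design()] (its `q1` is ignored).
#' @param objective one of `"ncp"`, `"auc"`, `"r2"`, `"power"`.
#' @return A list with `q1` (maximising threshold) and `value` (metric at the
#'   optimum).
#' @export
optimal_threshold <- function(model, design,
                              objective = c("ncp", "auc", "r2", "power")) {
  objective <- match.arg(objective)
  at <- function(lq1) {
    d <- design
    d$q1 <- min(10^lq1, 1)
    if (d$q0 >= d$q1) return(-Inf)
    design_metric(model, d, objective)
  }
  grid <- seq(-8, 0, length.out = 40)
  vals <- vapply(grid, at, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(at, c(lo, hi), maximum = TRUE, tol = 1e-7)
  best <- if (opt$objective >= vals[k]) list(l = opt$maximum, v = opt$objective)
          else list(l = grid[k], v = vals[k])
  # the full-window endpoint is always a candidate
  if (at(0) >= best$v) best <- list(l = 0, v = at(0))
  list(q1 = min(10^best$l, 1), value = best$v)
}

# ---------------------------------------------------------------------------
# Table regeneration

table_diseases <- list(
  crohn = list(name = "Crohn's disease", h2 = 0.76, K = 0.001),
  brca  = list(name = "Breast cancer",   h2 = 0.44, K = 0.036))

#' Regenerate the published summary tables
#'
#' Recomputes, from the analytic machinery, the grids of required sample
#' sizes (in 1000s of cases and controls, rounded up) for target AUC levels
#' under marker panels explaining half (`"table4"`, 100,000 markers) or all
#' (`"table5"`, 1,000,000 markers) of the heritability of liability, the
#' required sizes for target correlations with a quantitative trait
#' (`"table6"`), the AUC comparison for the five WTCCC diseases
#' (`"table2"`), and the liability R-squared / AUC comparison for published
#' designs (`"table3"`, the four columns whose study designs are fully
#' specified here).  Each sample-size cell reports the size together with
#' the P-value threshold that maximises the objective, with `q0 = 0`
#' throughout.
#'
#' @param which table identifier.
#' @return A data frame; sample-size tables have one row per (disease or
#'   heritability, target) pair and one column pair per null proportion.
#' @export
reproduce_table <- function(which = c("table4", "table5", "table6", "table2",
                                      "table3")) {
  which <- match.arg(which)
  switch(which,
         table4 = auc_sample_size_table(m = 1e5, frac_h2 = 0.5,
                                        pi0s = c(0.99, 0.9, 0.75, 0)),
         table5 = auc_sample_size_table(m = 1e6, frac_h2 = 1,
                                        pi0s = c(0.999, 0.99, 0.9, 0.75, 0)),
         table6 = correlation_sample_size_table(),
         table2 = wtccc_auc_table(),
         table3 = liability_r2_table())
}

auc_sample_size_table <- function(m, frac_h2, pi0s) {
  rows <- list()
  for (dname in names(table_diseases)) {
    d <- table_diseases[[dname]]
    vg <- frac_h2 * d$h2
    tr <- binary_trait(d$K, 0.5)
    des <- study_design(2, 2, tr, tr)
    maxauc <- pgs_auc(polygenic_model(m, vg), study_design(Inf, 2, tr, tr))
    targets <- c(auc_0.75 = 0.75, `0.90max` = 0.9 * maxauc,
                 `0.95max` = 0.95 * maxauc, `0.99max` = 0.99 * maxauc)
    for (tn in names(targets)) {
      row <- list(disease = d$name, max_auc = maxauc, target = targets[[tn]],
                  target_label = tn)
      for (pi0 in pi0s) {
        mod <- polygenic_model(m, vg, pi0 = pi0)
        cell <- if (targets[[tn]] > maxauc) list(n = NA, q1 = NA)
                else required_n(mod, des, "auc", targets[[tn]],
                                optimize_threshold = TRUE, rounding = 1000)
        row[[sprintf("n1000_pi0_%g", pi0)]] <- cell$n / 1000
        row[[sprintf("q1_pi0_%g", pi0)]] <- cell$q1
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

correlation_sample_size_table <- function() {
  rows <- list()
  for (h2 in c(0.8, 0.4)) {
    maxcor <- sqrt(h2)
    des <- study_design(2, 2)
    targets <- c(`0.90max` = 0.9 * maxcor, `0.95max` = 0.95 * maxcor,
                 `0.99max` = 0.99 * maxcor)
    for (tn in names(targets)) {
      row <- list(h2 = h2, max_cor = maxcor, target = targets[[tn]],
                  target_label = tn)
      for (pi0 in c(0.999, 0.99, 0.9, 0.75, 0)) {
        mod <- polygenic_model(1e6, h2, pi0 = pi0)
        cell <- required_n(mod, des, "correlation", targets[[tn]],
                           optimize_threshold = TRUE, rounding = 1000)
        row[[sprintf("n1000_pi0_%g", pi0)]] <- cell$n / 1000
        row[[sprintf("q1_pi0_%g", pi0)]] <- cell$q1
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

wtccc_auc_table <- function() {
  dis <- data.frame(
    disease = c("Bipolar disorder", "Coronary artery disease",
                "Crohn's disease", "Hypertension", "Type-2 diabetes"),
    K = c(0.01, 0.056, 0.001, 0.3, 0.03),
    h2 = c(0.69, 0.72, 0.76, 1, 0.6))
  n_cases <- 2000; n_controls <- 1480
  rows <- lapply(seq_len(nrow(dis)), function(i) {
    d <- dis[i, ]
    tr <- binary_trait(d$K, n_cases / (n_cases + n_controls))
    out <- data.frame(disease = d$disease, K = d$K, h2 = d$h2)
    for (est in c("linear", "allele_count")) {
      des <- study_design(n_cases + n_controls, 2, tr, tr, q1 = 0.8,
                          estimator = est)
      desi <- des; desi$n1 <- Inf
      for (frac in c(0.5, 1)) {
        mod <- polygenic_model(74062, frac * d$h2)
        tag <- paste0(est, if (frac == 0.5) "_half" else "_full")
        out[[paste0("auc_", tag)]] <- pgs_auc(mod, des)
        out[[paste0("auc_", tag, "_inf")]] <- pgs_auc(mod, desi)
      }
    }
    out
  })
  do.call(rbind, rows)
}

liability_r2_table <- function() {
  studies <- list(
    list(study = "Schizophrenia", K = 0.01, h2 = 0.8, m = 74062,
         n1 = 6909, P1 = 3322 / 6909, n2 = 5343, P2 = 2687 / 5343, q1 = 0.5),
    list(study = "Multiple sclerosis", K = 0.001, h2 = 0.5, m = 59470,
         n1 = 3362, P1 = 931 / 3362, n2 = 2953, P2 = 876 / 2953, q1 = 1),
    list(study = "Breast cancer", K = 0.036, h2 = 0.44, m = 161702,
         n1 = 0.9 * 2287, P1 = 0.5, n2 = 0.1 * 2287, P2 = 0.5, q1 = 1),
    list(study = "Prostate cancer", K = 0.024, h2 = 0.44, m = 165508,
         n1 = 0.9 * 2277, P1 = 0.5, n2 = 0.1 * 2277, P2 = 0.5, q1 = 1))
  rows <- lapply(studies, function(s) {
    tr1 <- binary_trait(s$K, s$P1); tr2 <- binary_trait(s$K, s$P2)
    out <- data.frame(study = s$study, K = s$K, h2 = s$h2)
    for (frac in c(0.25, 0.5, 1)) {
      mod <- polygenic_model(s$m, frac * s$h2)
      des <- study_design(s$n1, s$n2, tr1, tr2, q1 = s$q1)
      desi <- des; desi$n1 <- Inf
      tag <- sprintf("%g", frac)
      rep <- accuracy_report(mod, des)
      repi <- accuracy_report(mod, desi)
      out[[paste0("r2liab_", tag)]] <- rep$r2_liab
      out[[paste0("r2liab_", tag, "_inf")]] <- repi$r2_liab
      out[[paste0("auc_", tag)]] <- rep$auc
      out[[paste0("auc_", tag, "_inf")]] <- repi$auc
    }
    out
  })
  do.call(rbind, rows)
}
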