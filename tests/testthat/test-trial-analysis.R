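reg <- measure_registry()

test_that("binomial rescaling follows the min-shift/range rule and round-trips", {
  expect_equal(rescale_to_binomial(21, reg$tbes),
               data.frame(successes = 21, trials = 84))
  expect_equal(rescale_to_binomial(27, reg$self_efficacy),
               data.frame(successes = 0, trials = 108))
  expect_equal(rescale_to_binomial(50, reg$knowledge),
               data.frame(successes = 50, trials = 100))
  expect_error(rescale_to_binomial(90, reg$tbes), "outside")
  set.seed(1)
  for (m in c("tbes", "self_efficacy", "knowledge")) {
    spec <- reg[[m]]
    sc <- runif(20, spec$total_min, spec$total_max)
    bin <- rescale_to_binomial(sc, spec)
    expect_equal(spec$total_min + bin$successes, sc)
    expect_true(all(bin$successes >= 0 & bin$successes <= bin$trials))
  }
})

test_that("Holm adjustment matches its definition, a brute-force oracle, and p.adjust", {
  expect_equal(holm_adjust(c(.001, .02, .04)), c(.003, .04, .04))
  expect_equal(holm_adjust(.2), .2)
  expect_equal(holm_adjust(rep(.05, 16)), rep(.8, 16))
  expect_error(holm_adjust(c(.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(holm_adjust(p), oracle_holm(p))
    expect_equal(holm_adjust(p), p.adjust(p, method = "holm"))
    expect_true(all(holm_adjust(p) >= p))
    # permutation invariance in input order
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), holm_adjust(p)[perm])
    # smallest p gets the full Bonferroni factor
    expect_equal(min(holm_adjust(p)), min(1, length(p) * min(p)))
  }
})

test_that("the contrast set has 16 zero-sum rows in families of 8/4/4", {
  C <- build_contrasts()
  expect_equal(nrow(C), 16L)
  expect_equal(unname(table(attr(C, "family"))[
    c("within_condition", "cross_sectional", "difference_in_change")]),
    c(8L, 4L, 4L), ignore_attr = TRUE)
  expect_true(all(abs(rowSums(C)) < 1e-12))
  expect_error(build_contrasts(arms = c("a", "b", "c")), "exactly 2 arms")
})

test_that("the saturated fit reproduces directly tabulated cell proportions", {
  ds <- generate_trial(generator_config(), seed = 11)
  for (m in c("tbes", "knowledge")) {
    fit <- fit_marginal_binomial(ds, m, reg)
    expect_true(fit$converged)
    # independent oracle: plain aggregation of the raw scores
    for (i in seq_len(nrow(fit$cells))) {
      cell <- fit$cells[i, ]
      raw <- ds$score[ds$measure == m & ds$arm == cell$arm &
                        ds$timepoint == cell$timepoint]
      expect_equal(cell$model_mean, mean(raw), tolerance = 1e-8)
      expect_equal(cell$empirical_mean, mean(raw))
    }
    expect_true(all(fit$cells$ci_low <= fit$cells$model_mean &
                      fit$cells$model_mean <= fit$cells$ci_high))
  }
})

test_that("with one observation per cluster the sandwich equals the glm HC0 covariance", {
  cfg <- generator_config(n_per_arm = c(hmd = 30L, desktop = 30L))
  sc <- generate_endpoint_scores(cfg, "sus", seed = 5)
  spec <- reg$sus
  bin <- rescale_to_binomial(sc$score, spec)
  y <- bin$successes / bin$trials
  arm <- factor(sc$arm, levels = unique(sc$arm))
  X <- model.matrix(~ 0 + arm)
  fit <- exposim:::gee_binomial(y, bin$trials, X, cluster = sc$participant_id)
  g <- glm(y ~ 0 + arm, family = quasibinomial(), weights = bin$trials)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
  mu <- fitted(g)
  U <- X * (bin$trials * (y - mu))
  B <- t(X) %*% (X * (bin$trials * mu * (1 - mu)))
  hc0 <- solve(B) %*% (t(U) %*% U) %*% solve(B)
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-8)
})

test_that("the exchangeable working correlation converges and stays saturated", {
  ds <- generate_trial(generator_config(), seed = 13)
  ind <- fit_marginal_binomial(ds, "tbes", reg, "independence")
  exch <- fit_marginal_binomial(ds, "tbes", reg, "exchangeable")
  expect_true(exch$converged)
  expect_gt(exch$alpha, 0)    # positive within-participant correlation
  expect_lt(exch$alpha, 1)
  # saturated mean structure: both give (nearly) the tabulated proportions
  expect_equal(exch$cells$model_mean, ind$cells$model_mean, tolerance = 0.02)
})

test_that("degenerate boundary cells get the continuity adjustment", {
  people <- sprintf("P%02d", 1:8)
  ds <- data.frame(
    participant_id = rep(people, each = 4),
    arm = rep(c("hmd", "desktop"), each = 16),
    timepoint = rep(c("T0", "T1", "T2", "T3"), times = 8),
    measure = "tbes",
    score = 20)
  ds$score[ds$arm == "hmd" & ds$timepoint == "T0"] <- 0  # all at the floor
  fit <- fit_marginal_binomial(ds, "tbes", reg)
  expect_equal(fit$adjusted_cells, "hmd.T0")
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("Cohen's d matches its definitions and recovers a known effect", {
  mk <- function(t0, t1, arm = "a") {
    n <- length(t0)
    data.frame(participant_id = rep(sprintf("%s%03d", arm, 1:n), 2),
               arm = arm, timepoint = rep(c("T0", "T1"), each = n),
               measure = "m", score = c(t0, t1))
  }
  ds <- mk(c(0, 0), c(1, -1))
  expect_equal(cohens_d(ds, "m", "change", arm = "a", from = "T0", to = "T1"),
               0)
  same <- mk(c(1, 2), c(3, 4))
  expect_error(cohens_d(same, "m", "change", arm = "a", from = "T0", to = "T1"),
               "zero variance")
  set.seed(21)
  n <- 5000
  big <- mk(rep(0, n), rnorm(n, 0.8, 1))
  expect_equal(cohens_d(big, "m", "change", arm = "a", from = "T0", to = "T1"),
               0.8, tolerance = 0.05)
  # cross-sectional: mean difference over pooled SD
  two <- rbind(mk(rnorm(n, 1, 1), rep(0, n), arm = "a"),
               mk(rnorm(n, 0, 1), rep(0, n), arm = "b"))
  expect_equal(cohens_d(two, "m", "cross_sectional", timepoint = "T0"),
               1, tolerance = 0.06)
})

test_that("analyze_trial emits 16 Holm-adjusted hypotheses per measure", {
  ds <- generate_trial(generator_config(), seed = 3)
  rep_ <- analyze_trial(ds)
  ct <- report_contrasts(rep_)
  expect_equal(nrow(ct), 48L)
  expect_equal(unname(table(ct$measure)), rep(16L, 3), ignore_attr = TRUE)
  expect_true(all(ct$p_holm >= ct$p_raw - 1e-12))
  # within one measure, adjusted values are monotone in raw-p order
  for (m in unique(ct$measure)) {
    sub <- ct[ct$measure == m, ]
    o <- order(sub$p_raw)
    expect_true(!is.unsorted(sub$p_holm[o]))
  }
  expect_true(all(is.finite(ct$cohen_d)))
})

test_that("analysis reports serialize to CSV and JSON", {
  ds <- generate_trial(generator_config(), seed = 6)
  rep_ <- analyze_trial(ds)
  dir <- tempfile()
  write_analysis_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c("contrasts.csv", "cells.csv",
                                               "report.json")))))
  back <- read.csv(file.path(dir, "contrasts.csv"))
  expect_equal(nrow(back), 48L)
  parsed <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(names(parsed$measures), c("knowledge", "self_efficacy", "tbes"))
})

test_that("endpoint comparison tests exactly one hypothesis with the right sign", {
  # identical groups: zero logit difference
  sc <- data.frame(participant_id = sprintf("P%02d", 1:20),
                   arm = rep(c("hmd", "desktop"), each = 10),
                   score = rep(c(70, 80, 85, 90, 95), 4))
  res <- analyze_endpoint(sc, reg$sus)
  expect_equal(nrow(res$comparison), 1L)
  expect_equal(res$comparison$estimate_logit, 0, tolerance = 1e-10)
  # large-n generated difference: significant, hmd below desktop
  cfg <- generator_config(n_per_arm = c(hmd = 500L, desktop = 500L),
                          subject_sd = 0)
  big <- generate_endpoint_scores(cfg, "sus", seed = 8)
  res2 <- analyze_endpoint(big, reg$sus)
  expect_lt(res2$comparison$estimate_logit, 0)
  expect_lt(res2$comparison$p_raw, 0.001)
  expect_error(analyze_endpoint(sc[sc$arm == "hmd", ], reg$sus),
               "exactly 2 arms")
})
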