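test_that("aggregate_patient computes medians with the even-count convention", {
  f <- data.frame(patient_id = rep("a", 3), fd = c(2.10, 2.12, 2.14))
  expect_equal(aggregate_patient(f, min_nuclei = 3)$fd, 2.12)
  f2 <- data.frame(patient_id = rep("a", 4), fd = 1:4)
  expect_equal(aggregate_patient(f2, min_nuclei = 4)$fd, 2.5)
  f3 <- data.frame(patient_id = rep(c("a", "b"), c(100, 99)), x = 1)
  expect_error(aggregate_patient(f3), "b")
})

test_that("Mann-Whitney matches hand-computed exact cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney equals full labeling enumeration", {
  set.seed(31)
  for (i in 1:6) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1:100, nx + ny) # tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    got <- mann_whitney(x, y)
    expect_identical(got$method, "mann_whitney_exact")
    expect_equal(got$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  set.seed(32)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  got <- mann_whitney(x, y)
  expect_identical(got$method, "mann_whitney_normal")
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("Spearman rho and exact permutation p match oracles", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10))$statistic, 1)
  r <- spearman(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$statistic, -0.5)
  set.seed(33)
  for (n in c(4, 6, 7)) {
    x <- sample(1:50, n); y <- sample(1:50, n)
    got <- spearman(x, y)
    expect_identical(got$method, "spearman_exact")
    expect_equal(got$p_value, oracle_spearman_exact_p(x, y), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("large-sample Spearman agrees with cor.test's t approximation", {
  set.seed(34)
  x <- rnorm(15); y <- x + rnorm(15)
  got <- spearman(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Clopper-Pearson reproduces the published intervals", {
  ci2 <- clopper_pearson_ci(2, 19)
  expect_identical(round(ci2$lower, 3), 0.013)
  expect_identical(round(ci2$upper, 3), 0.331)
  expect_identical(round(ci2$lower, 4), 0.0130)
  expect_identical(round(ci2$upper, 4), 0.3314)
  ci4 <- clopper_pearson_ci(4, 19)
  expect_identical(round(ci4$lower, 4), 0.0605)
  expect_identical(round(ci4$upper, 4), 0.4557)
})

test_that("Clopper-Pearson limits equal Beta quantiles over a grid", {
  for (n in c(5, 19, 40)) {
    for (s in c(0, 1, floor(n / 2), n)) {
      ci <- clopper_pearson_ci(s, n, 0.95)
      lo <- if (s == 0) 0 else qbeta(0.025, s, n - s + 1)
      hi <- if (s == n) 1 else qbeta(0.975, s + 1, n - s)
      expect_equal(ci$lower, lo, tolerance = 1e-9)
      expect_equal(ci$upper, hi, tolerance = 1e-9)
    }
  }
  expect_error(clopper_pearson_ci(5, 4), "counts")
  expect_error(clopper_pearson_ci(1, 4, level = 1), "level")
})

test_that("exact CIs are conservative: coverage >= nominal", {
  # coverage of p = 0.1 at n = 19 over 2000 simulated binomials
  cis <- lapply(0:19, function(s) clopper_pearson_ci(s, 19))
  set.seed(35)
  draws <- rbinom(2000, 19, 0.1)
  covered <- vapply(draws, function(s) {
    ci <- cis[[s + 1]]
    ci$lower <= 0.1 && 0.1 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("Cox estimate matches grid-search partial likelihood maximization", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1, z = c(1, 0, 1, 0))
  fit <- cox_univariate(d, "z")
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1),
               time = d$time, event = d$event, x = d$z)
  expect_lt(abs(fit$coefficient - grid[which.max(ll)]), 2e-3)
})

test_that("Cox coefficient is affine-equivariant", {
  set.seed(36)
  d <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.8),
                  z = rnorm(30))
  f1 <- cox_univariate(d, "z")
  d$z2 <- 2 * d$z
  f2 <- cox_univariate(d, "z2")
  expect_equal(f2$coefficient, f1$coefficient / 2, tolerance = 1e-6)
})

test_that("Cox agrees with survival::coxph under Breslow ties", {
  set.seed(37)
  d <- data.frame(time = round(rexp(60), 1) + 0.1, # induces ties
                  event = rbinom(60, 1, 0.7), z = rnorm(60))
  fit <- cox_univariate(d, "z")
  ref <- survival::coxph(survival::Surv(time, event) ~ z, data = d,
                         ties = "breslow")
  expect_equal(fit$coefficient, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$p_value,
               summary(ref)$coefficients[1, "Pr(>|z|)"], tolerance = 1e-6)
  # stratified variant
  d$grp <- rep(0:1, 30)
  fs <- cox_stratified(d, "z", "grp")
  rs <- survival::coxph(survival::Surv(time, event) ~ z +
                          survival::strata(grp),
                        data = d, ties = "breslow")
  expect_equal(fs$coefficient, unname(coef(rs)), tolerance = 1e-6)
})

test_that("monotone likelihood is flagged, not silently diverged", {
  # perfect separation: all group-1 events precede every group-0 event
  d <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                  event = c(1, 1, 1, 1, 1, 1),
                  z = c(1, 1, 1, 0, 0, 0))
  fit <- cox_univariate(d, "z")
  expect_false(fit$converged)
})

test_that("Cox input validation", {
  d <- data.frame(time = 1:4, event = c(1, 1, 0, 0), z = 1)
  expect_error(cox_univariate(d, "z"), "constant")
  d2 <- data.frame(time = 1:4, event = c(1, 0, 0, 0), z = c(1, 0, 1, 0))
  expect_error(cox_univariate(d2, "z"), "2 events")
  # covariate constant within every stratum: no information
  d3 <- data.frame(time = c(1, 2, 3, 4), event = 1,
                   z = c(1, 1, 0, 0), s = c(1, 1, 2, 2))
  expect_error(cox_stratified(d3, "z", "s"), "information")
})

test_that("single-stratum stratified Cox reduces to the univariate fit", {
  set.seed(38)
  d <- data.frame(time = rexp(25), event = rbinom(25, 1, 0.8),
                  z = rnorm(25), s = 1)
  f1 <- cox_univariate(d, "z")
  f2 <- cox_stratified(d, "z", "s")
  expect_identical(f1$coefficient, f2$coefficient)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("statistics are invariant to patient ordering", {
  set.seed(39)
  d <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.7), z = rnorm(30))
  perm <- sample(30)
  f1 <- cox_univariate(d, "z")
  f2 <- cox_univariate(d[perm, ], "z")
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-12)
  m1 <- mann_whitney(d$z[d$event == 1], d$z[d$event == 0])
  m2 <- mann_whitney(sample(d$z[d$event == 1]), sample(d$z[d$event == 0]))
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})

test_that("cohort_report has the published table shape", {
  set.seed(40)
  npat <- 6
  feats <- do.call(rbind, lapply(seq_len(npat), function(i) {
    data.frame(patient_id = sprintf("p%02d", i),
               entropy = rnorm(5, 7.5, 0.2), fd = rnorm(5, 2.1, 0.01))
  }))
  patients <- data.frame(patient_id = sprintf("p%02d", seq_len(npat)),
                         flt3_itd = rep(0:1, each = 3),
                         leukocyte_count = rlnorm(npat, log(5), 1),
                         time = rexp(npat, 0.05), event = rbinom(npat, 1, 0.5))
  rep <- cohort_report(feats, patients, "flt3_itd", min_nuclei = 5)
  expect_identical(rep$comparison$feature,
                   c("entropy", "fd", "leukocyte_count"))
  expect_true(all(is.finite(rep$comparison$p)))
  expect_identical(rep$correlations$feature, c("entropy", "fd"))
  patients$flt3_itd <- c(0, 1, 2, 0, 1, 2)
  expect_error(cohort_report(feats, patients, "flt3_itd", min_nuclei = 5),
               "2 levels")
})

test_that("group-comparison p-values are null-calibrated", {
  # identical group distributions: Mann-Whitney p approximately uniform
  set.seed(41)
  ps <- replicate(200, {
    med <- rnorm(12)
    mann_whitney(med[1:6], med[7:12])$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
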