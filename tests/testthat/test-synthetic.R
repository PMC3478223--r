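test_that("generate_mask meets its area and connectivity contract", {
  for (shape in c("oval", "bilobed")) {
    m <- generate_mask(shape, 10000, seed = 1)
    expect_gte(sum(m), 9000)
    expect_lte(sum(m), 11000)
    expect_identical(chromatex:::count_components4(m), 1L)
  }
  expect_error(generate_mask("oval", 10), "area_px")
  expect_error(generate_mask("hexagon", 1000))
})

test_that("bilobed masks are measurably less circular than ovals", {
  mo <- generate_mask("oval", 10000, seed = 1)
  mb <- generate_mask("bilobed", 10000, seed = 1)
  ffo <- form_factor(const_nucleus(mo))
  ffb <- form_factor(const_nucleus(mb))
  expect_gt(ffo - ffb, 0.02)
})

test_that("fBm surfaces have the prescribed increment scaling", {
  fit_exponent <- function(s) {
    l <- 1:16
    v <- vapply(l, function(j) {
      mean((s[, -(1:j), drop = FALSE] - s[, 1:(256 - j), drop = FALSE])^2)
    }, numeric(1))
    unname(coef(lm(log(v) ~ log(l)))[2])
  }
  expect_lt(abs(fit_exponent(generate_fbm_surface(0.5, 256, seed = 7)) - 1.0), 0.2)
  expect_lt(abs(fit_exponent(generate_fbm_surface(0.9, 256, seed = 7)) - 1.8), 0.3)
})

test_that("fBm synthesis is deterministic and validates inputs", {
  s1 <- generate_fbm_surface(0.5, 64, seed = 7)
  s2 <- generate_fbm_surface(0.5, 64, seed = 7)
  expect_identical(s1, s2)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_error(generate_fbm_surface(0, 64), "hurst")
  expect_error(generate_fbm_surface(1, 64), "hurst")
  expect_error(generate_fbm_surface(0.5, 16), "size")
})

test_that("compose_nucleus hits the target gray statistics", {
  m <- generate_mask("oval", 3000, seed = 3)
  s <- generate_fbm_surface(0.8, max(32L, max(dim(m))), seed = 4)
  n <- compose_nucleus(m, s, 130, 9, 0, seed = 5)
  gs <- gray_stats(n)
  expect_gte(gs[["mean_gray"]], 128); expect_lte(gs[["mean_gray"]], 132)
  expect_gte(gs[["sd_gray"]], 8); expect_lte(gs[["sd_gray"]], 10)
  # background is white and masked out
  expect_true(all(n$gray[!n$mask] == 255L))
  expect_error(compose_nucleus(m, s, 120, 0), "sd_gray")
  expect_error(compose_nucleus(m, s[1:10, 1:10], 120, 5), "cover")
})

test_that("ITD-like gray targets are reproduced within +-2", {
  m <- generate_mask("bilobed", 3000, seed = 6)
  s <- generate_fbm_surface(0.7, max(32L, max(dim(m))), seed = 6)
  n <- compose_nucleus(m, s, 108, 6.3, 0.5, seed = 6)
  gs <- gray_stats(n)
  expect_lt(abs(gs[["mean_gray"]] - 108.2), 2)
  expect_lt(abs(gs[["sd_gray"]] - 6.3), 2)
})

test_that("realized gray stats are unbiased over seeds", {
  stats <- t(vapply(1:20, function(s) {
    m <- generate_mask("oval", 800, seed = s)
    srf <- generate_fbm_surface(0.75, max(32L, max(dim(m))), seed = s + 100L)
    gray_stats(compose_nucleus(m, srf, 120, 7, 1, seed = s + 200L))
  }, numeric(2)))
  expect_lt(abs(mean(stats[, 1]) - 120), 2)
  expect_lt(abs(mean(stats[, 2]) - 7), 2)
})

test_that("generate_cohort satisfies its structural invariants", {
  b <- generate_cohort(test_config(seed = 7L))
  expect_s3_class(b, "cohort_bundle")
  expect_identical(nrow(b$patients), 4L)
  expect_identical(length(b$nuclei), 12L)
  pids <- vapply(b$nuclei, function(n) n$patient_id, character(1))
  expect_true(all(pids %in% b$patients$patient_id))
  expect_true(all(table(pids) == 3L))
  # event rule: event = 1 iff death occurred within follow-up
  expect_true(all(b$patients$event %in% 0:1))
  expect_true(all(b$patients$time <= 41))
  expect_true(all(b$patients$time[b$patients$event == 0] == 41))
})

test_that("cohorts are bit-reproducible under a fixed seed", {
  b1 <- generate_cohort(test_config(seed = 9L))
  b2 <- generate_cohort(test_config(seed = 9L))
  expect_identical(b1$patients, b2$patients)
  expect_identical(lapply(b1$nuclei, `[[`, "gray"),
                   lapply(b2$nuclei, `[[`, "gray"))
  # patient streams are label-derived: growing the cohort keeps old patients
  b3 <- generate_cohort(test_config(seed = 9L, n_patients = 3L))
  expect_identical(b1$patients$leukocyte_count[1],
                   b3$patients$leukocyte_count[b3$patients$patient_id ==
                                                 b1$patients$patient_id[1]])
})

test_that("config validation rejects out-of-range parameters", {
  cfg <- test_config()
  cfg$group_params$itd$hurst <- 1.2
  expect_error(chromatex:::validate_generator_config(cfg), "hurst")
  cfg <- test_config()
  cfg$group_params$classical$sd_gray <- -1
  expect_error(chromatex:::validate_generator_config(cfg), "sd_gray")
  expect_error(generator_config(nuclei_per_patient = 0), "nuclei_per_patient")
})
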