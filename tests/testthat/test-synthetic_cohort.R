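test_that("generator is bit-reproducible under a fixed seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_gwg_cohort(cfg)
  b <- simulate_gwg_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$baselines, b$baselines)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth$participants, b$truth$participants)
  # and a different seed changes the data
  c <- simulate_gwg_cohort(small_config(seed = 12))
  expect_false(identical(a$visits, c$visits))
})

test_that("noise-free limit puts every gain exactly on exp(mu*) - 5", {
  cfg <- small_config(n = c(A = 60), seed = 3, sigma_b = 0, sigma_e = 0)
  dat <- simulate_gwg_cohort(cfg)
  bm <- match(dat$visits$participant_id, dat$baselines$participant_id)
  gain <- dat$visits$weight_kg - dat$baselines$baseline_weight_kg[bm]
  mu <- true_mean_curve(cfg, dat$visits$ga_weeks, "A",
                        dat$baselines$bmi_group[bm][1])
  # per-visit truth must respect each participant's own BMI group
  mu <- mapply(function(t, g) true_mean_curve(cfg, t, "A", g),
               dat$visits$ga_weeks, dat$baselines$bmi_group[bm])
  expect_equal(gain, exp(mu) - 5, tolerance = 1e-12)
})

test_that("residual spread around the true curve matches the configured variances", {
  cfg <- small_config(n = c(A = 2000), seed = 21)
  dat <- simulate_gwg_cohort(cfg)
  bm <- match(dat$visits$participant_id, dat$baselines$participant_id)
  y <- log(dat$visits$weight_kg - dat$baselines$baseline_weight_kg[bm] + 5)
  mu <- mapply(function(t, g) true_mean_curve(cfg, t, "A", g),
               dat$visits$ga_weeks, dat$baselines$bmi_group[bm])
  sd_obs <- sd(y - mu)
  sd_true <- sqrt(cfg$sigma_b^2 + cfg$sigma_e^2)
  expect_lt(abs(sd_obs - sd_true) / sd_true, 0.10)
})

test_that("configured marginal outcome risks are recovered at large n", {
  cfg <- small_config(n = c(A = 10000), seed = 31)
  dat <- simulate_gwg_cohort(cfg)
  p_pt <- mean(dat$outcomes$delivery_ga_weeks < 37)
  # binomial 3.5-sigma band around the configured marginal risk
  tol <- 3.5 * sqrt(0.13 * 0.87 / 10000)
  expect_lt(abs(p_pt - 0.13), tol)
  p_sb <- mean(dat$outcomes$stillbirth)
  expect_lt(abs(p_sb - 0.026), 3.5 * sqrt(0.026 * 0.974 / 10000))
})

test_that("every participant has at least one visit and valid structure", {
  cfg <- small_config(seed = 41)
  dat <- simulate_gwg_cohort(cfg)
  expect_setequal(unique(dat$visits$participant_id),
                  dat$baselines$participant_id)
  expect_true(all(dat$visits$weight_kg > 0))
  expect_true(all(dat$visits$ga_weeks > 0 & dat$visits$ga_weeks <= 43))
  expect_true(all(dat$baselines$enrol_ga_weeks < 25))
  expect_true(all(dat$outcomes$delivery_ga_weeks <= 42))
  # BMI group consistent with BMI value at the cut-offs
  expect_identical(dat$baselines$bmi_group,
                   classify_bmi(dat$baselines$bmi_kg_m2))
})

test_that("config validation rejects malformed inputs", {
  expect_error(gwg_sim_config(bmi_group_probs = c(
    underweight = 0.3, normal = 0.3, overweight = 0.3, obese = 0.3)),
    "sum to 1")
  expect_error(gwg_sim_config(sigma_b = -1), "sigma")
  expect_error(gwg_sim_config(enrol_ga = list(mean = 13, sd = 3, min = 2,
                                              max = 24)), "\\[4, 25\\)")
})

test_that("missingness injection hits the target rate and respects rate 0", {
  cfg <- small_config(n = c(A = 10000), seed = 51)
  dat <- simulate_gwg_cohort(cfg)
  # rate 0: tables unchanged
  d0 <- inject_missingness(dat, c(birth_weight_g = 0), "MCAR", seed = 1)
  expect_identical(d0$outcomes, dat$outcomes)
  # 12% target: realized fraction within the binomial 99% interval
  d1 <- inject_missingness(dat, c(birth_weight_g = 0.12), "MCAR", seed = 1)
  fr <- mean(is.na(d1$outcomes$birth_weight_g))
  expect_true(fr >= 0.10 && fr <= 0.14)
  # MAR at the same rate has the same marginal target
  d2 <- inject_missingness(dat, c(birth_weight_g = 0.12), "MAR", seed = 1)
  fr2 <- mean(is.na(d2$outcomes$birth_weight_g))
  expect_true(fr2 >= 0.10 && fr2 <= 0.14)
  # masked originals retained for imputation-quality checks
  expect_equal(nrow(d1$masked$birth_weight_g), sum(is.na(d1$outcomes$birth_weight_g)))
  expect_false(anyNA(d1$masked$birth_weight_g$value))
})

test_that("MAR masking depends on the observable driver, MCAR does not", {
  cfg <- small_config(n = c(A = 8000), seed = 61)
  dat <- simulate_gwg_cohort(cfg)
  d <- inject_missingness(dat, c(birth_weight_g = 0.2), "MAR", seed = 5)
  educ <- dat$baselines$education_years
  miss <- is.na(d$outcomes$birth_weight_g)
  # lower education -> higher masking probability
  expect_lt(mean(educ[miss]), mean(educ[!miss]))
  dm <- inject_missingness(dat, c(birth_weight_g = 0.2), "MCAR", seed = 5)
  missm <- is.na(dm$outcomes$birth_weight_g)
  expect_lt(abs(mean(educ[missm]) - mean(educ[!missm])), 0.5)
})

test_that("unknown mechanism and invalid rates error", {
  dat <- simulate_gwg_cohort(small_config(n = c(A = 50), seed = 7))
  expect_error(inject_missingness(dat, c(birth_weight_g = 0.1), "MNAR"))
  expect_error(inject_missingness(dat, c(birth_weight_g = 1.5), "MCAR"),
               "\\[0, 1\\]")
  expect_error(inject_missingness(dat, c(nonexistent = 0.1), "MCAR"),
               "not found")
})

test_that("cohort round-trips through the CSV/JSON export", {
  dat <- simulate_gwg_cohort(small_config(n = c(A = 40), seed = 9))
  dir <- withr::local_tempdir()
  write_gwg_cohort(dat, dir)
  back <- read_gwg_cohort(dir)
  expect_equal(back$visits$weight_kg, dat$visits$weight_kg)
  expect_equal(back$baselines$participant_id, dat$baselines$participant_id)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
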