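test_that("saturated 2x2 modified Poisson equals the closed-form risk ratio", {
  d <- data.frame(y = c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80)),
                  group = rep(c("G1", "G3"), each = 100))
  fit <- modified_poisson_rr(d, "y", "group")
  rr <- fit$table$rr[fit$table$group == "G1"]
  expect_equal(rr, 1.5, tolerance = 1e-8)
  expect_equal(fit$table$rr[fit$table$group == "G3"], 1)
  # crude risks and intercept-only adjusted risks agree
  expect_equal(fit$table$adj_risk_pct, fit$table$crude_risk_pct,
               tolerance = 1e-6)
})

test_that("covariates independent of the outcome leave the RR nearly unchanged", {
  set.seed(66)
  n <- 6000
  g <- sample(c("G1", "G2", "G3", "G4"), n, replace = TRUE)
  p <- c(G1 = 0.30, G2 = 0.24, G3 = 0.20, G4 = 0.16)[g]
  d <- data.frame(y = as.integer(runif(n) < p), group = g,
                  age = rnorm(n, 25, 5), height = rnorm(n, 152, 6),
                  parous = runif(n) < 0.6)
  crude <- modified_poisson_rr(d, "y", "group")
  adj <- modified_poisson_rr(d, "y", "group",
                             covariates = c("age", "height", "parous"))
  i <- crude$table$group == "G1"
  expect_lt(abs(adj$table$rr[i] - crude$table$rr[i]) / crude$table$rr[i], 0.05)
})

test_that("robust Wald intervals cover a known risk ratio near the nominal rate", {
  set.seed(77)
  reps <- 100
  n <- 5000
  true_rr <- 1.5
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    g <- sample(c("G1", "G3"), n, replace = TRUE)
    p <- ifelse(g == "G1", 0.15 * true_rr, 0.15)
    d <- data.frame(y = as.integer(runif(n) < p), group = g)
    t <- modified_poisson_rr(d, "y", "group")$table
    i <- t$group == "G1"
    cover[r] <- true_rr >= t$rr_lcl[i] && true_rr <= t$rr_ucl[i]
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("zero-event groups report undefined ratios with a diagnostic", {
  d <- data.frame(y = c(rep(0, 50), rep(1, 10), rep(0, 40)),
                  group = rep(c("G1", "G3"), each = 50))
  fit <- modified_poisson_rr(d, "y", "group")
  i <- fit$table$group == "G1"
  expect_true(is.na(fit$table$rr[i]))
  expect_match(fit$table$note[i], "zero events")
  expect_error(modified_poisson_rr(d, "y", "group", ref = "G9"), "absent")
})

test_that("marginal standardization is internally consistent", {
  set.seed(88)
  n <- 4000
  g <- sample(c("G1", "G3"), n, replace = TRUE)
  x <- rnorm(n)
  p <- pmin(exp(log(0.12) + 0.5 * (g == "G1") + 0.15 * x), 0.95)
  d <- data.frame(y = as.integer(runif(n) < p), group = g, x = x)
  fit <- modified_poisson_rr(d, "y", "group", covariates = "x")
  t <- fit$table
  # with exposure-covariate independence the RR transports: ref risk * RR
  # approximates the comparison group's standardized risk
  r3 <- t$adj_risk_pct[t$group == "G3"]
  r1 <- t$adj_risk_pct[t$group == "G1"]
  expect_lt(abs(r3 * t$rr[t$group == "G1"] - r1) / r1, 0.02)
  expect_true(all(t$adj_risk_pct >= 0 & t$adj_risk_pct <= 100))
  expect_true(all(t$adj_risk_lcl <= t$adj_risk_pct &
                    t$adj_risk_pct <= t$adj_risk_ucl))
  ar <- adjusted_risk(fit, "G1")
  expect_equal(ar$risk_pct, r1)
})

test_that("standardized risks stay inside [0, 100] across random designs", {
  set.seed(99)
  for (r in 1:25) {
    n <- 400
    g <- sample(c("G1", "G2", "G3"), n, replace = TRUE)
    x <- rnorm(n)
    p <- plogis(-1.5 + 0.4 * (g == "G1") + 0.6 * x)
    d <- data.frame(y = as.integer(runif(n) < p), group = g, x = x)
    t <- suppressWarnings(modified_poisson_rr(d, "y", "group",
                                              covariates = "x"))$table
    expect_true(all(t$adj_risk_pct >= 0 & t$adj_risk_pct <= 100))
  }
})

test_that("dose-response curve tracks the simulated risk shape", {
  set.seed(111)
  n <- 8000
  z <- rnorm(n)
  bmi <- sample(c("normal", "underweight"), n, replace = TRUE, prob = c(.7, .3))
  p <- plogis(-1.2 - 0.8 * z)          # monotone decreasing in z
  d <- data.frame(y = as.integer(runif(n) < p), z = z, bmi_group = bmi)
  dr <- gee_dose_response(d, "y", z_col = "z", bmi_col = "bmi_group")
  cv <- dr$curves[dr$curves$bmi_group == "normal" &
                    dr$curves$z >= -2 & dr$curves$z <= 2, ]
  expect_true(all(diff(cv$prob) < 0.01))      # decreasing within tolerance
  expect_lt(cv$prob[nrow(cv)], cv$prob[1])
  # null effect: flat within a Monte-Carlo band
  d0 <- d; d0$y <- as.integer(runif(n) < 0.25)
  dr0 <- gee_dose_response(d0, "y", z_col = "z", bmi_col = "bmi_group")
  cv0 <- dr0$curves[dr0$curves$bmi_group == "normal" &
                      abs(dr0$curves$z) <= 2, ]
  expect_lt(diff(range(cv0$prob)), 0.06)
  # invariant to row order
  perm <- sample(n)
  dr2 <- gee_dose_response(d[perm, ], "y", z_col = "z", bmi_col = "bmi_group")
  m <- merge(dr$curves, dr2$curves, by = c("bmi_group", "z"))
  expect_equal(m$prob.x, m$prob.y, tolerance = 1e-8)
})

test_that("baseline-characteristic associations use cohort-cluster variance", {
  set.seed(122)
  n <- 10000
  cohort <- sample(LETTERS[1:5], n, replace = TRUE)
  cat <- sample(c("ref", "shift"), n, replace = TRUE)
  z <- rnorm(n) - 0.2 * (cat == "shift")
  d <- data.frame(z = z, cat = cat, cohort = cohort)
  a <- baseline_assoc(d, characteristic = "cat")
  expect_equal(a$level, "shift")
  expect_lt(abs(a$estimate - (-0.2)), 0.05)
  # null characteristic
  d$null <- sample(c("u", "v"), n, replace = TRUE)
  a0 <- baseline_assoc(d, characteristic = "null")
  expect_lt(abs(a0$estimate), 0.05)
  # duplicating every cluster leaves the point estimate unchanged
  dd <- rbind(d, transform(d, cohort = paste0(cohort, "2")))
  a2 <- baseline_assoc(dd, characteristic = "cat")
  expect_equal(a2$estimate, a$estimate, tolerance = 1e-10)
  # single cohort falls back with a warning
  expect_warning(baseline_assoc(d[d$cohort == "A", ], characteristic = "cat"),
                 "single cohort")
})

test_that("outcome indicators implement the clinical definitions", {
  o <- data.frame(delivery_ga_weeks = c(36.9, 37, 31.9, 40),
                  birth_weight_g = c(2499, 2500, 1499, 3200),
                  newborn_centile = c(9.9, 10, 2.9, 50),
                  stillbirth = c(FALSE, TRUE, FALSE, FALSE),
                  caesarean = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(outcome_indicator(o, "preterm37"), c(1, 0, 1, 0))
  expect_equal(outcome_indicator(o, "preterm32"), c(0, 0, 1, 0))
  expect_equal(outcome_indicator(o, "lbw"), c(1, 0, 1, 0))
  expect_equal(outcome_indicator(o, "vlbw"), c(0, 0, 1, 0))
  expect_equal(outcome_indicator(o, "sga10"), c(1, 0, 1, 0))
  expect_equal(outcome_indicator(o, "sga3"), c(0, 0, 1, 0))
  expect_equal(outcome_indicator(o, "stillbirth"), c(0, 1, 0, 0))
  expect_error(outcome_indicator(o, "apgar"), "unknown outcome")
})
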