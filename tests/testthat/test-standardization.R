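test_that("total gain uses the last valid visit at or before delivery", {
  tt <- toy_tables()
  v <- validate_visits(tt$visits, tt$baselines)
  tg <- total_gwg(v, tt$baselines, tt$outcomes)
  p1 <- tg[tg$participant_id == "p1", ]
  expect_equal(p1$total_gwg_kg, 8.5)
  expect_equal(p1$ga_last_weeks, 38)
  # single visit equal to baseline -> gain 0 at that GA
  p3 <- tg[tg$participant_id == "p3", ]
  expect_equal(p3$total_gwg_kg, 0.5)
  # a visit after delivery is not a candidate
  v2 <- v
  v2$ga_weeks[v2$participant_id == "p1" & v2$ga_weeks == 38] <- 41
  tg2 <- total_gwg(v2, tt$baselines, tt$outcomes)
  expect_equal(tg2$total_gwg_kg[tg2$participant_id == "p1"], 3)
  expect_equal(tg2$ga_last_weeks[tg2$participant_id == "p1"], 20)
  # participant with no qualifying visit errors by name
  out3 <- tt$outcomes
  out3$delivery_ga_weeks[out3$participant_id == "p3"] <- 9
  expect_error(total_gwg(v, tt$baselines, out3), "p3")
})

test_that("Z-score arithmetic matches the hand oracle", {
  ch <- flat_chart(mu_log = 2.4, sd_log = 0.3)
  z <- gwg_zscore(6.8, 38, ch, "A", "normal")
  expect_equal(log(6.8 + 5), 2.46810, tolerance = 1e-5)
  expect_equal(z, 0.22700, tolerance = 1e-5)
  # gain equal to the chart median gives z = 0
  expect_equal(gwg_zscore(exp(2.4) - 5, 38, ch, "A", "normal"), 0,
               tolerance = 1e-12)
  # gain at the chart 25th percentile returns the 25% normal quantile
  p25 <- exp(2.4 + qnorm(0.25) * 0.3) - 5
  expect_equal(round(gwg_zscore(p25, 38, ch, "A", "normal"), 4), -0.6745)
  # kg-scale option standardizes against shifted-lognormal moments
  m <- exp(2.4 + 0.3^2 / 2) - 5
  zkg <- gwg_zscore(m, 38, ch, "A", "normal", scale = "kg")
  expect_equal(zkg, 0, tolerance = 1e-12)
  # outside chart support errors
  expect_error(gwg_zscore(5, 4, ch, "A", "normal"), "support")
})

test_that("quartile groups partition the line at full-precision cut-offs", {
  expect_equal(as.character(zscore_group(c(-1, 0, 0.5, 1))),
               c("G1", "G2", "G3", "G4"))
  q <- qnorm(c(0.25, 0.75))
  expect_equal(as.character(zscore_group(c(q[1], q[1] + 1e-9))), c("G1", "G2"))
  expect_equal(as.character(zscore_group(c(q[2], q[2] + 1e-9))), c("G3", "G4"))
  # every finite z maps to exactly one group
  z <- runif(1000, -6, 6)
  expect_false(anyNA(zscore_group(z)))
  # simulated standard normal occupies each group at ~25%
  set.seed(12)
  tab <- table(zscore_group(rnorm(50000)))
  expect_true(all(abs(tab / 50000 - 0.25) < 0.01))
})

test_that("IOM recommended gain reproduces the printed-constant arithmetic", {
  expect_equal(iom_recommended("normal", 40), 2 + 0.42 * 27)
  expect_equal(iom_recommended("normal", 40), 13.34)
  expect_equal(iom_recommended("obese", 37), 0.5 + 0.22 * 24)
  expect_equal(iom_recommended("obese", 37), 5.78)
  # at exactly 13 weeks only the first-trimester constant remains
  expect_equal(iom_recommended(c("underweight", "normal", "overweight",
                                 "obese"), 13), c(2, 2, 0.5, 0.5))
  expect_error(iom_recommended("normal", 12), "13 weeks")
  expect_error(iom_recommended("slim", 20), "unknown")
})

test_that("adequacy ratio is scale-equivariant and categorizes totals", {
  expect_equal(iom_adequacy_ratio(13.34, 13.34)$ratio, 100)
  expect_equal(iom_adequacy_ratio(6.67, 13.34)$ratio, 50)
  expect_equal(iom_adequacy_ratio(0, 10)$ratio, 0)
  r1 <- iom_adequacy_ratio(4, 10)$ratio
  expect_equal(iom_adequacy_ratio(8, 10)$ratio, 2 * r1)
  cat4 <- iom_adequacy_ratio(c(10, 13, 19), rep(13.34, 3), rep("normal", 3))
  expect_equal(cat4$iom_category, c("below", "adequate", "above"))
  expect_error(iom_adequacy_ratio(5, 0), "positive")
})

test_that("external-standard plugin standardizes and self-agrees with the chart", {
  ch <- flat_chart(mu_log = 2.4, sd_log = 0.3)
  own <- list(fun = function(ga) list(mean = rep(2.4, length(ga)),
                                      sd = rep(0.3, length(ga))),
              support = c(8, 42), scale = "log")
  expect_equal(external_standard_zscore(6.8, 38, own),
               gwg_zscore(6.8, 38, ch, "A", "normal"), tolerance = 1e-12)
  # kg-scale synthetic standard: gain at the standard mean gives z = 0
  std <- list(fun = function(ga) list(mean = rep(13.2, length(ga)),
                                      sd = rep(3, length(ga))),
              support = c(14, 40))
  expect_equal(external_standard_zscore(13.2, 40, std), 0)
  # monotone in the gain
  expect_lt(external_standard_zscore(10, 40, std),
            external_standard_zscore(14, 40, std))
  # GA outside the declared support errors
  expect_error(external_standard_zscore(13.2, 41, std), "support")
})

test_that("trimester gains pick the right windows and go missing cleanly", {
  tt <- toy_tables()
  v <- validate_visits(tt$visits, tt$baselines)
  tw <- trimester_gwg(v, tt$baselines)
  p1 <- tw[tw$participant_id == "p1", ]
  expect_equal(p1$t2_gwg_kg, 3)    # 20-week visit
  expect_equal(p1$t3_gwg_kg, 8.5)  # 38-week visit
  # p3 has only a 10-week visit: both trimester gains missing
  p3 <- tw[tw$participant_id == "p3", ]
  expect_true(is.na(p3$t2_gwg_kg) && is.na(p3$t3_gwg_kg))
  # example mirroring typical second/third-trimester gains
  v2 <- data.frame(participant_id = "q", cohort = "A",
                   ga_weeks = c(20, 38), weight_kg = c(53.4, 57.1))
  b2 <- data.frame(participant_id = "q", baseline_weight_kg = 50)
  tw2 <- trimester_gwg(validate_visits(v2, b2), b2)
  expect_equal(c(tw2$t2_gwg_kg, tw2$t3_gwg_kg), c(3.4, 7.1))
})

test_that("zscore_table assembles the export columns", {
  cfg <- small_config(n = c(A = 200), seed = 15)
  dat <- simulate_gwg_cohort(cfg)
  dat$visits <- validate_visits(dat$visits, dat$baselines)
  fit <- gwg_reference(dat$visits, dat$baselines)
  ch <- reference_chart(fit)
  zt <- zscore_table(dat$visits, dat$baselines, dat$outcomes, ch)
  expect_named(zt, c("participant_id", "cohort", "bmi_group", "ga_last_weeks",
                     "total_gwg_kg", "z", "percentile", "group"))
  expect_true(all(zt$percentile > 0 & zt$percentile < 100))
  expect_identical(as.character(zt$group), as.character(zscore_group(zt$z)))
})
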