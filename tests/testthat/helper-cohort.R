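# Small simulation configs and hand-built tables shared across tests.

small_config <- function(n = c(A = 300, B = 250), seed = 101, ...) {
  gwg_sim_config(n_per_cohort = n, seed = seed, ...)
}

# a minimal hand-built trio of tables: 3 participants, simple round numbers
toy_tables <- function() {
  baselines <- data.frame(
    participant_id = c("p1", "p2", "p3"),
    cohort = "A",
    maternal_age_years = c(24, 30, 21),
    enrol_ga_weeks = c(12, 14, 10),
    height_cm = c(152, 160, 148),
    baseline_weight_kg = c(50, 62, 45),
    bmi_kg_m2 = c(21.6, 24.2, 20.5),
    bmi_group = "normal",
    parous = c(TRUE, FALSE, TRUE),
    prior_preterm = c(FALSE, FALSE, TRUE),
    prior_stillbirth = FALSE,
    education_years = c(8, 12, 5),
    chronic_htn = FALSE, diabetes = FALSE,
    stringsAsFactors = FALSE)
  visits <- data.frame(
    participant_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    cohort = "A",
    ga_weeks = c(12, 20, 38, 14, 30, 10),
    weight_kg = c(50, 53, 58.5, 62, 66, 45.5),
    stringsAsFactors = FALSE)
  outcomes <- data.frame(
    participant_id = c("p1", "p2", "p3"),
    delivery_ga_weeks = c(39.5, 38, 40),
    birth_weight_g = c(3000, 2400, 3100),
    stillbirth = FALSE,
    newborn_centile = c(40, 8, 55),
    caesarean = c(FALSE, TRUE, FALSE),
    spontaneous_labour = c(TRUE, FALSE, TRUE),
    infant_sex = c("female", "male", "female"),
    stringsAsFactors = FALSE)
  list(visits = visits, baselines = baselines, outcomes = outcomes)
}

# flat synthetic chart with constant mu_log / sd_log, for exact arithmetic
flat_chart <- function(mu_log = 2.4, sd_log = 0.3, cohort = "A",
                       bmi_group = "normal", weeks = 8:42) {
  pc <- sapply(c(3, 5, 10, 25, 50, 75, 90, 95, 97), function(p) {
    exp(mu_log + qnorm(p / 100) * sd_log) - 5
  })
  out <- data.frame(cohort = cohort, bmi_group = bmi_group, ga_week = weeks,
                    mu_log = mu_log, sd_log = sd_log,
                    matrix(rep(pc, each = length(weeks)), nrow = length(weeks),
                           dimnames = list(NULL, paste0("p", c(3, 5, 10, 25,
                                                               50, 75, 90,
                                                               95, 97)))),
                    stringsAsFactors = FALSE)
  class(out) <- c("gwg_chart", "data.frame")
  out
}
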