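#' Simulation configuration for synthetic pregnancy cohorts
#'
#' Assembles and validates the full parameter set that drives
#' [simulate_gwg_cohort()]. The defaults emulate a five-cohort consortium of
#' South-Asian / Sub-Saharan-African antenatal cohorts: cohort sizes summing
#' to 15,286 pregnancies, a BMI mix dominated by normal and underweight
#' groups, enrolment before 25 weeks, a median of 4 weight measurements at
#' 4-6 week intervals, and a true mean gain curve on the shifted-log scale
#' (`y = ln(gain + 5)`) calibrated so the median total gain at 39 weeks is
#' about 7 kg for a normal-BMI participant in the central cohort.
#'
#' @param n_per_cohort named positive integer vector: participants per cohort;
#'   names are the cohort labels.
#' @param bmi_group_probs probability vector over the four baseline BMI groups
#'   `underweight, normal, overweight, obese` (must sum to 1 within 1e-12).
#' @param enrol_ga list `mean, sd, min, max`: truncated-normal distribution of
#'   enrolment gestational age in weeks, support within `[4, 25)`.
#' @param visit_schedule list with `count_probs` (named probability vector
#'   over total weight-measurement counts, names are integer counts) and
#'   `gap_min`/`gap_max` (uniform inter-visit gap in weeks).
#' @param curve true mean-curve parameters on the transformed scale; see
#'   [true_mean_curve()]. Defaults to a quadratic in `(t - 8)` with small
#'   cohort intercept shifts and BMI intercept/slope shifts, so the truth lies
#'   (very nearly) inside the family fitted by [gwg_reference()].
#' @param sigma_b between-woman SD of the random intercept (transformed
#'   scale, must be >= 0).
#' @param sigma_e residual SD (transformed scale, must be >= 0).
#' @param outcome_params nested list of outcome-generating parameters; see
#'   Details.
#' @param newborn_standard synthetic birth-weight-for-GA standard used to
#'   compute newborn centiles: list `mean_40` (mean at 40 weeks, g),
#'   `slope_per_week` (g per week below 40) and `sd` (g).
#' @param missing_rates named vector of per-column missingness probabilities
#'   used by [inject_missingness()] (defaults: 12% birth weight, 1.5% prior
#'   preterm birth).
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#'
#' @details `outcome_params` components:
#' \describe{
#'   \item{preterm}{`baseline` marginal risk of delivery <37 weeks and
#'     `log_rr_per_z`, the log risk ratio per unit of the latent Z
#'     (`b_i/sigma_b`). Risks follow `p0 * exp(beta*Z - beta^2/2)` so that
#'     `baseline` is the marginal risk. Alternatively `group_rr`, a length-4
#'     vector of risk ratios per latent Z quartile group (G1..G4, G3 = 1).}
#'   \item{birthweight}{`mean`, `sd` (g), `z_effect` (g per unit of the
#'     latent gain Z), `ga_effect` (g per week of delivery GA relative to
#'     39.2). Or, for direct control of low-birth-weight risk, `lbw_baseline`
#'     plus `lbw_group_rr` (length 4, per latent gain-Z quartile): the group
#'     mean is then set so `P(bw < 2500 | group)` equals the target risk.}
#'   \item{stillbirth}{`baseline` and `log_rr_per_z` as for preterm.}
#'   \item{caesarean, spontaneous_labour}{`baseline` marginal probabilities.}
#' }
#'
#' @return an object of class `gwg_sim_config` (a validated list).
#' @export
gwg_sim_config <- function(
    n_per_cohort = c(cohort_A = 2786, cohort_B = 2025, cohort_C = 3456,
                     cohort_D = 6004, cohort_E = 1015),
    bmi_group_probs = c(underweight = 3536, normal = 9178,
                        overweight = 2048, obese = 524) / 15286,
    enrol_ga = list(mean = 13.4, sd = 3.4, min = 4, max = 24.9),
    visit_schedule = list(
      count_probs = c(`2` = 0.08, `3` = 0.22, `4` = 0.30, `5` = 0.22,
                      `6` = 0.12, `7` = 0.06),
      gap_min = 4, gap_max = 6),
    curve = NULL,
    sigma_b = 0.10,
    sigma_e = 0.08,
    outcome_params = list(
      preterm = list(baseline = 0.13, log_rr_per_z = -0.15, group_rr = NULL),
      birthweight = list(mean = 2800, sd = 350, z_effect = 150,
                         ga_effect = 90, lbw_baseline = NULL,
                         lbw_group_rr = NULL),
      stillbirth = list(baseline = 0.026, log_rr_per_z = 0),
      caesarean = list(baseline = 0.266),
      spontaneous_labour = list(baseline = 0.785)),
    newborn_standard = list(mean_40 = 3300, slope_per_week = 130, sd = 400),
    missing_rates = c(birth_weight_g = 0.12, prior_preterm = 0.015),
    seed = 1L) {

  if (is.null(names(n_per_cohort)) || any(names(n_per_cohort) == "")) {
    stop("'n_per_cohort' must be a named vector (names are cohort labels)")
  }
  if (any(n_per_cohort < 1)) stop("'n_per_cohort' entries must be positive")
  if (is.null(curve)) curve <- default_curve_params(names(n_per_cohort))

  cfg <- list(n_per_cohort = n_per_cohort,
              cohorts = names(n_per_cohort),
              bmi_group_probs = bmi_group_probs,
              enrol_ga = enrol_ga,
              visit_schedule = visit_schedule,
              curve = curve,
              sigma_b = sigma_b, sigma_e = sigma_e,
              outcome_params = outcome_params,
              newborn_standard = newborn_standard,
              missing_rates = missing_rates,
              seed = as.integer(seed))
  class(cfg) <- "gwg_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.gwg_sim_config <- function(x, ...) {
  cat("Synthetic GWG cohort configuration\n")
  cat("  cohorts:", paste(sprintf("%s (n=%d)", x$cohorts, x$n_per_cohort),
                          collapse = ", "), "\n")
  cat("  BMI mix:", paste(sprintf("%s %.1f%%", names(x$bmi_group_probs),
                                  100 * x$bmi_group_probs), collapse = ", "), "\n")
  cat(sprintf("  sigma_b = %.3f, sigma_e = %.3f (transformed scale)\n",
              x$sigma_b, x$sigma_e))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

bmi_levels <- function() c("underweight", "normal", "overweight", "obese")

default_curve_params <- function(cohorts) {
  # quadratic on (t - 8), transformed scale; intercept ln(5) means zero mean
  # gain at 8 weeks; calibrated so exp(mu*(39)) - 5 = 7 kg at baseline
  c2 <- 2e-4
  c1 <- (log(12 / 5) - c2 * 31^2) / 31
  shift <- rep(0, length(cohorts))
  names(shift) <- cohorts
  # mild cohort heterogeneity (about -0.9 kg to +0.3 kg at 39 weeks)
  preset <- c(-0.078, -0.043, 0.025, -0.025, 0)
  shift[] <- rep_len(preset, length(cohorts))
  list(t0 = 8,
       base = c(c0 = log(5), c1 = c1, c2 = c2),
       cohort_shift = shift,
       bmi_shift = c(underweight = -0.02, normal = 0,
                     overweight = 0.01, obese = 0.02),
       bmi_slope = c(underweight = 8e-4, normal = 0,
                     overweight = -1.2e-3, obese = -1.8e-3))
}

#' True mean transformed-gain curve of a simulation configuration
#'
#' Evaluates `mu*(t)`, the generating mean of `ln(gain + 5)` at gestational
#' age `t`, for a given cohort and BMI group.
#'
#' @param config a `gwg_sim_config`.
#' @param t gestational age in weeks (vectorized).
#' @param cohort,bmi_group scalars identifying the stratum.
#' @return numeric vector, transformed (log) scale.
#' @export
true_mean_curve <- function(config, t, cohort, bmi_group) {
  cv <- config$curve
  if (!cohort %in% names(cv$cohort_shift)) stop("unknown cohort: ", cohort)
  if (!bmi_group %in% names(cv$bmi_shift)) stop("unknown BMI group: ", bmi_group)
  u <- t - cv$t0
  cv$base[["c0"]] + cv$cohort_shift[[cohort]] + cv$bmi_shift[[bmi_group]] +
    (cv$base[["c1"]] + cv$bmi_slope[[bmi_group]]) * u + cv$base[["c2"]] * u^2
}

validate_sim_config <- function(cfg) {
  p <- cfg$bmi_group_probs
  if (length(p) != 4L || !identical(names(p), bmi_levels())) {
    stop("'bmi_group_probs' must be named ",
         paste(bmi_levels(), collapse = ", "))
  }
  if (abs(sum(p) - 1) > 1e-12) stop("'bmi_group_probs' must sum to 1 (1e-12)")
  if (any(p < 0)) stop("'bmi_group_probs' must be non-negative")
  cp <- cfg$visit_schedule$count_probs
  if (abs(sum(cp) - 1) > 1e-12) {
    stop("visit count probabilities must sum to 1 (1e-12)")
  }
  if (cfg$sigma_b < 0 || cfg$sigma_e < 0) stop("sigma_b and sigma_e must be >= 0")
  eg <- cfg$enrol_ga
  if (eg$min < 4 || eg$max >= 25) {
    stop("enrolment GA support must lie within [4, 25) weeks")
  }
  # true curve must be non-decreasing on [8, 42] in every stratum
  grid <- seq(8, 42, by = 0.5)
  for (co in cfg$cohorts) {
    for (g in bmi_levels()) {
      mu <- true_mean_curve(cfg, grid, co, g)
      if (any(diff(mu) < -1e-12)) {
        stop("true mean curve decreasing on [8, 42] for ", co, "/", g)
      }
    }
  }
  for (nm in c("preterm", "birthweight", "stillbirth", "caesarean",
               "spontaneous_labour")) {
    if (is.null(cfg$outcome_params[[nm]])) {
      stop("outcome_params$", nm, " missing")
    }
  }
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1)) {
    stop("missing_rates must lie in [0, 1]")
  }
  invisible(cfg)
}
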