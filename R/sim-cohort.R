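#' Simulate a multi-cohort longitudinal pregnancy dataset
#'
#' Generates antenatal visit weights, participant baselines and delivery
#' outcomes with the statistical structure assumed by the reference-chart
#' analysis, together with the ground truth needed for recovery tests.
#'
#' Weights are generated as `w_ij = w_i0 + g(t_ij)` where the transformed gain
#' `y_ij = ln(g + 5) = mu*(t_ij) + b_i + e_ij`, with `b_i ~ N(0, sigma_b^2)` a
#' participant random intercept and `e_ij ~ N(0, sigma_e^2)` residual noise.
#' Because `g = exp(y) - 5 > -5` for any finite `y`, the shifted-log transform
#' is invertible on every generated visit by construction; a bounded
#' retry-then-fail guard protects the physical invariant `weight > 0`.
#'
#' Outcome generation uses two latent standardized scores stored in the truth:
#' `z_intercept = b_i / sigma_b` drives gestational-duration outcomes (preterm
#' birth, stillbirth), avoiding circularity with visit truncation at delivery;
#' `z_gain = (y_last - mu*(t_last)) / sqrt(sigma_b^2 + sigma_e^2)` — the true
#' standardized total gain, i.e. the exposure the analysis pipeline estimates —
#' drives birth weight.
#'
#' @param config a [gwg_sim_config()].
#' @return A list of class `gwg_cohort` with elements `visits`, `baselines`,
#'   `outcomes` (data frames; column names documented in the README) and
#'   `truth` (class `gwg_truth`: the config plus per-participant latents).
#' @seealso [inject_missingness()], [write_gwg_cohort()]
#' @export
simulate_gwg_cohort <- function(config) {
  stopifnot(inherits(config, "gwg_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  N <- sum(config$n_per_cohort)
  cohort <- rep(config$cohorts, config$n_per_cohort)
  pid <- sprintf("%s_%06d", cohort,
                 unlist(lapply(config$n_per_cohort, seq_len), use.names = FALSE))

  ## --- baseline characteristics -------------------------------------------
  grp <- sample(bmi_levels(), N, replace = TRUE, prob = config$bmi_group_probs)
  bmi <- draw_bmi_within_group(grp)
  grp <- classify_bmi(bmi)   # consistent with value at the cut-offs
  height <- rtruncnorm(N, 152.5, 6, 135, 180)
  weight0 <- bmi * (height / 100)^2
  age <- round(rtruncnorm(N, 24.8, 5.2, 15, 45))
  parous <- stats::runif(N) < 0.605
  prior_pt <- parous & (stats::runif(N) < 0.112)
  prior_sb <- parous & (stats::runif(N) < 0.076)
  educ <- pmin(pmax(round(stats::rnorm(N, 9.5, 4.2)), 0), 18)
  chtn <- stats::runif(N) < 0.019
  diab <- stats::runif(N) < 0.004
  eg <- config$enrol_ga
  enrol <- rtruncnorm(N, eg$mean, eg$sd, eg$min, eg$max)

  ## --- latent trajectory level and visit schedule -------------------------
  b <- stats::rnorm(N, 0, config$sigma_b)
  z_int <- if (config$sigma_b > 0) b / config$sigma_b else rep(0, N)
  vs <- config$visit_schedule
  counts <- as.integer(sample(names(vs$count_probs), N, replace = TRUE,
                              prob = vs$count_probs))
  idx <- rep(seq_len(N), counts - 1L)
  gaps <- stats::runif(length(idx), vs$gap_min, vs$gap_max)
  follow_ga <- enrol[idx] + stats::ave(gaps, idx, FUN = cumsum)

  ## --- delivery gestational age -------------------------------------------
  op <- config$outcome_params
  ga_term <- rtruncnorm(N, 39.2, 1.0, 37, 42)
  p_pt <- latent_risk(op$preterm, z_int)
  preterm <- stats::runif(N) < p_pt
  # truncated-exponential shortfall below 37 weeks; ~10% of preterm <32 wk
  e <- stats::qexp(stats::runif(N) * stats::pexp(13, rate = 1 / 2.2),
                   rate = 1 / 2.2)
  delivery <- ifelse(preterm, 37 - e, ga_term)
  delivery <- pmax(delivery, enrol + 1)  # delivery strictly after enrolment
  p_sb <- latent_risk(op$stillbirth, z_int)
  stillbirth <- stats::runif(N) < p_sb

  ## --- visit weights -------------------------------------------------------
  keep <- follow_ga < delivery[idx]
  v_pid <- c(seq_len(N), idx[keep])
  v_ga <- c(enrol, follow_ga[keep])
  ord <- order(v_pid, v_ga)
  v_pid <- v_pid[ord]; v_ga <- v_ga[ord]
  mu <- mu_star_vec(config, v_ga, cohort[v_pid], grp[v_pid])
  sd_tot <- sqrt(config$sigma_b^2 + config$sigma_e^2)
  for (try in 1:10) {
    eps <- stats::rnorm(length(v_ga), 0, config$sigma_e)
    y <- mu + b[v_pid] + eps
    w <- weight0[v_pid] + exp(y) - 5
    bad <- w <= 0
    if (!any(bad)) break
    if (try == 10L) {
      stop("could not generate positive visit weights after 10 retries; ",
           "participants: ",
           paste(unique(pid[v_pid[bad]]), collapse = ", "))
    }
  }
  visits <- data.frame(participant_id = pid[v_pid],
                       cohort = cohort[v_pid],
                       ga_weeks = v_ga,
                       weight_kg = w,
                       stringsAsFactors = FALSE)

  last_row <- cumsum(tabulate(v_pid, N))           # rows sorted by pid then ga
  y_last <- y[last_row]
  t_last <- v_ga[last_row]
  z_gain <- if (sd_tot > 0) {
    (y_last - mu_star_vec(config, t_last, cohort, grp)) / sd_tot
  } else rep(0, N)

  ## --- birth weight and derived outcomes ----------------------------------
  bw_par <- op$birthweight
  if (!is.null(bw_par$lbw_group_rr)) {
    rr <- bw_par$lbw_group_rr
    if (length(rr) != 4L) stop("lbw_group_rr must have length 4 (G1..G4)")
    g_idx <- as.integer(zscore_group(z_gain))
    p_g <- pmin(bw_par$lbw_baseline * rr[g_idx], 0.99)
    mu_bw <- 2500 - bw_par$sd * stats::qnorm(p_g)
    bw <- stats::rnorm(N, mu_bw, bw_par$sd)
  } else {
    bw <- bw_par$mean + bw_par$z_effect * z_gain +
      bw_par$ga_effect * (delivery - 39.2) + stats::rnorm(N, 0, bw_par$sd)
  }
  bw <- round(pmax(bw, 300))
  std <- config$newborn_standard
  centile <- 100 * stats::pnorm(
    (bw - (std$mean_40 - std$slope_per_week * (40 - delivery))) / std$sd)
  centile <- pmin(pmax(centile, 1e-4), 100 - 1e-4)
  caes <- stats::runif(N) < op$caesarean$baseline
  spont <- stats::runif(N) < op$spontaneous_labour$baseline
  sex <- sample(c("female", "male"), N, replace = TRUE)

  baselines <- data.frame(
    participant_id = pid, cohort = cohort,
    maternal_age_years = age, enrol_ga_weeks = enrol,
    height_cm = height, baseline_weight_kg = weight0,
    bmi_kg_m2 = bmi, bmi_group = grp,
    parous = parous, prior_preterm = prior_pt, prior_stillbirth = prior_sb,
    education_years = educ, chronic_htn = chtn, diabetes = diab,
    stringsAsFactors = FALSE)
  outcomes <- data.frame(
    participant_id = pid,
    delivery_ga_weeks = delivery,
    birth_weight_g = bw,
    stillbirth = stillbirth,
    newborn_centile = centile,
    caesarean = caes,
    spontaneous_labour = spont,
    infant_sex = sex,
    stringsAsFactors = FALSE)
  truth <- structure(
    list(config = config,
         participants = data.frame(participant_id = pid, b = b,
                                   z_intercept = z_int, z_gain = z_gain,
                                   stringsAsFactors = FALSE)),
    class = "gwg_truth")
  structure(list(visits = visits, baselines = baselines, outcomes = outcomes,
                 truth = truth),
            class = "gwg_cohort")
}

#' @export
print.gwg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic GWG cohort: %d participants, %d visits, %d cohorts\n",
              nrow(x$baselines), nrow(x$visits),
              length(unique(x$baselines$cohort))))
  invisible(x)
}

latent_risk <- function(par, z) {
  if (!is.null(par$group_rr)) {
    rr <- par$group_rr
    if (length(rr) != 4L) stop("group_rr must have length 4 (G1..G4)")
    p <- par$baseline * rr[as.integer(zscore_group(z))]
  } else {
    beta <- par$log_rr_per_z
    # exp(-beta^2/2) offsets E[exp(beta*Z)] so 'baseline' is the marginal risk
    p <- par$baseline * exp(beta * z - beta^2 / 2)
  }
  pmin(p, 0.99)
}

mu_star_vec <- function(config, t, cohort, grp) {
  cv <- config$curve
  u <- t - cv$t0
  cv$base[["c0"]] + unname(cv$cohort_shift[cohort]) +
    unname(cv$bmi_shift[grp]) +
    (cv$base[["c1"]] + unname(cv$bmi_slope[grp])) * u + cv$base[["c2"]] * u^2
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_bmi_within_group <- function(grp) {
  n <- length(grp)
  out <- numeric(n)
  spec <- list(underweight = c(17.3, 0.9, 15, 18.45),
               normal = c(21.0, 1.8, 18.5, 24.85),
               overweight = c(27.0, 1.4, 25, 29.85),
               obese = c(32.0, 2.0, 30, 45))
  for (g in names(spec)) {
    i <- grp == g
    s <- spec[[g]]
    out[i] <- rtruncnorm(sum(i), s[1], s[2], s[3], s[4])
  }
  out
}

#' Classify baseline BMI into the four standard groups
#'
#' Cut-offs: underweight <18.5, normal 18.5-24.9, overweight 25-29.9,
#' obese >=30 kg/m^2.
#'
#' @param bmi numeric vector of BMI values (kg/m^2).
#' @return character vector over `underweight, normal, overweight, obese`.
#' @export
classify_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = bmi_levels()) |> as.character()
}

#' Inject missing values into a synthetic cohort
#'
#' Masks entries of the generated tables at the configured per-column rates,
#' either completely at random (MCAR) or dependent on observed covariates
#' (MAR-on-observables: the masking probability increases with lower maternal
#' education, calibrated so the marginal rate equals the target). Original
#' values are retained in the returned object so that imputation quality can
#' be checked against truth.
#'
#' @param cohort a `gwg_cohort` (or any list with `visits`, `baselines`,
#'   `outcomes` data frames).
#' @param rates named numeric vector: target missingness probability per
#'   column (column is looked up across the three tables).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed integer seed.
#' @return the input list with masked entries set to `NA` and an added element
#'   `masked`: per column, a data frame of `participant_id` and the original
#'   value.
#' @export
inject_missingness <- function(cohort, rates = cohort$truth$config$missing_rates,
                               mechanism = c("MCAR", "MAR"), seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  tables <- c("outcomes", "baselines", "visits")
  masked <- list()
  for (col in names(rates)) {
    rate <- rates[[col]]
    tb <- NULL
    for (t in tables) if (col %in% names(cohort[[t]])) { tb <- t; break }
    if (is.null(tb)) stop("column '", col, "' not found in any table")
    n <- nrow(cohort[[tb]])
    if (rate == 0) next
    if (mechanism == "MCAR") {
      p <- rep(rate, n)
    } else {
      educ <- cohort$baselines$education_years[
        match(cohort[[tb]]$participant_id, cohort$baselines$participant_id)]
      wgt <- exp(-0.12 * (educ - mean(educ)))
      p <- rate * wgt / mean(wgt)
      for (i in 1:10) {  # re-calibrate after clipping so the marginal holds
        p <- pmin(pmax(p, 0), 1)
        m <- mean(p)
        if (abs(m - rate) < 1e-12 || m == 0) break
        p <- p * rate / m
      }
    }
    hit <- stats::runif(n) < p
    masked[[col]] <- data.frame(
      participant_id = cohort[[tb]]$participant_id[hit],
      value = cohort[[tb]][[col]][hit], stringsAsFactors = FALSE)
    cohort[[tb]][[col]][hit] <- NA
  }
  cohort$masked <- masked
  cohort
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `visits.csv`, `baseline.csv`, `outcomes.csv` and a `truth.json`
#' sidecar (generating parameters and per-participant latents) into `dir`.
#'
#' @param cohort a `gwg_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_gwg_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("visits.csv", "baseline.csv", "outcomes.csv",
                            "truth.json"))
  utils::write.csv(cohort$visits, paths[1], row.names = FALSE)
  utils::write.csv(cohort$baselines, paths[2], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  tr <- cohort$truth
  tr$config$curve$cohort_shift <- as.list(tr$config$curve$cohort_shift)
  jsonlite::write_json(list(config = unclass(tr$config),
                            participants = tr$participants),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a synthetic cohort from delimited text files
#'
#' @param dir directory containing `visits.csv`, `baseline.csv`,
#'   `outcomes.csv` as written by [write_gwg_cohort()].
#' @return a list with `visits`, `baselines`, `outcomes` data frames.
#' @export
read_gwg_cohort <- function(dir) {
  list(visits = utils::read.csv(file.path(dir, "visits.csv")),
       baselines = utils::read.csv(file.path(dir, "baseline.csv")),
       outcomes = utils::read.csv(file.path(dir, "outcomes.csv")))
}
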