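#' Total gestational weight gain per pregnancy
#'
#' Total gain is the last valid weight at or before delivery minus the
#' baseline weight; its gestational age is the week at which the Z-score is
#' standardized.
#'
#' @param visits validated visits (must carry a `valid` column).
#' @param baselines baseline table.
#' @param outcomes outcome table (supplies `delivery_ga_weeks`).
#' @return data frame `participant_id, cohort, total_gwg_kg, ga_last_weeks`;
#'   participants with no valid visit at or before delivery raise an error
#'   naming them.
#' @export
total_gwg <- function(visits, baselines, outcomes) {
  if (!"valid" %in% names(visits)) {
    stop("visits must carry validity flags; run validate_visits() first")
  }
  outcomes <- outcomes[!duplicated(outcomes$participant_id), , drop = FALSE]
  del <- outcomes$delivery_ga_weeks[
    match(visits$participant_id, outcomes$participant_id)]
  v <- visits[visits$valid & !is.na(del) & visits$ga_weeks <= del, ,
              drop = FALSE]
  v <- v[order(v$participant_id, v$ga_weeks), , drop = FALSE]
  last <- !duplicated(v$participant_id, fromLast = TRUE)
  v <- v[last, , drop = FALSE]
  ids <- unique(visits$participant_id)
  miss <- setdiff(ids, v$participant_id)
  if (length(miss)) {
    stop("no valid weight measurement at or before delivery for: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
  }
  bm <- match(v$participant_id, baselines$participant_id)
  data.frame(participant_id = v$participant_id,
             cohort = v$cohort,
             total_gwg_kg = v$weight_kg - baselines$baseline_weight_kg[bm],
             ga_last_weeks = v$ga_weeks,
             stringsAsFactors = FALSE)
}

#' Weight-gain-for-gestational-age Z-score
#'
#' Standardizes a pregnancy's total gain against the reference chart row for
#' its cohort, BMI group and gestational week at last measurement:
#' on the default transformed scale,
#' `z = (ln(gain + 5) - mu_log(t)) / sd_log`. A kg-scale option standardizes
#' the raw gain against the mean and SD of the implied shifted-lognormal
#' distribution instead.
#'
#' @param total_gwg_kg total gain in kg.
#' @param ga_last_weeks gestational age (weeks) at the last measurement.
#' @param chart a `gwg_chart`.
#' @param cohort,bmi_group stratum identifiers (vectorized).
#' @param scale `"log"` (default) or `"kg"`.
#' @param lookup week lookup rule, see [chart_lookup()].
#' @return numeric Z-scores.
#' @export
gwg_zscore <- function(total_gwg_kg, ga_last_weeks, chart, cohort, bmi_group,
                       scale = c("log", "kg"),
                       lookup = c("nearest", "interpolate")) {
  scale <- match.arg(scale)
  row <- chart_lookup(chart, cohort, bmi_group, ga_last_weeks,
                      lookup = match.arg(lookup))
  if (scale == "log") {
    (transform_gwg(total_gwg_kg) - row$mu_log) / row$sd_log
  } else {
    # moments of gain = exp(Y) - 5 with Y ~ N(mu, sd^2)
    m <- exp(row$mu_log + row$sd_log^2 / 2) - 5
    s <- sqrt((exp(row$sd_log^2) - 1) * exp(2 * row$mu_log + row$sd_log^2))
    (total_gwg_kg - m) / s
  }
}

#' Z-score quartile groups
#'
#' Partitions Z-scores into the four groups corresponding to the quartiles of
#' the standard normal: G1 `z <= qnorm(0.25)`, G2 `qnorm(0.25) < z <= 0`,
#' G3 `0 < z <= qnorm(0.75)`, G4 `z > qnorm(0.75)`. Cut-offs are applied at
#' full precision (+/-0.6744898); they are conventionally displayed rounded to
#' -0.67 / 0.67.
#'
#' @param z finite numeric Z-scores.
#' @return factor with levels `G1, G2, G3, G4` (labels carry the percentile
#'   reading).
#' @export
zscore_group <- function(z) {
  q25 <- stats::qnorm(0.25)
  q75 <- stats::qnorm(0.75)
  cut(z, breaks = c(-Inf, q25, 0, q75, Inf),
      labels = c("G1", "G2", "G3", "G4"), right = TRUE)
}

#' Full Z-score results table
#'
#' Convenience wrapper combining [total_gwg()], [gwg_zscore()] and
#' [zscore_group()] into the per-pregnancy standardized-exposure table used by
#' the outcome models.
#'
#' @inheritParams total_gwg
#' @param chart a `gwg_chart`.
#' @param scale,lookup passed to [gwg_zscore()].
#' @return data frame `participant_id, cohort, bmi_group, ga_last_weeks,
#'   total_gwg_kg, z, percentile, group`.
#' @export
zscore_table <- function(visits, baselines, outcomes, chart,
                         scale = "log", lookup = "nearest") {
  tg <- total_gwg(visits, baselines, outcomes)
  bm <- match(tg$participant_id, baselines$participant_id)
  tg$bmi_group <- baselines$bmi_group[bm]
  tg$z <- gwg_zscore(tg$total_gwg_kg, tg$ga_last_weeks, chart,
                     tg$cohort, tg$bmi_group, scale = scale, lookup = lookup)
  tg$percentile <- 100 * stats::pnorm(tg$z)
  tg$group <- zscore_group(tg$z)
  tg[, c("participant_id", "cohort", "bmi_group", "ga_last_weeks",
         "total_gwg_kg", "z", "percentile", "group")]
}

iom_rates <- c(underweight = 0.51, normal = 0.42,
               overweight = 0.28, obese = 0.22)
iom_t1 <- c(underweight = 2, normal = 2, overweight = 0.5, obese = 0.5)
iom_total_range <- list(underweight = c(12.5, 18), normal = c(11.5, 16),
                        overweight = c(7, 11.5), obese = c(5, 9))

#' IOM-recommended total weight gain at a given gestational age
#'
#' Recommended gain = first-trimester gain (2 kg for underweight/normal BMI,
#' 0.5 kg for overweight/obese) plus the BMI-specific second/third-trimester
#' weekly rate (0.51 / 0.42 / 0.28 / 0.22 kg per week for underweight, normal,
#' overweight, obese) times `(ga - 13)` weeks.
#'
#' @param bmi_group character vector over the four BMI groups.
#' @param ga_final_weeks gestational age at the final weight (>= 13 weeks).
#' @return recommended gain in kg.
#' @export
iom_recommended <- function(bmi_group, ga_final_weeks) {
  if (any(ga_final_weeks < 13)) {
    stop("IOM recommendation undefined before 13 weeks ",
         "(first-trimester-only gain not modelled)")
  }
  if (!all(bmi_group %in% bmi_levels())) {
    stop("unknown BMI group: ",
         paste(setdiff(bmi_group, bmi_levels()), collapse = ", "))
  }
  unname(iom_t1[bmi_group] + iom_rates[bmi_group] * (ga_final_weeks - 13))
}

#' IOM adequacy ratio
#'
#' Ratio of observed to recommended gain times 100 (percent). When
#' `bmi_group` is supplied, the observed total gain is also categorized
#' against the IOM total-gain adequate range for that group (12.5-18 /
#' 11.5-16 / 7-11.5 / 5-9 kg).
#'
#' @param observed_kg observed total gain.
#' @param recommended_kg recommended gain (must be positive), e.g. from
#'   [iom_recommended()].
#' @param bmi_group optional BMI group for the adequacy category.
#' @return data frame `observed_gwg_kg, recommended_gwg_kg, ratio` and, when
#'   `bmi_group` is given, `iom_category` in `below, adequate, above`.
#' @export
iom_adequacy_ratio <- function(observed_kg, recommended_kg, bmi_group = NULL) {
  if (any(recommended_kg <= 0)) stop("recommended gain must be positive")
  out <- data.frame(observed_gwg_kg = observed_kg,
                    recommended_gwg_kg = recommended_kg,
                    ratio = 100 * observed_kg / recommended_kg)
  if (!is.null(bmi_group)) {
    rng <- do.call(rbind, iom_total_range[bmi_group])
    out$iom_category <- ifelse(observed_kg < rng[, 1], "below",
                               ifelse(observed_kg > rng[, 2], "above",
                                      "adequate"))
  }
  out
}

#' Standardize total gain against an external published standard
#'
#' Plugin interface for external weight-gain-for-gestational-age standards
#' (e.g. international standards built on normal-BMI populations). The
#' standard supplies its own mean/SD by gestational week, its GA support and
#' its scale; the published coefficients of any external standard are *not*
#' embedded in this package.
#'
#' @param total_gwg_kg total gain in kg.
#' @param ga_weeks gestational age at the measurement being standardized.
#' @param standard a list with elements:
#'   \describe{
#'     \item{fun}{function `ga -> list(mean, sd)`, or instead a `table` data
#'       frame with columns `ga_week, mean, sd` (nearest-week lookup).}
#'     \item{support}{length-2 numeric GA support; requests outside error.}
#'     \item{scale}{`"kg"` (default; mean/sd are on the kg gain scale) or
#'       `"log"` (mean/sd on the `ln(gain + 5)` scale).}
#'   }
#' @return numeric Z-scores.
#' @export
external_standard_zscore <- function(total_gwg_kg, ga_weeks, standard) {
  sup <- standard$support
  if (is.null(sup)) stop("standard must declare its GA 'support'")
  if (any(ga_weeks < sup[1] | ga_weeks > sup[2])) {
    stop("gestational age outside the standard's support [",
         sup[1], ", ", sup[2], "] weeks")
  }
  if (!is.null(standard$fun)) {
    ms <- standard$fun(ga_weeks)
    m <- ms$mean; s <- ms$sd
  } else if (!is.null(standard$table)) {
    i <- match(round(ga_weeks), standard$table$ga_week)
    if (anyNA(i)) stop("standard table has no row for requested week(s)")
    m <- standard$table$mean[i]; s <- standard$table$sd[i]
  } else stop("standard must supply 'fun' or 'table'")
  scale <- if (is.null(standard$scale)) "kg" else standard$scale
  x <- if (scale == "log") transform_gwg(total_gwg_kg) else total_gwg_kg
  (x - m) / s
}

#' Second- and third-trimester weight gain
#'
#' Second-trimester gain is the last valid weight in \[14, 28) weeks minus
#' baseline; third-trimester gain the last valid weight at >= 28 weeks minus
#' baseline (standard obstetric trimester windows). `NA` when no qualifying
#' visit exists.
#'
#' @param visits validated visits.
#' @param baselines baseline table.
#' @return data frame `participant_id, t2_gwg_kg, t3_gwg_kg`.
#' @export
trimester_gwg <- function(visits, baselines) {
  if (!"valid" %in% names(visits)) {
    stop("visits must carry validity flags; run validate_visits() first")
  }
  ids <- unique(visits$participant_id)
  v <- visits[visits$valid, , drop = FALSE]
  v <- v[order(v$participant_id, v$ga_weeks), , drop = FALSE]
  bw <- baselines$baseline_weight_kg[match(ids, baselines$participant_id)]
  last_in <- function(lo, hi) {
    sel <- v[v$ga_weeks >= lo & v$ga_weeks < hi, , drop = FALSE]
    sel <- sel[!duplicated(sel$participant_id, fromLast = TRUE), , drop = FALSE]
    sel$weight_kg[match(ids, sel$participant_id)]
  }
  data.frame(participant_id = ids,
             t2_gwg_kg = last_in(14, 28) - bw,
             t3_gwg_kg = last_in(28, Inf) - bw,
             stringsAsFactors = FALSE)
}
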