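chart_percentiles <- c(3, 5, 10, 25, 50, 75, 90, 95, 97)

#' Build weight-gain-for-gestational-age reference charts
#'
#' Tabulates, for every (cohort, BMI group, integer gestational week 8-42),
#' the fitted mean of the transformed gain (`mu_log`), the chart SD
#' (`sd_log = sqrt(sigma_b^2 + sigma_e^2)`, constant across weeks under the
#' homoscedastic mixed model) and back-transformed percentiles in kg:
#' `p = exp(mu_log + z_p * sd_log) - 5` with `z_p` the standard-normal
#' quantile. By construction `p50 = exp(mu_log) - 5` and standardizing any
#' chart percentile returns the matching normal quantile exactly.
#'
#' @param fit a [gwg_reference()] fit.
#' @param ga_grid integer weeks of the chart (must lie within 8-42).
#' @param cohorts,bmi_groups strata to tabulate (defaults: all fitted).
#' @return A data frame of class `gwg_chart` with columns `cohort, bmi_group,
#'   ga_week, mu_log, sd_log, p3, p5, p10, p25, p50, p75, p90, p95, p97`.
#' @export
reference_chart <- function(fit, ga_grid = 8:42, cohorts = fit$cohorts,
                            bmi_groups = NULL) {
  stopifnot(inherits(fit, "gwg_reference"))
  if (any(ga_grid < 8 | ga_grid > 42)) {
    stop("chart support is 8-42 weeks; refusing extrapolation")
  }
  rows <- list()
  for (co in cohorts) {
    f <- fit$fits[[co]]
    if (is.null(f)) stop("no fitted model for cohort ", co)
    if (!f$converged) stop("cohort ", co, " fit did not converge")
    groups <- if (is.null(bmi_groups)) f$bmi_levels else bmi_groups
    sd_log <- sqrt(f$sigma_b^2 + f$sigma_e^2)
    for (g in groups) {
      mu <- predict_mu_log(f, ga_grid, rep(g, length(ga_grid)))
      pc <- vapply(chart_percentiles, function(p) {
        inverse_transform_gwg(mu + stats::qnorm(p / 100) * sd_log)
      }, numeric(length(ga_grid)))
      colnames(pc) <- paste0("p", chart_percentiles)
      rows[[paste(co, g)]] <- data.frame(
        cohort = co, bmi_group = g, ga_week = ga_grid,
        mu_log = mu, sd_log = sd_log, pc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gwg_chart", "data.frame")
  out
}

#' Look up a chart row
#'
#' Returns the chart row(s) for given strata and gestational ages, using
#' nearest-integer-week lookup by default (charts are published per week) or
#' linear interpolation of `mu_log` between adjacent weeks.
#'
#' @param chart a `gwg_chart`.
#' @param cohort,bmi_group,ga_weeks vectors (recycled to common length).
#' @param lookup `"nearest"` or `"interpolate"`.
#' @return data frame with `mu_log` and `sd_log` for each request.
#' @export
chart_lookup <- function(chart, cohort, bmi_group, ga_weeks,
                         lookup = c("nearest", "interpolate")) {
  lookup <- match.arg(lookup)
  n <- max(length(cohort), length(bmi_group), length(ga_weeks))
  cohort <- rep_len(cohort, n); bmi_group <- rep_len(bmi_group, n)
  ga_weeks <- rep_len(ga_weeks, n)
  lo <- min(chart$ga_week); hi <- max(chart$ga_week)
  if (any(ga_weeks < lo - 0.5 | ga_weeks > hi + 0.5)) {
    stop("gestational age outside chart support [", lo, ", ", hi, "] weeks")
  }
  key <- paste(chart$cohort, chart$bmi_group, chart$ga_week)
  if (lookup == "nearest") {
    wk <- pmin(pmax(round(ga_weeks), lo), hi)
    i <- match(paste(cohort, bmi_group, wk), key)
    if (anyNA(i)) stop("no chart row for stratum: ",
                       paste(unique(paste(cohort, bmi_group)[is.na(i)]),
                             collapse = "; "))
    data.frame(mu_log = chart$mu_log[i], sd_log = chart$sd_log[i])
  } else {
    w0 <- pmin(pmax(floor(ga_weeks), lo), hi)
    w1 <- pmin(w0 + 1, hi)
    fr <- pmin(pmax(ga_weeks - w0, 0), 1)
    i0 <- match(paste(cohort, bmi_group, w0), key)
    i1 <- match(paste(cohort, bmi_group, w1), key)
    if (anyNA(i0) || anyNA(i1)) stop("no chart row for requested stratum")
    data.frame(mu_log = (1 - fr) * chart$mu_log[i0] + fr * chart$mu_log[i1],
               sd_log = (1 - fr) * chart$sd_log[i0] + fr * chart$sd_log[i1])
  }
}

#' Write a reference chart to CSV
#'
#' @param chart a `gwg_chart`.
#' @param file output path.
#' @param digits decimal places for the human-readable export (kg columns);
#'   `NULL` writes full precision (machine export).
#' @return invisibly, the (possibly rounded) table written.
#' @export
write_gwg_chart <- function(chart, file, digits = NULL) {
  out <- as.data.frame(chart)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "ga_week"
    out[num] <- lapply(out[num], round, digits = digits)
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
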