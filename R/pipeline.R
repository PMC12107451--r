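#' Run the full gestational-weight-gain analysis pipeline
#'
#' End-to-end orchestration: visit validation and eligibility filtering;
#' selection of the term-livebirth reference subpopulation; per-cohort
#' mixed-model reference charts; per-pregnancy Z-scores and quartile groups;
#' multiple imputation of incomplete covariates/outcomes; BMI-stratified
#' modified-Poisson risk-ratio models per outcome; and Rubin's-rules pooling
#' of log risk ratios and log risks across imputations. With complete input
#' data the pooling is degenerate (between-imputation variance 0) and the
#' results equal a single fit.
#'
#' @param visits,baselines,outcomes the three input tables (see
#'   [simulate_gwg_cohort()] for the column contract).
#' @param outcome_names outcomes to model (see [outcome_indicator()]).
#' @param covariates adjustment covariates; continuous ones are splined.
#' @param m imputations (used only when missing values are present).
#' @param iterations chained-equation sweeps.
#' @param by_cohort also rerun the outcome models separately per cohort.
#' @param exclude_prior_preterm also rerun among participants without a
#'   previous preterm birth.
#' @param min_stratum_n strata smaller than this are skipped with a note.
#' @param seed seed for the imputation engine.
#' @return An object of class `gwg_analysis`: flows, the `gwg_reference` fit,
#'   the chart, the Z-score table, pooled `risk_tables[[outcome]][[stratum]]`
#'   data frames, and any sensitivity reruns.
#' @export
run_gwg_analysis <- function(visits, baselines, outcomes,
                             outcome_names = primary_outcomes(),
                             covariates = c("maternal_age_years",
                                            "enrol_ga_weeks", "height_cm",
                                            "bmi_kg_m2", "parous",
                                            "prior_preterm"),
                             m = 50, iterations = 5,
                             by_cohort = FALSE,
                             exclude_prior_preterm = FALSE,
                             min_stratum_n = 50, seed = 1L) {
  visits <- validate_visits(visits, baselines)
  flow_study <- select_study_population(visits, baselines, outcomes)
  ids <- flow_study$participants
  v <- visits[visits$participant_id %in% ids, , drop = FALSE]
  b <- baselines[baselines$participant_id %in% ids, , drop = FALSE]
  o <- flow_study$outcomes
  flow_ref <- select_reference_subpopulation(flow_study, v, o)

  fit <- gwg_reference(v, b, participants = flow_ref$participants)
  chart <- reference_chart(fit)
  zt <- zscore_table(v, b, o, chart)

  tab <- merge(zt, b, by = c("participant_id", "cohort", "bmi_group"))
  tab <- merge(tab, o, by = "participant_id")

  impute_vars <- intersect(
    c(covariates, "education_years", "prior_stillbirth", "chronic_htn",
      "diabetes", "delivery_ga_weeks", "ga_last_weeks", "total_gwg_kg", "z",
      "spontaneous_labour", "caesarean", "stillbirth", "birth_weight_g",
      "newborn_centile", "infant_sex"),
    names(tab))
  has_missing <- any(vapply(tab[impute_vars], anyNA, logical(1)))
  copies <- if (has_missing && m >= 2) {
    imp <- impute_chained(tab, impute_vars, m = m, iterations = iterations,
                          seed = seed)
    imp$imputations
  } else {
    imp <- NULL
    list(tab)
  }

  analyze <- function(copies, label = "overall") {
    res <- list()
    for (oc in outcome_names) {
      res[[oc]] <- list()
      for (g in intersect(bmi_levels(), unique(tab$bmi_group))) {
        fits <- lapply(copies, function(d) {
          d$group <- zscore_group(d$z)      # refresh group from (imputed) z
          d$.out <- outcome_indicator(d, oc)
          d <- d[d$bmi_group == g & !is.na(d$.out), , drop = FALSE]
          if (nrow(d) < min_stratum_n ||
              length(unique(d$group)) < 2 || !"G3" %in% d$group) {
            return(NULL)
          }
          modified_poisson_rr(d, ".out", "group", covariates = covariates)
        })
        fits <- Filter(Negate(is.null), fits)
        res[[oc]][[g]] <- if (length(fits)) pool_risk_tables(fits) else NULL
      }
    }
    res
  }

  risk_tables <- analyze(copies)
  sensitivity <- list()
  if (exclude_prior_preterm) {
    sub <- lapply(copies, function(d) {
      d[!is.na(d$prior_preterm) & !d$prior_preterm, , drop = FALSE]
    })
    sensitivity$no_prior_preterm <-
      list(n = nrow(sub[[1]]), risk_tables = analyze(sub))
  }
  if (by_cohort) {
    sensitivity$by_cohort <- lapply(
      stats::setNames(nm = sort(unique(tab$cohort))), function(co) {
        sub <- lapply(copies, function(d) d[d$cohort == co, , drop = FALSE])
        list(n = nrow(sub[[1]]), risk_tables = analyze(sub))
      })
  }

  structure(list(flow_study = flow_study, flow_reference = flow_ref,
                 fit = fit, chart = chart, zscores = zt,
                 risk_tables = risk_tables, imputation = imp,
                 m = length(copies), covariates = covariates,
                 sensitivity = sensitivity),
            class = "gwg_analysis")
}

#' Pool modified-Poisson risk tables across imputations
#'
#' Applies Rubin's rules to the log risk ratios and log adjusted risks of a
#' list of [modified_poisson_rr()] fits (one per completed data set). With a
#' single fit the table is returned with its own confidence intervals
#' (pooling degenerate).
#'
#' @param fits list of `gwg_rr` objects sharing the same groups.
#' @return data frame, one row per group: `events, N` (averaged over copies),
#'   pooled `adj_risk_pct` with CI, pooled `rr` with CI.
#' @export
pool_risk_tables <- function(fits) {
  stopifnot(length(fits) >= 1)
  groups <- fits[[1]]$table$group
  ref <- fits[[1]]$ref
  z <- stats::qnorm(0.975)
  out <- do.call(rbind, lapply(groups, function(g) {
    rows <- lapply(fits, function(f) f$table[f$table$group == g, ])
    ev <- mean(vapply(rows, `[[`, numeric(1), "events"))
    N <- mean(vapply(rows, `[[`, numeric(1), "N"))
    risks <- vapply(rows, `[[`, numeric(1), "adj_risk_pct")
    r_se <- vapply(rows, function(r) {
      (log(r$adj_risk_ucl) - log(r$adj_risk_lcl)) / (2 * z)
    }, numeric(1))
    if (any(!is.finite(log(risks))) || any(!is.finite(r_se))) {
      risk <- mean(risks); rci <- c(NA_real_, NA_real_)
    } else if (length(fits) >= 2) {
      pr <- rubin_pool(log(risks), r_se^2)
      risk <- exp(pr$estimate); rci <- exp(pr$ci)
    } else {
      risk <- risks; rci <- c(rows[[1]]$adj_risk_lcl, rows[[1]]$adj_risk_ucl)
    }
    if (g == ref) {
      rr <- 1; rrci <- c(1, 1)
    } else {
      lrr <- vapply(rows, function(r) log(r$rr), numeric(1))
      lse <- vapply(rows, function(r) {
        (log(r$rr_ucl) - log(r$rr_lcl)) / (2 * z)
      }, numeric(1))
      if (anyNA(lrr)) {
        rr <- NA_real_; rrci <- c(NA_real_, NA_real_)
      } else if (length(fits) >= 2) {
        pl <- rubin_pool(lrr, lse^2)
        rr <- exp(pl$estimate); rrci <- exp(pl$ci)
      } else {
        rr <- exp(lrr); rrci <- c(rows[[1]]$rr_lcl, rows[[1]]$rr_ucl)
      }
    }
    data.frame(group = g, events = ev, N = N,
               adj_risk_pct = risk, adj_risk_lcl = rci[1],
               adj_risk_ucl = rci[2],
               rr = rr, rr_lcl = rrci[1], rr_ucl = rrci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.gwg_analysis <- function(x, ...) {
  cat("GWG analysis pipeline\n")
  cat(sprintf("  study population: %d; reference subpopulation: %d\n",
              length(x$flow_study$participants),
              length(x$flow_reference$participants)))
  cat(sprintf("  analyses on %d completed data set(s)\n", x$m))
  for (oc in names(x$risk_tables)) {
    cat("  outcome:", oc, "\n")
    for (g in names(x$risk_tables[[oc]])) {
      t <- x$risk_tables[[oc]][[g]]
      if (is.null(t)) next
      cat("   ", g, "\n")
      for (i in seq_len(nrow(t))) {
        cat(sprintf("      %-3s %7.0f/%-7.0f adj %5.1f%% (%4.1f, %4.1f)  RR %s\n",
                    t$group[i], t$events[i], t$N[i], t$adj_risk_pct[i],
                    t$adj_risk_lcl[i], t$adj_risk_ucl[i],
                    if (is.na(t$rr[i])) "NA" else
                      sprintf("%.2f (%.2f, %.2f)", t$rr[i], t$rr_lcl[i],
                              t$rr_ucl[i])))
      }
    }
  }
  invisible(x)
}

#' Export pooled risk tables as CSV
#'
#' One row per outcome x BMI stratum x Z-score group.
#'
#' @param analysis a `gwg_analysis`.
#' @param file output CSV path.
#' @return invisibly, the exported data frame.
#' @export
write_risk_tables <- function(analysis, file) {
  rows <- list()
  for (oc in names(analysis$risk_tables)) {
    for (g in names(analysis$risk_tables[[oc]])) {
      t <- analysis$risk_tables[[oc]][[g]]
      if (is.null(t)) next
      rows[[paste(oc, g)]] <- cbind(outcome = oc, bmi_group = g, t)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
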