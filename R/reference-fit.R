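#' Shifted-log transform of gestational weight gain
#'
#' `y = ln(gwg + 5)`: a constant of +5 kg removes negative gains (weight loss
#' down to -5 kg) before the natural-log transform chosen to minimise skewness
#' of the gain distribution.
#'
#' @param gwg_kg weight gain in kg (visit weight minus baseline weight).
#' @return transformed gain (unitless, log scale).
#' @export
transform_gwg <- function(gwg_kg) {
  bad <- which(!is.na(gwg_kg) & gwg_kg <= -5)
  if (length(bad)) {
    stop("gestational weight gain <= -5 kg at position(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": shifted-log transform undefined")
  }
  log(gwg_kg + 5)
}

#' @rdname transform_gwg
#' @param y transformed gain.
#' @export
inverse_transform_gwg <- function(y) exp(y) - 5

#' Fit the longitudinal reference model of gestational weight gain
#'
#' Fits, separately for each cohort, a linear mixed-effects model of the
#' transformed gain `y = ln(gain + 5)` on a restricted quadratic spline in
#' gestational age (cohort-specific knots at the 5th, 35th, 65th and 95th
#' percentiles of visit gestational ages), BMI-group main effects and a
#' BMI-group-by-linear-gestational-age interaction, with a participant-level
#' random intercept. Estimation is by REML (unbiased variance components,
#' which set the chart SD). Fit it on the reference subpopulation — term
#' livebirths with early baseline weight — so the chart describes
#' uncomplicated gain.
#'
#' @param visits validated visit records (invalid visits are dropped); only
#'   rows whose `participant_id` is in `participants` are used when that
#'   argument is supplied.
#' @param baselines participant baseline table (supplies `baseline_weight_kg`
#'   and `bmi_group`).
#' @param participants optional character vector restricting the fit (e.g. the
#'   reference subpopulation from [select_reference_subpopulation()]).
#' @param knot_probs percentiles (percent) for gestational-age knots.
#' @param reml logical; REML (default) or ML.
#' @return An object of class `gwg_reference`: per-cohort fits (fixed-effect
#'   coefficients, `sigma_b`, `sigma_e`, knot set, convergence flag) plus the
#'   model frame summary. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' cfg <- gwg_sim_config(n_per_cohort = c(A = 300), seed = 42)
#' dat <- simulate_gwg_cohort(cfg)
#' dat$visits <- validate_visits(dat$visits, dat$baselines)
#' fit <- gwg_reference(dat$visits, dat$baselines)
#' chart <- reference_chart(fit)
#' head(chart)
#' @export
gwg_reference <- function(visits, baselines, participants = NULL,
                          knot_probs = c(5, 35, 65, 95), reml = TRUE) {
  if (!"valid" %in% names(visits)) visits <- validate_visits(visits, baselines)
  v <- visits[visits$valid, , drop = FALSE]
  if (!is.null(participants)) {
    v <- v[v$participant_id %in% participants, , drop = FALSE]
  }
  bm <- match(v$participant_id, baselines$participant_id)
  obs <- data.frame(participant_id = v$participant_id,
                    cohort = v$cohort,
                    ga_weeks = v$ga_weeks,
                    gwg_kg = v$weight_kg - baselines$baseline_weight_kg[bm],
                    bmi_group = factor(baselines$bmi_group[bm],
                                       levels = bmi_levels()),
                    stringsAsFactors = FALSE)
  obs$y <- transform_gwg(obs$gwg_kg)
  cohorts <- sort(unique(obs$cohort))
  fits <- lapply(cohorts, function(co) {
    fit_reference_one(obs[obs$cohort == co, , drop = FALSE], co,
                      knot_probs, reml)
  })
  names(fits) <- cohorts
  structure(list(fits = fits, cohorts = cohorts, knot_probs = knot_probs,
                 reml = reml, n_obs = nrow(obs),
                 n_participants = length(unique(obs$participant_id)),
                 call = match.call()),
            class = "gwg_reference")
}

fit_reference_one <- function(obs, cohort, knot_probs, reml) {
  obs$bmi_group <- droplevels(obs$bmi_group)
  if (nlevels(obs$bmi_group) < length(bmi_levels())) {
    warning("cohort ", cohort, ": BMI group(s) absent from data; ",
            "their effects are dropped")
  }
  knots <- percentile_knots(obs$ga_weeks, probs = knot_probs)
  B <- rqs_basis(obs$ga_weeks, knots)
  colnames(B) <- c("ga", paste0("ga_rqs", seq_len(ncol(B) - 1L)))
  dat <- cbind(obs, as.data.frame(B))
  fx <- paste(c(colnames(B),
                if (nlevels(dat$bmi_group) > 1L) c("bmi_group", "bmi_group:ga")),
              collapse = " + ")
  fixed_formula <- stats::as.formula(paste("y ~", fx))
  fixed_rhs <- paste("~", fx)

  # a perfect fixed-effect fit (zero-noise data) cannot be handled by the
  # mixed-model machinery; detect it and return the degenerate fit directly
  lm0 <- stats::lm(fixed_formula, data = dat)
  if (stats::sd(stats::residuals(lm0)) < 1e-8) {
    return(list(cohort = cohort, coef = stats::coef(lm0),
                sigma_b = 0, sigma_e = 0, knots = knots,
                bmi_levels = levels(dat$bmi_group), fixed_rhs = fixed_rhs,
                converged = TRUE, degenerate = TRUE,
                n_obs = nrow(dat),
                n_participants = length(unique(dat$participant_id)),
                ga_range = range(dat$ga_weeks)))
  }

  form <- stats::update(fixed_formula, . ~ . + (1 | participant_id))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  mod <- lme4::lmer(form, data = dat, REML = reml, control = ctrl)
  conv <- length(mod@optinfo$conv$lme4$messages) == 0L
  if (!conv) {
    warning("cohort ", cohort, ": convergence messages: ",
            paste(mod@optinfo$conv$lme4$messages, collapse = "; "))
  }
  vc <- as.data.frame(lme4::VarCorr(mod))
  list(cohort = cohort,
       coef = lme4::fixef(mod),
       sigma_b = vc$sdcor[vc$grp == "participant_id"],
       sigma_e = vc$sdcor[vc$grp == "Residual"],
       knots = knots,
       bmi_levels = levels(dat$bmi_group), fixed_rhs = fixed_rhs,
       converged = conv, degenerate = FALSE,
       n_obs = nrow(dat),
       n_participants = length(unique(dat$participant_id)),
       ga_range = range(dat$ga_weeks),
       model = mod)
}

predict_mu_log <- function(fit_one, ga, bmi_group) {
  B <- rqs_basis(ga, fit_one$knots)
  colnames(B) <- c("ga", paste0("ga_rqs", seq_len(ncol(B) - 1L)))
  g <- factor(bmi_group, levels = fit_one$bmi_levels)
  if (anyNA(g)) stop("BMI group not present in fitted model: ",
                     paste(unique(bmi_group[is.na(factor(bmi_group,
                       levels = fit_one$bmi_levels))]), collapse = ", "))
  df <- data.frame(as.data.frame(B), bmi_group = g)
  X <- stats::model.matrix(stats::as.formula(fit_one$fixed_rhs), df)
  co <- fit_one$coef
  if (!all(names(co) %in% colnames(X))) {
    stop("internal: coefficient/design mismatch: ",
         paste(setdiff(names(co), colnames(X)), collapse = ", "))
  }
  drop(X[, names(co), drop = FALSE] %*% co)
}

#' @export
print.gwg_reference <- function(x, ...) {
  cat("Weight-gain-for-gestational-age reference model",
      sprintf("(%s)\n", if (x$reml) "REML" else "ML"))
  cat(sprintf("  %d observations on %d participants, %d cohort(s)\n",
              x$n_obs, x$n_participants, length(x$cohorts)))
  for (f in x$fits) {
    cat(sprintf("  %-12s sigma_b = %.4f  sigma_e = %.4f  sd_chart = %.4f%s\n",
                f$cohort, f$sigma_b, f$sigma_e,
                sqrt(f$sigma_b^2 + f$sigma_e^2),
                if (!f$converged) "  [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' @export
summary.gwg_reference <- function(object, ...) {
  out <- lapply(object$fits, function(f) {
    list(cohort = f$cohort, coefficients = f$coef, sigma_b = f$sigma_b,
         sigma_e = f$sigma_e, knots = as.numeric(f$knots),
         converged = f$converged, n_obs = f$n_obs,
         n_participants = f$n_participants)
  })
  structure(out, class = "summary.gwg_reference")
}

#' @export
print.summary.gwg_reference <- function(x, ...) {
  for (f in x) {
    cat("Cohort", f$cohort, "\n")
    cat("  knots (GA weeks):", paste(signif(f$knots, 5), collapse = ", "), "\n")
    cat(sprintf("  sigma_b = %.5f  sigma_e = %.5f  (n = %d obs / %d women)\n",
                f$sigma_b, f$sigma_e, f$n_obs, f$n_participants))
    print(round(f$coefficients, 5))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.gwg_reference <- function(object, ...) lapply(object$fits, `[[`, "coef")

#' Predict mean transformed gain (or median gain in kg) from a reference fit
#'
#' @param object a `gwg_reference`.
#' @param newdata data frame with columns `cohort`, `bmi_group`, `ga_weeks`.
#' @param type `"mu_log"` for the fixed-effect mean on the transformed scale,
#'   `"gwg_kg"` for the back-transformed median gain `exp(mu) - 5`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.gwg_reference <- function(object, newdata,
                                  type = c("mu_log", "gwg_kg"), ...) {
  type <- match.arg(type)
  if (any(newdata$ga_weeks < 8 | newdata$ga_weeks > 42)) {
    stop("prediction refused outside the chart support of 8-42 weeks")
  }
  out <- numeric(nrow(newdata))
  for (co in unique(newdata$cohort)) {
    f <- object$fits[[co]]
    if (is.null(f)) stop("no fitted model for cohort ", co)
    i <- newdata$cohort == co
    out[i] <- predict_mu_log(f, newdata$ga_weeks[i], newdata$bmi_group[i])
  }
  if (type == "gwg_kg") inverse_transform_gwg(out) else out
}

#' @export
fitted.gwg_reference <- function(object, ...) {
  unlist(lapply(object$fits, function(f) {
    if (f$degenerate) return(NULL)
    stats::fitted(f$model)
  }), use.names = FALSE)
}

#' Residuals of a reference fit
#'
#' @param object a `gwg_reference`.
#' @param type `"conditional"` (includes the predicted random intercept) or
#'   `"marginal"` (fixed-effect residuals).
#' @param ... unused.
#' @export
residuals.gwg_reference <- function(object,
                                    type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  unlist(lapply(object$fits, function(f) {
    if (f$degenerate) return(NULL)
    if (type == "conditional") stats::residuals(f$model)
    else f$model@resp$y - drop(lme4::getME(f$model, "X") %*% f$coef)
  }), use.names = FALSE)
}

#' Simulate transformed-gain observations from a fitted reference model
#'
#' Draws new response vectors for the observed design (new random intercepts
#' and residuals at the fitted variance components).
#'
#' @param object a `gwg_reference`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns per cohort fit, stacked over
#'   cohorts in the fit's observation order.
#' @export
simulate.gwg_reference <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(object$fits, function(f) {
    if (f$degenerate) stop("cannot simulate from a degenerate (zero-noise) fit")
    stats::simulate(f$model, nsim = nsim, use.u = FALSE)
  })
  do.call(rbind, sims)
}

#' Plot reference percentile curves
#'
#' Draws the back-transformed percentile fan (3rd-97th) of weight gain by
#' gestational age for one cohort and BMI group.
#'
#' @param x a `gwg_reference`.
#' @param cohort,bmi_group stratum to plot (defaults: first cohort, normal).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gwg_reference <- function(x, cohort = x$cohorts[1],
                               bmi_group = "normal", ...) {
  ch <- reference_chart(x, cohorts = cohort, bmi_groups = bmi_group)
  pc <- c("p3", "p5", "p10", "p25", "p50", "p75", "p90", "p95", "p97")
  graphics::matplot(ch$ga_week, as.matrix(ch[, pc]), type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(pc), "Zissou 1"),
                    xlab = "Gestational age (weeks)",
                    ylab = "Weight gain (kg)",
                    main = sprintf("GWG reference percentiles: %s, %s BMI",
                                   cohort, bmi_group), ...)
  graphics::legend("topleft", legend = pc, lty = 1, bty = "n", cex = 0.8,
                   col = grDevices::hcl.colors(length(pc), "Zissou 1"))
  invisible(ch)
}
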