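#' Outcome definitions
#'
#' Maps an outcome name to its binary indicator over the outcome table.
#' Available outcomes: `preterm37` (<37 weeks), `preterm32` (<32 weeks),
#' `lbw` (<2500 g), `vlbw` (<1500 g), `sga10` (newborn centile <10),
#' `sga3` (<3), `stillbirth`, `caesarean`.
#'
#' @param outcomes outcome table.
#' @param name outcome name.
#' @return integer 0/1 vector (NA where the defining field is missing).
#' @export
outcome_indicator <- function(outcomes, name) {
  switch(name,
    preterm37  = as.integer(outcomes$delivery_ga_weeks < 37),
    preterm32  = as.integer(outcomes$delivery_ga_weeks < 32),
    lbw        = as.integer(outcomes$birth_weight_g < 2500),
    vlbw       = as.integer(outcomes$birth_weight_g < 1500),
    sga10      = as.integer(outcomes$newborn_centile < 10),
    sga3       = as.integer(outcomes$newborn_centile < 3),
    stillbirth = as.integer(outcomes$stillbirth),
    caesarean  = as.integer(outcomes$caesarean),
    stop("unknown outcome: ", name))
}

primary_outcomes <- function() c("preterm37", "lbw", "sga10", "sga3")

add_covariate_splines <- function(data, covariates) {
  # continuous covariates enter through restricted quadratic splines with
  # three equally spaced knots; binary/factor covariates enter as-is
  terms <- character(0)
  for (cv in covariates) {
    x <- data[[cv]]
    if (length(unique(x)) < 2L) next   # constant in this stratum: no information
    if (is.numeric(x) && length(unique(x)) > 6L) {
      kn <- equally_spaced_knots(x, k = 3)
      B <- rqs_basis(x, kn)
      nm <- c(cv, paste0(cv, "_rqs", seq_len(ncol(B) - 1L)))
      colnames(B) <- nm
      data[nm] <- as.data.frame(B)[nm]
      terms <- c(terms, nm)
    } else {
      terms <- c(terms, cv)
    }
  }
  list(data = data, terms = terms)
}

#' Modified Poisson risk-ratio regression
#'
#' Fits a log-link Poisson working model to a binary outcome and reports risk
#' ratios with sandwich (robust) 95% confidence intervals — the standard
#' device for estimating risk ratios directly from cohort data without the
#' non-collapsibility and convergence problems of log-binomial models.
#' Continuous covariates are expanded into restricted quadratic splines with
#' three equally spaced knots. Adjusted risks per exposure group are computed
#' by marginal standardization: the average predicted risk over the observed
#' covariate distribution with the exposure group set counterfactually, with
#' delta-method confidence intervals on the log-risk scale.
#'
#' @param data one row per pregnancy; must contain `y` (or the column named by
#'   `outcome`) and the exposure group column.
#' @param outcome name of the binary outcome column (0/1).
#' @param group name of the exposure factor column (Z-score groups); the
#'   reference level is `ref`.
#' @param covariates character vector of adjustment covariate columns
#'   (possibly empty for crude ratios).
#' @param ref reference group label (default `"G3"`, the 51st-75th centile
#'   group). Adjusted risks are standardized over the analyzed rows' observed
#'   covariate distribution.
#' @return An object of class `gwg_rr`: list with `table` (one row per group:
#'   events, N, crude and adjusted risk in percent with CI, RR with CI on the
#'   log scale internally), the fitted `model`, its robust `vcov`, and
#'   bookkeeping. Groups with zero events yield `NA` ratios and a diagnostic
#'   `note`.
#' @export
modified_poisson_rr <- function(data, outcome, group, covariates = character(),
                                ref = "G3") {
  data <- data[!is.na(data[[outcome]]) & !is.na(data[[group]]), , drop = FALSE]
  g <- factor(data[[group]])
  if (!ref %in% levels(g)) stop("reference group '", ref, "' absent")
  g <- stats::relevel(g, ref = ref)
  data$.y <- data[[outcome]]
  data$.g <- g
  cc <- stats::complete.cases(data[covariates])
  if (!all(cc)) data <- data[cc, , drop = FALSE]
  sp <- add_covariate_splines(data, covariates)
  data <- sp$data
  rhs <- paste(c(".g", sp$terms), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)),
                    family = stats::poisson(link = "log"), data = data,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  V <- sandwich::vcovHC(fit, type = "HC0")

  lv <- levels(droplevels(data$.g))
  events <- tapply(data$.y, data$.g, sum)[lv]
  N <- tapply(data$.y, data$.g, length)[lv]
  co <- stats::coef(fit)
  z <- stats::qnorm(0.975)
  std_data <- data
  tab <- do.call(rbind, lapply(lv, function(l) {
    note <- ""
    if (l == ref) {
      rr <- 1; rl <- 1; ru <- 1
    } else {
      cn <- paste0(".g", l)
      if (is.na(events[l]) || events[l] == 0) {
        rr <- rl <- ru <- NA_real_
        note <- "zero events: risk ratio undefined"
      } else {
        b <- co[cn]; se <- sqrt(V[cn, cn])
        rr <- exp(b); rl <- exp(b - z * se); ru <- exp(b + z * se)
      }
    }
    ar <- marginal_risk(fit, V, std_data, l)
    data.frame(group = l, events = as.integer(events[l]),
               N = as.integer(N[l]),
               crude_risk_pct = 100 * events[l] / N[l],
               adj_risk_pct = 100 * ar$risk,
               adj_risk_lcl = 100 * ar$ci[1], adj_risk_ucl = 100 * ar$ci[2],
               rr = rr, rr_lcl = rl, rr_ucl = ru, note = note,
               stringsAsFactors = FALSE)
  }))
  ord <- order(match(tab$group, sort(lv)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, model = fit, vcov = V, ref = ref,
                 outcome = outcome, covariates = covariates),
            class = "gwg_rr")
}

marginal_risk <- function(fit, V, data, level) {
  nd <- data
  nd$.g <- factor(level, levels = levels(data$.g))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), nd)
  co <- stats::coef(fit)
  co <- co[!is.na(co)]                 # drop aliased terms
  keep <- intersect(names(co), colnames(V))
  co <- co[keep]
  V <- V[keep, keep, drop = FALSE]
  X <- X[, keep, drop = FALSE]
  p <- exp(drop(X %*% co))
  risk <- mean(p)
  grad <- colMeans(p * X)                      # d mean(exp(Xb)) / d b
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  # CI on the log-risk scale keeps the interval positive
  se_log <- se / risk
  list(risk = risk, ci = risk * exp(c(-1, 1) * stats::qnorm(0.975) * se_log))
}

#' @export
print.gwg_rr <- function(x, digits = 3, ...) {
  cat("Modified Poisson risk-ratio model for '", x$outcome, "' (reference ",
      x$ref, ")\n", sep = "")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-3s %5d/%5d  risk %5.1f%%  adj %5.1f%% (%.1f, %.1f)  RR %s\n",
                t$group[i], t$events[i], t$N[i], t$crude_risk_pct[i],
                t$adj_risk_pct[i], t$adj_risk_lcl[i], t$adj_risk_ucl[i],
                if (is.na(t$rr[i])) "NA" else
                  sprintf("%.2f (%.2f, %.2f)", t$rr[i], t$rr_lcl[i],
                          t$rr_ucl[i])))
  }
  invisible(x)
}

#' Adjusted (standardized) risk for one exposure group
#'
#' Marginal standardization from a fitted `gwg_rr`: the average predicted risk
#' with every pregnancy's exposure set to `level`, as a percentage with a
#' delta-method CI.
#'
#' @param object a `gwg_rr`.
#' @param level exposure group label.
#' @return list `risk_pct`, `ci_pct`.
#' @export
adjusted_risk <- function(object, level) {
  stopifnot(inherits(object, "gwg_rr"))
  row <- object$table[object$table$group == level, ]
  if (!nrow(row)) stop("group '", level, "' not in fitted strata")
  list(risk_pct = row$adj_risk_pct,
       ci_pct = c(row$adj_risk_lcl, row$adj_risk_ucl))
}

#' Dose-response curve of outcome risk in the continuous Z-score
#'
#' Marginal logistic regression of the outcome on the continuous Z-score
#' (restricted quadratic spline, three equally spaced knots) plus covariates;
#' with one record per pregnancy and an independence working correlation this
#' coincides with ordinary logistic estimation, and robust variances are
#' reported. Per-pregnancy predicted probabilities are then smoothed against
#' the Z-score within each BMI stratum with a penalized regression spline and
#' exported on a fixed grid.
#'
#' @param data one row per pregnancy with the outcome column, `z`, covariates
#'   and `bmi_group`.
#' @param outcome binary outcome column name.
#' @param z_col continuous Z-score column name.
#' @param covariates adjustment covariates (splined when continuous).
#' @param bmi_col BMI stratum column.
#' @param grid Z grid for the exported curve.
#' @return list of class `gwg_dose_response`: `curves` (data frame `bmi_group,
#'   z, prob`), `predictions` (per-pregnancy), `model`, `vcov`.
#' @export
gee_dose_response <- function(data, outcome, z_col = "z",
                              covariates = character(), bmi_col = "bmi_group",
                              grid = seq(-3, 3, by = 0.1)) {
  data <- data[stats::complete.cases(data[c(outcome, z_col, covariates,
                                            bmi_col)]), , drop = FALSE]
  kn <- equally_spaced_knots(data[[z_col]], k = 3)
  B <- rqs_basis(data[[z_col]], kn)
  nm <- c(".z", paste0(".z_rqs", seq_len(ncol(B) - 1L)))
  colnames(B) <- nm
  data[nm] <- as.data.frame(B)[nm]
  sp <- add_covariate_splines(data, covariates)
  data <- sp$data
  rhs <- paste(c(nm, sp$terms), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste(outcome, "~", rhs)),
                    family = stats::binomial(), data = data)
  if (!fit$converged) stop("dose-response logistic model failed to converge")
  V <- sandwich::vcovHC(fit, type = "HC0")
  data$.pred <- stats::fitted(fit)
  curves <- do.call(rbind, lapply(sort(unique(data[[bmi_col]])), function(g) {
    d <- data[data[[bmi_col]] == g, , drop = FALSE]
    if (nrow(d) < 30) return(NULL)
    sm <- mgcv::gam(.pred ~ s(x, k = 10), data =
                      data.frame(.pred = d$.pred, x = d[[z_col]]))
    gz <- grid[grid >= min(d[[z_col]]) & grid <= max(d[[z_col]])]
    data.frame(bmi_group = g, z = gz,
               prob = as.numeric(stats::predict(sm,
                                                newdata = data.frame(x = gz))),
               stringsAsFactors = FALSE)
  }))
  structure(list(curves = curves,
                 predictions = data.frame(z = data[[z_col]],
                                          bmi_group = data[[bmi_col]],
                                          prob = data$.pred),
                 model = fit, vcov = V),
            class = "gwg_dose_response")
}

#' @export
print.gwg_dose_response <- function(x, ...) {
  cat("Dose-response curves (marginal logistic + penalized smoother)\n")
  cat("  strata:", paste(unique(x$curves$bmi_group), collapse = ", "), "\n")
  invisible(x)
}

#' Association between a baseline characteristic and the GWG Z-score
#'
#' Marginal (identity-link) linear model of the Z-score on a categorized
#' baseline characteristic, with cluster-robust standard errors using study
#' cohort as the cluster. With a single cohort, heteroscedasticity-robust
#' standard errors are used instead, with a warning.
#'
#' @param data data frame with the Z-score, characteristic and cohort columns.
#' @param z_col Z-score column name.
#' @param characteristic column name of the (categorical) characteristic.
#' @param cluster_col cohort column name.
#' @return data frame: one row per non-reference level with `estimate`
#'   (mean Z difference), `se`, `lcl`, `ucl`.
#' @export
baseline_assoc <- function(data, z_col = "z", characteristic,
                           cluster_col = "cohort") {
  data <- data[stats::complete.cases(data[c(z_col, characteristic)]), ,
               drop = FALSE]
  f <- stats::as.formula(paste(z_col, "~ factor(", characteristic, ")"))
  fit <- stats::lm(f, data = data)
  cl <- data[[cluster_col]]
  if (length(unique(cl)) < 2L) {
    warning("single cohort: falling back to heteroscedasticity-robust SEs")
    V <- sandwich::vcovHC(fit, type = "HC1")
  } else {
    V <- sandwich::vcovCL(fit, cluster = cl)
  }
  co <- stats::coef(fit)[-1]
  se <- sqrt(diag(V))[-1]
  z <- stats::qnorm(0.975)
  data.frame(level = sub("^factor\\([^)]*\\)", "", names(co)),
             estimate = unname(co), se = unname(se),
             lcl = unname(co - z * se), ucl = unname(co + z * se),
             stringsAsFactors = FALSE)
}
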