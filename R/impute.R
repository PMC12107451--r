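#' Multiple imputation by chained equations
#'
#' Fills in missing values of an analysis table `m` times by fully-conditional
#' specification: each incomplete variable is regressed on the other listed
#' variables among its observed rows, model parameters are drawn from their
#' approximate posterior, and missing entries are drawn from the resulting
#' posterior-predictive distribution. Continuous variables use Bayesian normal
#' linear regression (scaled inverse-chi-squared draw for the residual
#' variance, normal draw for the coefficients); binary (logical or two-level
#' factor) variables use logistic regression with a normal approximation to
#' the coefficient posterior. A non-convergent or separated logistic sub-model
#' falls back to observed-frequency draws with a warning. Cycling repeats for
#' `iterations` sweeps. Deterministic given `seed`.
#'
#' @param data data frame, one row per pregnancy.
#' @param variables character vector naming the variables that enter the
#'   imputation model (both the incomplete ones and their predictors).
#'   Missingness must be confined to these columns; each must have at least
#'   one observed value.
#' @param m number of completed copies (the motivating analysis used 50;
#'   tests use fewer for speed).
#' @param iterations chained-equation sweeps per copy.
#' @param seed integer seed.
#' @return An object of class `gwg_imputation`: list with `imputations` (list
#'   of `m` completed data frames), `variables`, `m`, `iterations`, `seed`.
#' @seealso [rubin_pool()], [complete_imputation()]
#' @export
impute_chained <- function(data, variables, m = 50, iterations = 5,
                           seed = 1L) {
  stopifnot(is.data.frame(data), m >= 1, iterations >= 1)
  bad <- setdiff(variables, names(data))
  if (length(bad)) stop("variables not in data: ", paste(bad, collapse = ", "))
  other <- setdiff(names(data), variables)
  if (any(vapply(data[other], anyNA, logical(1)))) {
    stop("missingness must be confined to the listed variables")
  }
  fully_missing <- variables[vapply(data[variables],
                                    function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing)) {
    stop("variable(s) fully missing, cannot impute: ",
         paste(fully_missing, collapse = ", "))
  }
  incomplete <- variables[vapply(data[variables], anyNA, logical(1))]
  set.seed(as.integer(seed))
  imputations <- vector("list", m)
  for (k in seq_len(m)) {
    comp <- data
    # initialize by sampling observed values
    for (v in incomplete) {
      na <- is.na(comp[[v]])
      comp[[v]][na] <- sample(comp[[v]][!na], sum(na), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in incomplete) {
        na <- is.na(data[[v]])
        preds <- setdiff(variables, v)
        comp[[v]][na] <- draw_imputation(data[[v]], comp, v, preds, na)
      }
    }
    imputations[[k]] <- comp
  }
  structure(list(imputations = imputations, variables = variables,
                 incomplete = incomplete, m = m, iterations = iterations,
                 seed = as.integer(seed)),
            class = "gwg_imputation")
}

draw_imputation <- function(orig, comp, v, preds, na) {
  df <- comp[preds]
  # drop constant predictors to keep the design full rank
  keep <- vapply(df, function(x) length(unique(x)) > 1L, logical(1))
  X <- stats::model.matrix(~ ., data = df[, keep, drop = FALSE])
  y <- comp[[v]]
  obs <- !na
  binary <- is.logical(orig) ||
    (is.factor(orig) && nlevels(orig) == 2L) ||
    (is.numeric(orig) && all(orig[obs] %in% 0:1))
  if (binary) {
    yb <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE], yb[obs],
                                      family = stats::binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged &&
      all(abs(stats::coef(fit)) < 25, na.rm = TRUE)
    if (!ok) {
      warning("logistic imputation model for '", v,
              "' unstable; falling back to observed-frequency draws")
      p <- mean(yb[obs])
      draw <- stats::runif(sum(na)) < p
    } else {
      beta <- stats::coef(fit)
      beta[is.na(beta)] <- 0
      # normal approximation to the posterior: vcov = (X'WX)^-1 from the
      # final IRLS decomposition
      V <- chol2inv(qr.R(structure(fit$qr, class = "qr")))
      bdraw <- beta + drop(chol_mvrnorm(V))
      p <- stats::plogis(drop(X[na, , drop = FALSE] %*% bdraw))
      draw <- stats::runif(sum(na)) < p
    }
    if (is.factor(orig)) factor(levels(orig)[draw + 1L], levels = levels(orig))
    else if (is.logical(orig)) draw
    else as.integer(draw)
  } else {
    Xo <- X[obs, , drop = FALSE]
    qrx <- qr(Xo)
    betah <- qr.coef(qrx, y[obs])
    betah[is.na(betah)] <- 0
    res <- y[obs] - drop(Xo %*% betah)
    df_res <- max(length(res) - qrx$rank, 1L)
    sig2 <- sum(res^2) / stats::rchisq(1, df_res)
    XtXi <- tryCatch(chol2inv(qr.R(qrx)), error = function(e) NULL)
    if (is.null(XtXi)) XtXi <- diag(1e-8, length(betah))
    bdraw <- betah + drop(chol_mvrnorm(sig2 * XtXi))
    drop(X[na, , drop = FALSE] %*% bdraw) +
      stats::rnorm(sum(na), 0, sqrt(sig2))
  }
}

chol_mvrnorm <- function(Sigma) {
  # one draw from N(0, Sigma), tolerant of near-singular Sigma
  p <- nrow(Sigma)
  ch <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-10 * max(diag(Sigma), 1e-12), p))
  })
  drop(crossprod(ch, stats::rnorm(p)))
}

#' @export
print.gwg_imputation <- function(x, ...) {
  cat(sprintf("Multiple imputation: m = %d copies, %d sweeps, seed %d\n",
              x$m, x$iterations, x$seed))
  cat("  imputed variables:", paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one completed data set
#'
#' @param imp a `gwg_imputation`.
#' @param i copy index in `1..m`.
#' @return the i-th completed data frame.
#' @export
complete_imputation <- function(imp, i = 1L) {
  stopifnot(inherits(imp, "gwg_imputation"), i >= 1, i <= imp$m)
  imp$imputations[[i]]
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; the total
#' variance combines within-imputation variance `W = mean(variances)` and
#' between-imputation variance `B = var(estimates)` as
#' `T = W + (1 + 1/m) * B`.
#'
#' @param estimates numeric vector of per-imputation point estimates
#'   (length m >= 2). Pool ratio-scale quantities (risk ratios) on the log
#'   scale.
#' @param variances per-imputation squared standard errors (same length,
#'   all >= 0).
#' @param conf.level confidence level for the interval.
#' @param df_method `"normal"` (default) or `"small_sample"` (Rubin's
#'   t-reference with `df = (m - 1) * (1 + W / ((1 + 1/m) B))^2`).
#' @return object of class `pooled_estimate`: list with `estimate, W, B, T,
#'   se, ci, m, df`.
#' @export
rubin_pool <- function(estimates, variances, conf.level = 0.95,
                       df_method = c("normal", "small_sample")) {
  df_method <- match.arg(df_method)
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling requires m >= 2 imputations")
  if (length(variances) != m) stop("estimates and variances lengths differ")
  if (any(variances < 0)) stop("variances must be >= 0")
  est <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  alpha <- 1 - conf.level
  if (df_method == "small_sample" && B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  }
  structure(list(estimate = est, W = W, B = B, T = Tv, se = se,
                 ci = c(est - q * se, est + q * se), m = m, df = df,
                 conf.level = conf.level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate %.5g (SE %.4g), %g%% CI [%.5g, %.5g]; m = %d, W = %.4g, B = %.4g\n",
    x$estimate, x$se, 100 * x$conf.level, x$ci[1], x$ci[2], x$m, x$W, x$B))
  invisible(x)
}

#' Write an imputation set to indexed CSV files
#'
#' Serializes the m completed copies as `imp_001.csv ...` plus a JSON manifest
#' (seed, m, variables, iterations).
#'
#' @param imp a `gwg_imputation`.
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
write_imputation_set <- function(imp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(imp$m)) {
    utils::write.csv(imp$imputations[[k]],
                     file.path(dir, sprintf("imp_%03d.csv", k)),
                     row.names = FALSE)
  }
  manifest <- list(seed = imp$seed, m = imp$m, variables = imp$variables,
                   iterations = imp$iterations)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
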