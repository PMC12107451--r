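#' Knot placement at fixed empirical percentiles
#'
#' Places spline knots at the empirical percentiles of the observed predictor
#' values. The default probabilities (5, 35, 65, 95) are the conventional
#' four-knot placement used for gestational-age trends in reference-chart
#' modelling.
#'
#' @param values numeric vector of observed predictor values (e.g. gestational
#'   age in weeks at each visit).
#' @param probs percentiles (in percent) at which to place knots.
#' @return An object of class `knot_set`: a numeric vector of strictly
#'   increasing knots with attributes `placement_rule` and `probs`.
#' @details Quantiles use the linear-interpolation definition
#'   (`stats::quantile`, type 7). At least 20 distinct values are required;
#'   coincident knots are an error rather than silently collapsed, because a
#'   degenerate knot set changes the meaning of the spline basis.
#' @seealso [equally_spaced_knots()], [rqs_basis()]
#' @export
percentile_knots <- function(values, probs = c(5, 35, 65, 95)) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 20L) {
    stop("percentile_knots() needs at least 20 distinct finite values; got ",
         length(unique(values)))
  }
  if (length(probs) < 3L || is.unsorted(probs, strictly = TRUE)) {
    stop("'probs' must be at least 3 strictly increasing percentiles")
  }
  k <- unname(stats::quantile(values, probs = probs / 100, type = 7))
  if (anyDuplicated(k) || is.unsorted(k, strictly = TRUE)) {
    stop("coincident knots at percentiles (", paste(probs, collapse = ", "),
         "): values too concentrated for this placement")
  }
  new_knot_set(k, placement_rule = sprintf("percentile(%s)",
                                           paste(probs, collapse = ",")),
               probs = probs)
}

#' Equally spaced interior knots
#'
#' Places `k` knots strictly inside the observed range of the predictor, at
#' `min + j*(max - min)/(k + 1)` for `j = 1..k`. Three equally spaced knots is
#' the placement used for continuous adjustment covariates and for the
#' continuous Z-score in the dose-response models.
#'
#' @param values numeric vector of observed values, or a length-2 range.
#' @param k number of interior knots.
#' @return A `knot_set`.
#' @export
equally_spaced_knots <- function(values, k = 3) {
  values <- values[is.finite(values)]
  lo <- min(values)
  hi <- max(values)
  if (!(hi > lo)) stop("degenerate range: max(values) must exceed min(values)")
  if (k < 3L) stop("'k' must be at least 3")
  kn <- lo + seq_len(k) * (hi - lo) / (k + 1)
  new_knot_set(kn, placement_rule = sprintf("equally_spaced(%d)", k))
}

new_knot_set <- function(knots, placement_rule, probs = NULL) {
  stopifnot(is.numeric(knots), length(knots) >= 3L,
            !is.unsorted(knots, strictly = TRUE))
  structure(as.numeric(knots), class = "knot_set",
            placement_rule = placement_rule, probs = probs)
}

#' @export
print.knot_set <- function(x, ...) {
  cat("Knot set (", attr(x, "placement_rule"), "): ",
      paste(signif(unclass(x), 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restricted quadratic spline basis
#'
#' Builds the restricted quadratic spline (RQS) design columns for a predictor:
#' one linear column plus, for each knot `k_j` except the last, the column
#' \deqn{s_j(x) = \frac{(x - k_j)_+^2 - (x - k_K)_+^2}{k_K - k_1}.}
#' Each `s_j` is continuous with continuous first derivative, and every
#' function in the span is linear for `x >= k_K` (the "restriction"), so
#' fitted trends cannot curve wildly beyond the data-dense region.
#'
#' @param x numeric vector of predictor values.
#' @param knots a `knot_set` or a strictly increasing numeric vector of length
#'   at least 3.
#' @return A numeric matrix with `length(x)` rows and `length(knots)` columns:
#'   `x` followed by `rqs1 .. rqs(K-1)`.
#' @export
rqs_basis <- function(x, knots) {
  if (!inherits(knots, "knot_set")) {
    knots <- new_knot_set(knots, placement_rule = "user")
  }
  k <- as.numeric(knots)
  K <- length(k)
  pp <- function(u) pmax(u, 0)
  last <- pp(x - k[K])^2
  denom <- k[K] - k[1]
  s <- vapply(seq_len(K - 1L),
              function(j) (pp(x - k[j])^2 - last) / denom,
              numeric(length(x)))
  out <- cbind(x, matrix(s, nrow = length(x)))
  colnames(out) <- c("x", paste0("rqs", seq_len(K - 1L)))
  out
}
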