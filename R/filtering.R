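#' Flag implausible antenatal weight measurements
#'
#' A visit is invalid when the weight change from the participant's baseline
#' weight is more extreme than -4 kg or +19 kg (the 1st and 99th percentiles
#' of weight change in the motivating consortium). The boundary values are
#' valid: "more extreme than" is read as strict exceedance. Only the visit is
#' invalidated, never the participant — other visits are kept.
#'
#' @param visits data frame with `participant_id, cohort, ga_weeks, weight_kg`.
#' @param baselines data frame with `participant_id, baseline_weight_kg`.
#' @param lower,upper validity bounds on the weight change in kg (inclusive).
#' @return `visits` with added columns `weight_change_kg` and logical `valid`.
#' @export
validate_visits <- function(visits, baselines, lower = -4, upper = 19) {
  m <- match(visits$participant_id, baselines$participant_id)
  if (anyNA(m)) {
    orphans <- unique(visits$participant_id[is.na(m)])
    stop("visits without a baseline record for participant(s): ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) sprintf(" (and %d more)", length(orphans) - 10))
  }
  change <- visits$weight_kg - baselines$baseline_weight_kg[m]
  visits$weight_change_kg <- change
  visits$valid <- change >= lower & change <= upper
  visits
}

#' Select the eligible study population
#'
#' Applies the study eligibility rules in order, attributing each excluded
#' participant to the first rule it violates: (1) fewer than two valid weight
#' measurements; (2) unknown birth outcome (missing delivery gestational age);
#' (3) unknown neonatal vital status (missing stillbirth flag); (4) multiple
#' gestation (only if the outcomes table carries a logical `singleton`
#' column; otherwise all pregnancies are assumed singleton); (5) delivery
#' after 42 weeks. When a participant contributes several outcome rows, only
#' the first pregnancy (first row) is used.
#'
#' @param visits validated visits (see [validate_visits()]); the `valid`
#'   column is computed here if absent.
#' @param baselines,outcomes the companion tables.
#' @return A list of class `gwg_flow`: `participants` (character vector of
#'   retained ids), `flow` (data frame of per-step exclusion counts) and
#'   `outcomes` (the de-duplicated outcome rows of retained participants).
#' @export
select_study_population <- function(visits, baselines, outcomes) {
  if (!"valid" %in% names(visits)) visits <- validate_visits(visits, baselines)
  outcomes <- outcomes[!duplicated(outcomes$participant_id), , drop = FALSE]
  ids <- baselines$participant_id
  n_valid <- table(factor(visits$participant_id[visits$valid], levels = ids))
  om <- match(ids, outcomes$participant_id)

  steps <- list(
    "fewer than 2 valid weight measurements" = as.vector(n_valid) < 2,
    "unknown birth outcome" =
      is.na(om) | is.na(outcomes$delivery_ga_weeks[om]),
    "unknown neonatal vital status" = is.na(outcomes$stillbirth[om]),
    "multiple gestation" = if ("singleton" %in% names(outcomes)) {
      !is.na(outcomes$singleton[om]) & !outcomes$singleton[om]
    } else rep(FALSE, length(ids)),
    "delivery after 42 weeks" = outcomes$delivery_ga_weeks[om] > 42)

  excluded <- rep(FALSE, length(ids))
  flow <- data.frame(step = c("assessed", names(steps)),
                     excluded = 0L, remaining = length(ids),
                     stringsAsFactors = FALSE)
  for (i in seq_along(steps)) {
    hit <- !excluded & !is.na(steps[[i]]) & steps[[i]]
    # missing predicates count as violations only for the two "unknown" rules,
    # where NA is itself the violation; those predicates are NA-free above
    hit_na <- !excluded & is.na(steps[[i]]) &
      names(steps)[i] %in% c("unknown birth outcome",
                             "unknown neonatal vital status")
    hit <- hit | hit_na
    excluded <- excluded | hit
    flow$excluded[i + 1L] <- sum(hit)
    flow$remaining[i + 1L] <- length(ids) - sum(excluded)
  }
  keep <- ids[!excluded]
  structure(list(participants = keep, flow = flow,
                 outcomes = outcomes[outcomes$participant_id %in% keep, ,
                                     drop = FALSE]),
            class = "gwg_flow")
}

#' Select the reference subpopulation for chart estimation
#'
#' From the study population, excludes — hierarchically, so each participant
#' is counted once, in this order — (1) participants whose first valid weight
#' was measured after 20 gestational weeks, (2) preterm deliveries
#' (<37 weeks) and (3) stillbirths. The remainder are term livebirths with an
#' early baseline weight, the "healthy-reference" analogue used to fit the
#' weight-gain charts.
#'
#' @param population a `gwg_flow` from [select_study_population()], or a
#'   character vector of participant ids.
#' @param visits validated visits.
#' @param outcomes outcome records.
#' @return A `gwg_flow` with the reference ids and per-category counts.
#' @export
select_reference_subpopulation <- function(population, visits, outcomes) {
  ids <- if (inherits(population, "gwg_flow")) population$participants
         else as.character(population)
  if (!"valid" %in% names(visits)) {
    stop("visits must carry validity flags; run validate_visits() first")
  }
  outcomes <- outcomes[!duplicated(outcomes$participant_id), , drop = FALSE]
  v <- visits[visits$valid & visits$participant_id %in% ids, , drop = FALSE]
  first_ga <- tapply(v$ga_weeks, factor(v$participant_id, levels = ids), min)
  om <- match(ids, outcomes$participant_id)

  late_baseline <- !is.na(first_ga) & first_ga > 20
  preterm <- !late_baseline &
    !is.na(outcomes$delivery_ga_weeks[om]) & outcomes$delivery_ga_weeks[om] < 37
  still <- !late_baseline & !preterm &
    !is.na(outcomes$stillbirth[om]) & outcomes$stillbirth[om]

  excluded <- late_baseline | preterm | still
  flow <- data.frame(
    step = c("study population", "baseline weight after 20 weeks",
             "preterm delivery (<37 weeks)", "stillbirth"),
    excluded = c(0L, sum(late_baseline), sum(preterm), sum(still)),
    remaining = c(length(ids),
                  length(ids) - cumsum(c(sum(late_baseline), sum(preterm),
                                         sum(still)))),
    stringsAsFactors = FALSE)
  structure(list(participants = ids[!excluded], flow = flow,
                 outcomes = outcomes[outcomes$participant_id %in% ids[!excluded],
                                     , drop = FALSE]),
            class = "gwg_flow")
}

#' @export
print.gwg_flow <- function(x, ...) {
  cat("Participant flow:\n")
  f <- x$flow
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-42s excluded %6d   remaining %6d\n",
                f$step[i], f$excluded[i], f$remaining[i]))
  }
  invisible(x)
}

#' Export a participant-flow report
#'
#' Writes the flow-chart counts of one or more selection steps as a plain-text
#' report and a machine-readable JSON file.
#'
#' @param ... one or more `gwg_flow` objects (named arguments become section
#'   titles).
#' @param file path of the text report; the JSON sidecar gets extension
#'   `.json`.
#' @return invisibly, the list serialized to JSON.
#' @export
write_flow_report <- function(..., file) {
  flows <- list(...)
  if (is.null(names(flows))) names(flows) <- paste0("step", seq_along(flows))
  txt <- character(0)
  for (nm in names(flows)) {
    f <- flows[[nm]]$flow
    txt <- c(txt, nm, paste0(
      sprintf("  %-42s excluded %6d   remaining %6d",
              f$step, f$excluded, f$remaining)), "")
  }
  writeLines(txt, file)
  out <- lapply(flows, function(f) f$flow)
  jsonlite::write_json(out, sub("\\.[^.]*$", ".json", file),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(out)
}
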