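#' Classify AT biomarker status from the CSF Aβ42/pTau181 ratio
#'
#' Applies the pre-established cutoff of 39.20 on the Aβ42/pTau181 ratio.
#' Following the published rule literally, ratios at or below the cutoff are
#' `AT_minus` and ratios above it are `AT_plus`; note this is the reverse of
#' the usual biochemical direction for this ratio (low Aβ42/pTau181 normally
#' indicates amyloid pathology), so `positive_above = FALSE` flips the
#' assignment for conventional use. The boundary value is assigned to the
#' "below" side.
#'
#' @param abeta42,ptau181 CSF concentrations (pg/mL); `ptau181` must be
#'   positive.
#' @param cutoff ratio cutoff.
#' @param positive_above if `TRUE` (default, literal published rule), ratios
#'   above the cutoff are `AT_plus`.
#' @return character vector of `"AT_minus"` / `"AT_plus"`.
#' @export
classify_at <- function(abeta42, ptau181, cutoff = 39.20,
                        positive_above = TRUE) {
  if (any(ptau181 <= 0, na.rm = TRUE)) {
    rlang::abort("`ptau181` must be positive.")
  }
  ratio <- abeta42 / ptau181
  above <- ratio > cutoff
  if (!positive_above) above <- !above
  ifelse(above, "AT_plus", "AT_minus")
}

outcome_defaults <- function(outcome_name) {
  if (outcome_name %in% c("tau_SUVR", "FDG_SUVR")) {
    list(min_visits = 2L, min_span_months = 12)
  } else {
    # clinical scales and hippocampal volume: 3 visits spanning >= 24 months
    list(min_visits = 3L, min_span_months = 24)
  }
}

#' Default worsening direction of an outcome slope
#'
#' `+1` where an increasing value is worse (ADAS-Cog11, CDR-SB, tau SUVR),
#' `-1` where a decrease is worse (hippocampal volume, FDG SUVR).
#'
#' @param outcome_name outcome label.
#' @return `+1` or `-1`.
#' @export
outcome_worsening_sign <- function(outcome_name) {
  if (outcome_name %in% c("hippocampal_volume_norm", "FDG_SUVR")) -1 else 1
}

#' Select subjects with sufficient longitudinal coverage
#'
#' Keeps subjects with at least `min_visits` timepoints spanning at least
#' `min_span_months`. Defaults depend on the outcome: clinical scales and
#' hippocampal volume require (3 visits, 24 months); tau and FDG SUVR require
#' (2 visits, 12 months).
#'
#' @param series long tibble with columns `subject_id`, `outcome_name`,
#'   `months`, `value`.
#' @param min_visits,min_span_months override the per-outcome defaults.
#' @return filtered series (same columns).
#' @export
select_longitudinal <- function(series, min_visits = NULL,
                                min_span_months = NULL) {
  series |>
    dplyr::group_by(.data$outcome_name) |>
    dplyr::group_modify(function(df, key) {
      defs <- outcome_defaults(key$outcome_name)
      mv <- min_visits %||% defs$min_visits
      ms <- min_span_months %||% defs$min_span_months
      keep <- df |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(n = dplyr::n(),
                         span = max(.data$months) - min(.data$months),
                         .groups = "drop") |>
        dplyr::filter(.data$n >= mv, .data$span >= ms)
      dplyr::semi_join(df, keep, by = "subject_id")
    }) |>
    dplyr::ungroup()
}

#' Per-subject rates of change from a linear mixed model
#'
#' Fits `value ~ months + (1 + months | subject_id)` by REML and extracts each
#' subject's slope as the fixed slope plus the subject's best linear unbiased
#' predictor (BLUP). If the mixed fit is singular or fails, per-subject
#' ordinary least squares slopes are used instead and flagged in the `method`
#' column. Subjects with fewer than two visits are excluded.
#'
#' @param series long tibble for a single outcome (columns `subject_id`,
#'   `outcome_name`, `months`, `value`).
#' @return slope table: `subject_id`, `outcome_name`, `slope` (units/month),
#'   `n_visits`, `span_months`, `included`, `reason`, `method`.
#' @export
fit_subject_slopes <- function(series) {
  stopifnot(all(c("subject_id", "outcome_name", "months", "value") %in%
                  names(series)))
  if (dplyr::n_distinct(series$outcome_name) != 1L) {
    rlang::abort("`series` must contain a single outcome; split beforehand.")
  }
  outcome <- series$outcome_name[1]

  per_subj <- series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_visits = dplyr::n(),
                     span_months = max(.data$months) - min(.data$months),
                     .groups = "drop")
  usable <- per_subj$subject_id[per_subj$n_visits >= 2L]
  dat <- series[series$subject_id %in% usable, , drop = FALSE]
  if (dplyr::n_distinct(dat$subject_id) < 2L) {
    rlang::abort("need at least 2 subjects with >= 2 visits.")
  }

  slopes <- NULL
  method <- "blup"
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ months + (1 + months | subject_id), data = dat,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC(action = "ignore",
                                                             tol = 1e-4)))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
    cf <- coef(fit)$subject_id
    slopes <- setNames(cf[, "months"], rownames(cf))
  } else {
    method <- "ols"
    slopes <- vapply(split(dat, dat$subject_id), function(d) {
      unname(coef(lm(value ~ months, data = d))[2])
    }, numeric(1))
  }

  per_subj |>
    dplyr::mutate(
      outcome_name = outcome,
      included = .data$n_visits >= 2L,
      reason = ifelse(.data$included, NA_character_, "fewer than 2 visits"),
      slope = unname(slopes[.data$subject_id]),
      method = ifelse(.data$included, method, NA_character_)
    ) |>
    dplyr::select("subject_id", "outcome_name", "slope", "n_visits",
                  "span_months", "included", "reason", "method")
}

#' Remove outlying slopes beyond a z-score band
#'
#' Drops slopes more than `n_sd` standard deviations from the mean (mean and
#' sd computed once over the included slopes; single pass).
#'
#' @param slopes slope table from [fit_subject_slopes()].
#' @param n_sd band half-width in standard deviations.
#' @return slope table with outliers removed.
#' @export
trim_outlier_slopes <- function(slopes, n_sd = 4) {
  inc <- slopes$included & !is.na(slopes$slope)
  if (sum(inc) < 3L) rlang::abort("need at least 3 included slopes.")
  mu <- mean(slopes$slope[inc])
  sg <- sd(slopes$slope[inc])
  drop <- inc & sg > 0 & abs(slopes$slope - mu) > n_sd * sg
  slopes[!drop, , drop = FALSE]
}

#' Split subjects into fast and slow progressors at the median slope
#'
#' Fast progressors are subjects whose slope, oriented so that larger means
#' clinically worse, is strictly greater than the cohort median; everyone else
#' is slow. If all slopes are equal, every subject is labeled slow and a
#' warning is raised.
#'
#' @param slopes slope table with `subject_id` and `slope`.
#' @param worsening_sign `+1` if an increasing outcome is worse, `-1`
#'   otherwise (see [outcome_worsening_sign()]).
#' @return tibble `subject_id`, `slope`, `progression` (`"fast"`/`"slow"`).
#' @export
median_split <- function(slopes, worsening_sign = 1) {
  stopifnot(worsening_sign %in% c(-1, 1))
  inc <- if ("included" %in% names(slopes)) slopes$included else TRUE
  inc <- inc & !is.na(slopes$slope)
  df <- slopes[inc, c("subject_id", "slope")]
  if (nrow(df) < 2L) rlang::abort("need at least 2 slopes.")
  oriented <- df$slope * worsening_sign
  med <- median(oriented)
  if (all(oriented == oriented[1])) {
    rlang::warn("median_split: all slopes equal; every subject labeled slow.")
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(progression = ifelse(oriented > med, "fast", "slow"))
}

#' Label converters and stable subjects from diagnosis histories
#'
#' For the MCI cohort, converters are subjects whose first dementia diagnosis
#' occurs within `window_months` of baseline; stable subjects remain MCI at
#' every visit and have follow-up beyond the window; everyone else is
#' excluded. For the amyloid and asymptomatic cohorts no window applies: a
#' subject converts if the defining event occurs at any follow-up, and is
#' stable otherwise.
#'
#' @param history tibble with `subject_id`, `months` (from baseline), `status`.
#'   Expected baseline/event statuses: amyloid `"Abeta_neg"` -> `"Abeta_pos"`;
#'   asymptomatic `"CU"` -> `"MCI"` or `"Dementia"`; mci `"MCI"` ->
#'   `"Dementia"`.
#' @param cohort one of `"amyloid"`, `"asymptomatic"`, `"mci"`.
#' @param window_months conversion window for the MCI cohort (inclusive
#'   boundary).
#' @return tibble `subject_id`, `cohort`, `label`
#'   (`"stable"`/`"converter"`/`"excluded"`), `time_to_event_months`, `reason`.
#' @export
define_conversion_groups <- function(history,
                                     cohort = c("mci", "amyloid",
                                                "asymptomatic"),
                                     window_months = 36) {
  cohort <- match.arg(cohort)
  spec <- switch(cohort,
    mci = list(base = "MCI", event = "Dementia", windowed = TRUE),
    amyloid = list(base = "Abeta_neg", event = "Abeta_pos", windowed = FALSE),
    asymptomatic = list(base = "CU", event = c("MCI", "Dementia"),
                        windowed = FALSE)
  )
  history |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$months), , drop = FALSE]
      base_row <- df[df$months == min(df$months), , drop = FALSE]
      if (nrow(base_row) == 0L || !(base_row$status[1] %in% spec$base)) {
        return(tibble::tibble(label = "excluded",
                              time_to_event_months = NA_real_,
                              reason = "missing or inconsistent baseline status"))
      }
      ev <- df$months[df$status %in% spec$event & df$months > 0]
      t_event <- if (length(ev)) min(ev) else NA_real_
      if (spec$windowed) {
        if (!is.na(t_event) && t_event <= window_months) {
          tibble::tibble(label = "converter", time_to_event_months = t_event,
                         reason = NA_character_)
        } else if (is.na(t_event) && all(df$status %in% spec$base) &&
                   max(df$months) > window_months) {
          tibble::tibble(label = "stable", time_to_event_months = NA_real_,
                         reason = NA_character_)
        } else {
          tibble::tibble(label = "excluded", time_to_event_months = NA_real_,
                         reason = "insufficient follow-up or late conversion")
        }
      } else {
        if (!is.na(t_event)) {
          tibble::tibble(label = "converter", time_to_event_months = t_event,
                         reason = NA_character_)
        } else {
          tibble::tibble(label = "stable", time_to_event_months = NA_real_,
                         reason = NA_character_)
        }
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(cohort = cohort, .after = "subject_id")
}
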