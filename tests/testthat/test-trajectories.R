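test_that("AT classification follows the published ratio rule", {
  # ratio 50 > 39.20 -> AT+ under the literal published direction
  expect_equal(classify_at(500, 10), "AT_plus")
  # boundary assigned to the 'below' side
  expect_equal(classify_at(39.20 * 10, 10), "AT_minus")
  # ratio scale invariance
  expect_equal(classify_at(250, 5), classify_at(500, 10))
  expect_error(classify_at(500, 0), "ptau181")
  # conventional direction available behind the flag
  expect_equal(classify_at(500, 10, positive_above = FALSE), "AT_minus")
})

test_that("longitudinal selection applies per-outcome visit/span rules", {
  series <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d"), times = c(3, 3, 2, 2)),
    outcome_name = rep(c("ADAS-Cog11", "ADAS-Cog11", "tau_SUVR", "tau_SUVR"),
                       times = c(3, 3, 2, 2)),
    months = c(0, 12, 25, 0, 12, 23, 0, 13, 0, 11),
    value = rnorm(10)
  )
  kept <- select_longitudinal(series)
  expect_setequal(unique(kept$subject_id[kept$outcome_name == "ADAS-Cog11"]),
                  "a")                          # b: span 23 < 24
  expect_setequal(unique(kept$subject_id[kept$outcome_name == "tau_SUVR"]),
                  "c")                          # d: span 11 < 12; 2 visits ok
})

test_that("noise-free subject slopes are recovered exactly (OLS fallback)", {
  t <- c(0, 6, 12, 24)
  series <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 4),
    outcome_name = "CDR-SB",
    months = rep(t, 2),
    value = c(1 + 0.5 * t, 2 - 0.3 * t)
  )
  sl <- fit_subject_slopes(series)
  expect_equal(sl$slope[sl$subject_id == "a"], 0.5, tolerance = 1e-6)
  expect_equal(sl$slope[sl$subject_id == "b"], -0.3, tolerance = 1e-6)
  expect_true(all(sl$method == "ols"))   # singular mixed fit flagged
})

test_that("mixed-model slopes recover simulated truth and its fixed effect", {
  cfg <- sim_config(n_subjects = 150, outcome_noise_sd = 0.5, seed = 8)
  ch <- generate_cohort(cfg)
  lo <- generate_longitudinal_outcomes(ch$meta, ch$truth, cfg)
  sl <- fit_subject_slopes(lo$outcomes)
  truth <- lo$truth$true_slopes[["ADAS-Cog11"]][sl$subject_id]
  expect_gt(cor(sl$slope, truth), 0.9)
  expect_true(all(sl$method == "blup"))
  # recovery degrades monotonically as outcome noise grows
  rs <- vapply(c(0.5, 2, 8), function(ns) {
    cfgn <- sim_config(n_subjects = 80, outcome_noise_sd = ns, seed = 8)
    chn <- generate_cohort(cfgn)
    lon <- generate_longitudinal_outcomes(chn$meta, chn$truth, cfgn)
    sln <- fit_subject_slopes(lon$outcomes)
    cor(sln$slope, lon$truth$true_slopes[["ADAS-Cog11"]][sln$subject_id])
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("outlier trimming is a single 4-sd pass", {
  sl <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:21),
    outcome_name = "ADAS-Cog11",
    slope = c(rnorm(20, 0, 0.1), 0), n_visits = 3, span_months = 25,
    included = TRUE, reason = NA_character_, method = "blup"
  )
  sl$slope[21] <- mean(sl$slope[1:20]) + 40 * sd(sl$slope[1:20])
  trimmed <- trim_outlier_slopes(sl)
  expect_equal(nrow(trimmed), 20)
  expect_false("s21" %in% trimmed$subject_id)

  tight <- sl[1:20, ]
  expect_equal(nrow(trim_outlier_slopes(tight)), 20)  # all within band
})

test_that("median split labels strictly-above-median slopes fast", {
  sl <- tibble::tibble(subject_id = letters[1:4],
                       slope = c(0.1, 0.2, 0.3, 0.4))
  lab <- median_split(sl, worsening_sign = 1)
  expect_setequal(lab$subject_id[lab$progression == "fast"], c("c", "d"))
  expect_setequal(lab$subject_id[lab$progression == "slow"], c("a", "b"))

  # negate slopes and flip the worsening sign: identical labels
  neg <- median_split(dplyr::mutate(sl, slope = -slope), worsening_sign = -1)
  expect_equal(neg$progression, lab$progression)

  tied <- tibble::tibble(subject_id = letters[1:4], slope = rep(0.2, 4))
  expect_warning(lab2 <- median_split(tied), "all slopes equal")
  expect_true(all(lab2$progression == "slow"))

  # balance within one on continuous slopes
  set.seed(1)
  cont <- tibble::tibble(subject_id = sprintf("s%03d", 1:101),
                         slope = rnorm(101))
  lc <- median_split(cont)
  expect_lte(abs(sum(lc$progression == "fast") -
                   sum(lc$progression == "slow")), 1)
})

test_that("conversion groups implement the 3-year MCI window", {
  hist <- tibble::tibble(
    subject_id = rep(c("conv", "stab", "short", "nobase"), c(2, 3, 2, 1)),
    months = c(0, 30, 0, 12, 40, 0, 24, 6),
    status = c("MCI", "Dementia", "MCI", "MCI", "MCI", "MCI", "MCI", "MCI")
  )
  lab <- define_conversion_groups(hist, "mci")
  get <- function(id) lab[lab$subject_id == id, ]
  expect_equal(get("conv")$label, "converter")
  expect_equal(get("conv")$time_to_event_months, 30)
  expect_equal(get("stab")$label, "stable")
  expect_equal(get("short")$label, "excluded")   # no visit past 36 months
  expect_equal(get("nobase")$label, "excluded")  # first visit not at baseline? still MCI at months=6
  # every subject gets exactly one label
  expect_equal(sort(lab$subject_id), sort(unique(hist$subject_id)))
  expect_true(all(lab$label %in% c("stable", "converter", "excluded")))
  # converter implies a recorded event time
  expect_true(all(!is.na(lab$time_to_event_months[lab$label == "converter"])))

  # amyloid cohort: no window, converter at any follow-up
  ah <- tibble::tibble(
    subject_id = rep(c("late", "never"), c(2, 2)),
    months = c(0, 60, 0, 60),
    status = c("Abeta_neg", "Abeta_pos", "Abeta_neg", "Abeta_neg")
  )
  al <- define_conversion_groups(ah, "amyloid")
  expect_equal(al$label[al$subject_id == "late"], "converter")
  expect_equal(al$time_to_event_months[al$subject_id == "late"], 60)
  expect_equal(al$label[al$subject_id == "never"], "stable")
})
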