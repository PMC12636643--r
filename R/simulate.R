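#' Configuration for the synthetic CSF proteomics cohort
#'
#' Parameterizes every downstream stage of the pipeline: multi-batch TMT-style
#' intensity structure with intensity-dependent missingness, planted
#' group-differential proteins organized into co-expressed modules,
#' random-intercept/random-slope outcome trajectories, conversion events, and
#' monotone staged biomarker trajectories. Defaults are the study conditions
#' under which the pipeline's statistical guarantees are tested; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_subjects number of subjects (one baseline CSF sample each).
#' @param n_proteins number of simulated proteins.
#' @param n_batches number of TMT batches (plexes), assigned round-robin.
#' @param batch_log2_sd sd of per-batch multiplicative effects on the log2
#'   scale.
#' @param sample_load_sd sd of per-sample loading factors (log2 scale).
#' @param noise_sd residual log2 sd.
#' @param frac_differential fraction of proteins with a planted group effect.
#' @param effect_log2 magnitude of the planted converter-vs-stable difference
#'   (log2 units; signs are randomized per protein).
#' @param n_modules,module_size co-expression modules: number and size.
#'   `n_modules * module_size` must not exceed `n_proteins`.
#' @param module_loading loading of the shared module-level latent factor that
#'   induces within-module correlation.
#' @param missing_mcar fraction of cells set missing completely at random.
#' @param missing_mnar_quantile intensities below this global quantile are set
#'   missing (intensity-dependent missingness).
#' @param slope_fixed population slope of the longitudinal outcome
#'   (units/month).
#' @param slope_sd sd of subject-specific random slopes.
#' @param intercept_sd sd of subject-specific random intercepts.
#' @param outcome_noise_sd residual sd of the longitudinal outcome.
#' @param visit_months strictly increasing visit schedule (months from
#'   baseline).
#' @param conversion_frac probability that a subject is a converter.
#' @param ebm_z post-event biomarker mean, in z units.
#' @param ebm_sigma biomarker sd around the pre/post-event means.
#' @param seed integer seed; identical configs (including seed) give
#'   bit-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 300, n_proteins = 200, n_batches = 10,
                       batch_log2_sd = 1.0, sample_load_sd = 0.25,
                       noise_sd = 0.5, frac_differential = 0.1,
                       effect_log2 = 1.0, n_modules = 5, module_size = 20,
                       module_loading = 0.5,
                       missing_mcar = 0.05, missing_mnar_quantile = 0.05,
                       slope_fixed = 0.2, slope_sd = 0.1, intercept_sd = 1.0,
                       outcome_noise_sd = 1.0, visit_months = c(0, 12, 25),
                       conversion_frac = 0.3, ebm_z = 2, ebm_sigma = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_proteins = check_count(n_proteins, "n_proteins"),
    n_batches = check_count(n_batches, "n_batches"),
    batch_log2_sd = check_nonneg(batch_log2_sd, "batch_log2_sd"),
    sample_load_sd = check_nonneg(sample_load_sd, "sample_load_sd"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    frac_differential = check_fraction(frac_differential, "frac_differential"),
    effect_log2 = effect_log2,
    n_modules = check_count(n_modules, "n_modules"),
    module_size = check_count(module_size, "module_size"),
    module_loading = check_nonneg(module_loading, "module_loading"),
    missing_mcar = check_fraction(missing_mcar, "missing_mcar"),
    missing_mnar_quantile = check_fraction(missing_mnar_quantile,
                                           "missing_mnar_quantile"),
    slope_fixed = slope_fixed,
    slope_sd = check_nonneg(slope_sd, "slope_sd"),
    intercept_sd = check_nonneg(intercept_sd, "intercept_sd"),
    outcome_noise_sd = check_nonneg(outcome_noise_sd, "outcome_noise_sd"),
    visit_months = visit_months,
    conversion_frac = check_fraction(conversion_frac, "conversion_frac"),
    ebm_z = ebm_z,
    ebm_sigma = check_nonneg(ebm_sigma, "ebm_sigma"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(effect_log2) || length(effect_log2) != 1L) {
    rlang::abort("`effect_log2` must be a single real number.",
                 class = "csfprog_config_error")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_proteins) {
    rlang::abort("`module_size` x `n_modules` must not exceed `n_proteins`.",
                 class = "csfprog_config_error")
  }
  if (length(visit_months) < 1L || any(diff(visit_months) <= 0)) {
    rlang::abort("`visit_months` must be non-empty and strictly increasing.",
                 class = "csfprog_config_error")
  }
  if (cfg$ebm_z == 0) {
    rlang::abort("`ebm_z` must be nonzero.", class = "csfprog_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Generate baseline cohort metadata and conversion ground truth
#'
#' One baseline CSF sample per subject; batches assigned round-robin;
#' converter/stable group labels drawn with probability `conversion_frac`;
#' conversion times drawn uniformly over \[6, max follow-up\] months for
#' converters. CSF Aβ42 and pTau181 (pg/mL), APOE ε4 dose and age are drawn
#' from plausible marginal distributions so the Aβ42/pTau181 ratio straddles
#' the AT cutoff.
#'
#' @param config a [sim_config()].
#' @return list with `meta` (tibble of sample metadata) and `truth` (the
#'   in-progress ground-truth list; see [simulate_study()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_subjects
    subject_id <- sprintf("S%04d", seq_len(n))
    sample_id <- sprintf("CSF%04d", seq_len(n))
    batch_id <- sprintf("B%02d", ((seq_len(n) - 1L) %% config$n_batches) + 1L)
    converter <- rbinom(n, 1L, config$conversion_frac) == 1L
    max_fu <- max(config$visit_months)
    conversion_months <- ifelse(converter,
                                runif(n, min = min(6, max_fu), max = max_fu),
                                NA_real_)
    meta <- tibble::tibble(
      sample_id = sample_id,
      subject_id = subject_id,
      batch_id = batch_id,
      group = ifelse(converter, "converter", "stable"),
      diagnosis = sample(c("CU", "MCI"), n, replace = TRUE),
      abeta42 = stats::rlnorm(n, log(1000), 0.35),
      ptau181 = stats::rlnorm(n, log(25), 0.30),
      apoe4_dose = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      age = round(rnorm(n, 73, 6), 1)
    )
    truth <- list(conversion_times = setNames(conversion_months, subject_id))
    list(meta = meta, truth = truth)
  })
}

#' Generate a multi-batch raw intensity matrix with planted structure
#'
#' log2 intensity = protein baseline + batch offset + sample loading +
#' module latent factor + group effect (differential proteins only) + noise;
#' exponentiated to raw intensities. Missingness (MCAR plus below-quantile
#' MNAR) is applied and encoded as zeros, matching the raw-input convention.
#'
#' @param meta sample metadata from [generate_cohort()].
#' @param truth the in-progress truth list from [generate_cohort()].
#' @param config a [sim_config()].
#' @return list with `abundance` (raw [abundance_matrix()], zeros = missing)
#'   and the augmented `truth` (`differential_effects`, `batch_factors`,
#'   `module_membership`).
#' @export
generate_proteome <- function(meta, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("batch_id", "group") %in% names(meta))) {
    rlang::abort("`meta` must have `batch_id` and `group` columns.")
  }
  withr::with_seed(config$seed + 1L, {
    p <- config$n_proteins
    n <- nrow(meta)
    protein_id <- sprintf("P%04d", seq_len(p))
    batches <- sort(unique(meta$batch_id))

    module_membership <- rep(NA_character_, p)
    idx <- seq_len(config$n_modules * config$module_size)
    module_membership[idx] <- rep(sprintf("M%02d", seq_len(config$n_modules)),
                                  each = config$module_size)
    names(module_membership) <- protein_id

    n_diff <- round(config$frac_differential * p)
    diff_idx <- if (n_diff > 0) sample.int(p, n_diff) else integer(0)
    effects <- setNames(rep(0, p), protein_id)
    effects[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE) *
      config$effect_log2

    batch_factors <- setNames(rnorm(length(batches), 0, config$batch_log2_sd),
                              batches)
    loading <- rnorm(n, 0, config$sample_load_sd)
    baseline <- rnorm(p, 20, 2)
    g <- as.numeric(meta$group == "converter")

    log2m <- matrix(baseline, p, n) +
      matrix(batch_factors[meta$batch_id], p, n, byrow = TRUE) +
      matrix(loading, p, n, byrow = TRUE) +
      outer(effects, g) +
      matrix(rnorm(p * n, 0, config$noise_sd), p, n)

    if (config$n_modules > 0 && config$module_loading > 0) {
      latent <- matrix(rnorm(config$n_modules * n), config$n_modules, n)
      for (m in seq_len(config$n_modules)) {
        rows <- which(module_membership == sprintf("M%02d", m))
        log2m[rows, ] <- log2m[rows, ] +
          config$module_loading * matrix(latent[m, ], length(rows), n,
                                         byrow = TRUE)
      }
    }

    intensity <- 2^log2m
    dimnames(intensity) <- list(protein_id, meta$sample_id)

    if (config$missing_mnar_quantile > 0) {
      thr <- quantile(intensity, config$missing_mnar_quantile)
      intensity[intensity < thr] <- 0
    }
    if (config$missing_mcar > 0) {
      mcar <- matrix(runif(p * n) < config$missing_mcar, p, n)
      intensity[mcar] <- 0
    }

    truth$differential_effects <- effects[effects != 0]
    truth$batch_factors <- batch_factors
    truth$module_membership <- module_membership
    list(abundance = abundance_matrix(intensity, scale = "raw"),
         truth = truth)
  })
}

#' Generate random-intercept/random-slope longitudinal outcomes
#'
#' Each subject's series follows `y_ij = (b0 + u0_i) + (b1 + u1_i) t_ij +
#' e_ij` with `b1 = slope_fixed`, `sd(u1) = slope_sd`, `sd(u0) =
#' intercept_sd`, `sd(e) = outcome_noise_sd` and visits at
#' `config$visit_months`. The true per-subject slope `b1 + u1_i` is stored in
#' the truth.
#'
#' @inheritParams generate_proteome
#' @param outcome_name label recorded in the long table.
#' @param intercept_fixed population intercept.
#' @return list with `outcomes` (long tibble: subject_id, outcome_name,
#'   months, value) and augmented `truth` (`true_slopes`).
#' @export
generate_longitudinal_outcomes <- function(meta, truth, config,
                                           outcome_name = "ADAS-Cog11",
                                           intercept_fixed = 10) {
  stopifnot(inherits(config, "sim_config"))
  tm <- config$visit_months
  if (length(tm) < 1L || any(diff(tm) <= 0)) {
    rlang::abort("`visit_months` must be strictly increasing.",
                 class = "csfprog_config_error")
  }
  withr::with_seed(config$seed + 2L, {
    n <- nrow(meta)
    u0 <- rnorm(n, 0, config$intercept_sd)
    u1 <- rnorm(n, 0, config$slope_sd)
    true_slope <- config$slope_fixed + u1
    outcomes <- tidyr::expand_grid(subject_id = meta$subject_id,
                                   months = tm) |>
      dplyr::mutate(
        outcome_name = outcome_name,
        value = (intercept_fixed + rep(u0, each = length(tm))) +
          rep(true_slope, each = length(tm)) * .data$months +
          rnorm(n * length(tm), 0, config$outcome_noise_sd)
      ) |>
      dplyr::select("subject_id", "outcome_name", "months", "value")
    ts <- setNames(true_slope, meta$subject_id)
    truth$true_slopes <- c(truth$true_slopes,
                           setNames(list(ts), outcome_name))
    list(outcomes = outcomes, truth = truth)
  })
}

#' Generate staged biomarker data for ordering recovery
#'
#' Each subject is assigned a stage k uniform on `{0..N}`; biomarker i takes
#' value `Normal(ebm_z, ebm_sigma)` if its position in the true event sequence
#' is `<= k`, else `Normal(0, ebm_sigma)`.
#'
#' @param config a [sim_config()].
#' @param n_biomarkers number of biomarkers N (>= 2).
#' @param n_subjects number of staged subjects (defaults to
#'   `config$n_subjects`).
#' @return list with `z` (subjects x biomarkers matrix) and `truth`
#'   (`true_sequence`: ordered biomarker names; `true_stages`: named integer
#'   vector).
#' @export
generate_staging_data <- function(config, n_biomarkers = 10,
                                  n_subjects = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  n_biomarkers <- check_count(n_biomarkers, "n_biomarkers", min = 2L)
  withr::with_seed(config$seed + 3L, {
    biomarkers <- sprintf("BM%02d", seq_len(n_biomarkers))
    true_sequence <- sample(biomarkers)
    position <- match(biomarkers, true_sequence)   # event position of each marker
    stages <- sample(0:n_biomarkers, n_subjects, replace = TRUE)
    mu <- outer(stages, position, FUN = function(k, pos) {
      ifelse(pos <= k, config$ebm_z, 0)
    })
    z <- mu + matrix(rnorm(n_subjects * n_biomarkers, 0, config$ebm_sigma),
                     n_subjects, n_biomarkers)
    dimnames(z) <- list(sprintf("S%04d", seq_len(n_subjects)), biomarkers)
    list(z = z,
         truth = list(true_sequence = true_sequence,
                      true_stages = setNames(stages, rownames(z))))
  })
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper running [generate_cohort()], [generate_proteome()],
#' [generate_longitudinal_outcomes()] and [generate_staging_data()] under one
#' config, returning every input the pipeline consumes plus the complete
#' ground truth.
#'
#' @param config a [sim_config()].
#' @param n_biomarkers number of staged biomarkers.
#' @return list with `meta`, `abundance`, `outcomes`, `staging` (z matrix) and
#'   `truth`.
#' @export
simulate_study <- function(config, n_biomarkers = 10) {
  ch <- generate_cohort(config)
  pr <- generate_proteome(ch$meta, ch$truth, config)
  lo <- generate_longitudinal_outcomes(ch$meta, pr$truth, config)
  st <- generate_staging_data(config, n_biomarkers = n_biomarkers)
  truth <- lo$truth
  truth$true_sequence <- st$truth$true_sequence
  truth$true_stages <- st$truth$true_stages
  list(meta = ch$meta, abundance = pr$abundance, outcomes = lo$outcomes,
       staging = st$z, truth = truth)
}
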