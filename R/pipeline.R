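#' Pipeline configuration
#'
#' One nested list drives the full pipeline. A single global `seed` is
#' expanded deterministically into per-stage seeds; every stage records its
#' seed in the run manifest. Stage-level parameters mirror the corresponding
#' function arguments; `stages` toggles whole stages off. Defaults are sized
#' for a quick, fully reproducible synthetic run.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed.
#' @param sim named list of [sim_config()] overrides.
#' @param stages named list of logical stage toggles (`simulate`,
#'   `preprocess`, `trajectories`, `differential`, `enrichment`, `panels`,
#'   `staging`).
#' @param tampor_args,regress_args,dap_args,enrichment_args,panel_args,staging_args
#'   named lists of per-stage parameter overrides.
#' @param inputs optional named list of pre-existing input files
#'   (`abundance`, `meta`, `outcomes`) used when `stages$simulate` is off.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = list(),
                            stages = list(), tampor_args = list(),
                            regress_args = list(), dap_args = list(),
                            enrichment_args = list(), panel_args = list(),
                            staging_args = list(), inputs = list()) {
  st <- modifyList(list(simulate = TRUE, preprocess = TRUE,
                        trajectories = TRUE, differential = TRUE,
                        enrichment = TRUE, panels = TRUE, staging = TRUE),
                   stages)
  structure(list(
    out_dir = out_dir, seed = check_count(seed, "seed", min = 0L), sim = sim,
    stages = st, tampor_args = tampor_args, regress_args = regress_args,
    dap_args = dap_args, enrichment_args = enrichment_args,
    panel_args = panel_args, staging_args = staging_args, inputs = inputs
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @param out_dir overrides the config's output directory when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) rlang::abort("config must define `out_dir`.")
  do.call(pipeline_config, y)
}

write_tsv_det <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# JSON keeps names only on objects, not arrays: convert named atomic vectors
# (recursively) to named lists before writing ground truth.
named_to_list <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else if (is.list(x)) lapply(x, named_to_list)
  else x
}

read_truth <- function(path) {
  truth <- jsonlite::read_json(path)
  relist <- function(x) {
    if (is.list(x) && length(x) && all(lengths(x) <= 1L) &&
        !is.null(names(x))) {
      unlist(lapply(x, function(v) if (is.null(v)) NA else v))
    } else if (is.list(x)) lapply(x, relist) else x
  }
  relist(truth)
}

#' Run the full prognostics pipeline
#'
#' Executes simulate (optional) -> preprocess -> trajectories -> differential
#' -> enrichment -> panels -> staging, exchanging data between stages only
#' through the declared files under `config$out_dir`, and writes a
#' `manifest.json` recording the package version, per-stage seeds and
#' parameters, and the MD5 digest of every output file. Reruns with the same
#' config produce a bit-identical manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  seeds <- setNames(derive_seeds(config$seed, 7L),
                    c("simulate", "preprocess", "trajectories", "differential",
                      "enrichment", "panels", "staging"))
  manifest <- list(package = "csfprog",
                   version = as.character(utils::packageVersion("csfprog")),
                   seed = config$seed, stage_seeds = as.list(seeds),
                   stages = list(), files = list())
  fail <- function(stage, msg) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, msg))
  }
  need <- function(path, stage) {
    if (!file.exists(path)) fail(stage, sprintf("missing upstream output '%s'",
                                                basename(path)))
    path
  }

  # --- simulate ---------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    sim_cfg <- do.call(sim_config,
                       modifyList(list(seed = seeds[["simulate"]]), config$sim))
    study <- simulate_study(sim_cfg)
    write_abundance(study$abundance, od("abundance_raw.tsv"))
    write_tsv_det(study$meta, od("meta.tsv"))
    write_tsv_det(study$outcomes, od("outcomes.tsv"))
    write_tsv_det(data.frame(subject_id = rownames(study$staging),
                             study$staging, check.names = FALSE),
                  od("staging_z.tsv"))
    jsonlite::write_json(named_to_list(study$truth), od("truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest$stages$simulate <- list(
      n_subjects = sim_cfg$n_subjects, n_proteins = sim_cfg$n_proteins,
      n_batches = sim_cfg$n_batches)
  }

  meta_path <- config$inputs$meta %||% od("meta.tsv")
  abund_path <- config$inputs$abundance %||% od("abundance_raw.tsv")
  outcomes_path <- config$inputs$outcomes %||% od("outcomes.tsv")

  # --- preprocess -------------------------------------------------------
  if (isTRUE(config$stages$preprocess)) {
    meta <- utils::read.delim(need(meta_path, "preprocess"))
    m <- read_abundance(need(abund_path, "preprocess"), scale = "raw")
    m <- scale_sample_loading(m)
    m <- zeros_to_missing(m)
    m <- filter_quantified(m, min_frac = 0.5)
    m <- do.call(tampor, c(list(m = m, meta = meta), config$tampor_args))
    design <- data.frame(sample_id = meta$sample_id, batch = meta$batch_id)
    m <- do.call(bootstrap_regress_covariates,
                 c(list(m = m, design = design,
                        seed = seeds[["preprocess"]]),
                   config$regress_args))
    write_abundance(m, od("abundance_norm.tsv"), na_as = NA)
    manifest$stages$preprocess <- list(
      n_proteins = nrow(m$values),
      tampor_iterations = attr(m, "iterations") %||% NA)
  }

  # --- trajectories -----------------------------------------------------
  if (isTRUE(config$stages$trajectories)) {
    outcomes <- utils::read.delim(need(outcomes_path, "trajectories"))
    kept <- select_longitudinal(outcomes)
    slopes <- kept |>
      dplyr::group_split(.data$outcome_name) |>
      purrr::map_dfr(fit_subject_slopes) |>
      trim_outlier_slopes()
    labels <- slopes |>
      dplyr::group_by(.data$outcome_name) |>
      dplyr::group_modify(function(df, key) {
        median_split(df, outcome_worsening_sign(key$outcome_name))
      }) |>
      dplyr::ungroup()
    write_tsv_det(slopes, od("slopes.tsv"))
    write_tsv_det(labels, od("progression_labels.tsv"))
    manifest$stages$trajectories <- list(n_subjects = nrow(slopes))
  }

  # --- differential -----------------------------------------------------
  if (isTRUE(config$stages$differential)) {
    m <- read_abundance(need(od("abundance_norm.tsv"), "differential"),
                        scale = "log2")
    meta <- utils::read.delim(need(meta_path, "differential"))
    trait <- setNames(as.numeric(meta$group == "converter"), meta$sample_id)
    dap <- do.call(dap_linear, c(list(m = m, trait = trait), config$dap_args))
    write_tsv_det(dap, od("dap.tsv"))

    slopes <- utils::read.delim(need(od("slopes.tsv"), "differential"))
    slopes$sample_id <- setNames(meta$sample_id,
                                 meta$subject_id)[slopes$subject_id]
    pr <- pearson_rank(m, slopes[!is.na(slopes$sample_id), ])
    write_tsv_det(pr, od("pearson_rank.tsv"))

    conv <- meta[meta$group == "converter", ]
    truth <- read_truth(od("truth.json"))
    tte <- -truth$conversion_times[conv$subject_id] / 12
    names(tte) <- conv$sample_id
    mt <- abundance_matrix(m$values[, conv$sample_id, drop = FALSE],
                           scale = "log2")
    tte_fit <- time_to_event_regression(mt, tte)
    write_tsv_det(tte_fit, od("time_to_event.tsv"))
    manifest$stages$differential <- list(
      n_tested = nrow(dap), n_p05 = sum(dap$p_value < 0.05))
  }

  # --- enrichment -------------------------------------------------------
  if (isTRUE(config$stages$enrichment)) {
    dap <- utils::read.delim(need(od("dap.tsv"), "enrichment"))
    truth <- read_truth(od("truth.json"))
    mm <- truth$module_membership
    membership <- tibble::tibble(protein_id = names(mm),
                                 module_id = unname(mm))
    enr <- do.call(module_enrichment_z,
                   c(list(p_values = setNames(dap$p_value, dap$protein_id),
                          membership = membership,
                          seed = seeds[["enrichment"]]),
                     modifyList(list(B = 2000), config$enrichment_args)))
    enr <- fdr_over_modules(enr)
    write_tsv_det(enr, od("enrichment.tsv"))
    manifest$stages$enrichment <- list(
      n_modules = nrow(enr), n_significant = sum(enr$significant))
  }

  # --- panels -----------------------------------------------------------
  if (isTRUE(config$stages$panels)) {
    m <- read_abundance(need(od("abundance_norm.tsv"), "panels"),
                        scale = "log2")
    meta <- utils::read.delim(need(meta_path, "panels"))
    m <- filter_completeness(m, 0.95)
    m <- knn_impute(m, k = 5)
    X <- t(m$values)
    y <- as.numeric(meta[match(rownames(X), meta$sample_id), "group"] ==
                      "converter")
    pa <- config$panel_args
    pargs <- list(n_boot = pa$n_boot %||% 100, threshold = pa$threshold %||% 0.9,
                  n_runs = pa$n_runs %||% 20, grid = pa$grid %||% default_rf_grid())
    sel <- stability_select(X, y, n_boot = pargs$n_boot,
                            threshold = pargs$threshold,
                            seed = seeds[["panels"]])
    panel <- sel$feature[sel$selected]
    if (length(panel) == 0L) {
      rlang::inform("panels: no feature reached the stability threshold; using the 5 most frequent.")
      panel <- head(sel$feature, 5)
    }
    ev <- evaluate_panel(X[, panel, drop = FALSE], y, n_runs = pargs$n_runs,
                         grid = pargs$grid, seed = seeds[["panels"]])
    write_tsv_det(as.data.frame(sel), od("panel_selection.tsv"))
    write_tsv_det(ev$runs, od("panel_aucs.tsv"))
    write_tsv_det(ev$roc, od("panel_roc.tsv"))
    manifest$stages$panels <- list(
      panel = panel, median_auc = ev$median_auc,
      auc_lo = ev$auc_ci[1], auc_hi = ev$auc_ci[2])
  }

  # --- staging ----------------------------------------------------------
  if (isTRUE(config$stages$staging)) {
    zt <- utils::read.delim(need(od("staging_z.tsv"), "staging"),
                            check.names = FALSE)
    Z <- as.matrix(zt[, -1, drop = FALSE])
    rownames(Z) <- zt[[1]]
    sargs <- modifyList(list(n_restarts = 5, mcmc_iters = 2000),
                        config$staging_args)
    cfg <- event_model_config(n_restarts = sargs$n_restarts,
                              mcmc_iters = sargs$mcmc_iters,
                              seed = seeds[["staging"]])
    es <- fit_event_sequence(Z, cfg)
    write_tsv_det(tibble::tibble(position = seq_along(es$order),
                                 biomarker = es$order),
                  od("event_order.tsv"))
    write_tsv_det(data.frame(biomarker = rownames(es$positional_probability),
                             es$positional_probability, check.names = FALSE),
                  od("positional_probability.tsv"))
    write_tsv_det(data.frame(subject_id = rownames(es$stage_posterior),
                             map_stage = es$map_stages,
                             es$stage_posterior, check.names = FALSE),
                  od("stage_posteriors.tsv"))
    manifest$stages$staging <- list(
      order = es$order, log_likelihood = es$log_likelihood,
      acceptance_rate = es$acceptance_rate)
  }

  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        od("manifest.json")))
  manifest$files <- lapply(setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(manifest)
}
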