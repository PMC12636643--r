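# Vectorized simple linear regression of every protein row on one predictor.
# Exact OLS sums over observed cells only; returns one row per protein.
ols_by_protein <- function(values, x) {
  stopifnot(ncol(values) == length(x))
  M <- !is.na(values)
  Y <- values
  Y[!M] <- 0
  n <- unname(rowSums(M))
  Sx <- as.vector(M %*% x)
  Sxx <- as.vector(M %*% x^2)
  Sy <- unname(rowSums(Y))
  Syy <- unname(rowSums(Y^2))
  Sxy <- as.vector(Y %*% x)
  denom <- n * Sxx - Sx^2
  beta1 <- (n * Sxy - Sx * Sy) / denom
  beta0 <- (Sy - beta1 * Sx) / n
  rss <- Syy - beta0 * Sy - beta1 * Sxy
  rss <- pmax(rss, 0)
  df <- n - 2
  sigma2 <- rss / df
  se <- sqrt(sigma2 * n / denom)
  t <- beta1 / se
  p <- 2 * pt(-abs(t), df)
  tibble::tibble(
    protein_id = rownames(values),
    intercept = beta0, coefficient = beta1, t_stat = t, p_value = p,
    n_obs = n, df = df
  )
}

#' Differentially abundant proteins by per-protein linear models
#'
#' For each protein, ordinary least squares of log2 abundance on the trait
#' (binary group membership coded 0/1, or a continuous phenotype such as a
#' rate of change), a two-sided t test on the trait coefficient, and
#' Benjamini–Hochberg adjustment across all tested proteins. For a binary
#' trait this is equivalent to a pooled two-sample t test per protein.
#'
#' @param m log2 [abundance_matrix()].
#' @param trait numeric, logical, or two-level factor/character vector aligned
#'   to the samples of `m` (names, if present, are used to align).
#' @param min_obs proteins observed in fewer samples are skipped.
#' @return a `dap_table` tibble: `protein_id`, `coefficient`, `t_stat`,
#'   `p_value`, `q_value`, `direction`, `n_obs`. Skipped proteins are
#'   reported in the `"skipped"` attribute.
#' @export
dap_linear <- function(m, trait, min_obs = 4) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  if (!is.null(names(trait))) trait <- trait[colnames(vals)]
  if (length(trait) != ncol(vals)) {
    rlang::abort("`trait` must align to the samples of `m`.")
  }
  if (is.character(trait) || is.factor(trait) || is.logical(trait)) {
    f <- factor(trait)
    if (nlevels(f) != 2L) rlang::abort("categorical `trait` must have 2 levels.")
    if (min(table(f)) < 3L) {
      rlang::abort("need at least 3 samples per binary trait level.")
    }
    trait <- as.numeric(f) - 1
  }
  if (var(trait) == 0) rlang::abort("`trait` is constant; no contrast to test.")

  ok <- rowSums(!is.na(vals)) >= min_obs
  skipped <- rownames(vals)[!ok]
  res <- ols_by_protein(vals[ok, , drop = FALSE], trait) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"),
                  direction = sign(.data$coefficient)) |>
    dplyr::select("protein_id", "coefficient", "t_stat", "p_value",
                  "q_value", "direction", "n_obs")
  attr(res, "skipped") <- skipped
  class(res) <- c("dap_table", class(res))
  res
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment, aligned to the input
#' order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Rank proteins by Pearson correlation with per-subject slopes
#'
#' Computes the Pearson correlation between each protein's abundance and the
#' per-subject rate of change, ranks proteins by `|r|` within each outcome,
#' and flags the `top_k` strongest. The union of top proteins across outcomes
#' (the heatmap row set) is attached as attribute `"top_union"`.
#'
#' @param m log2 [abundance_matrix()]; columns are baseline samples.
#' @param slopes tibble with `sample_id` (matching columns of `m`),
#'   `outcome_name` and `slope`.
#' @param top_k number of top-ranked proteins flagged per outcome.
#' @param min_pairs minimum paired observations to compute a correlation.
#' @return tibble `protein_id`, `outcome_name`, `r`, `n_pairs`, `rank`, `top`.
#' @export
pearson_rank <- function(m, slopes, top_k = 30, min_pairs = 3) {
  stopifnot(inherits(m, "abundance_matrix"))
  stopifnot(all(c("sample_id", "outcome_name", "slope") %in% names(slopes)))
  res <- slopes |>
    dplyr::group_by(.data$outcome_name) |>
    dplyr::group_modify(function(df, key) {
      ids <- intersect(df$sample_id, colnames(m$values))
      if (length(ids) < min_pairs) {
        rlang::abort("too few samples with both abundance and slope.")
      }
      sl <- setNames(df$slope, df$sample_id)[ids]
      sub <- m$values[, ids, drop = FALSE]
      r <- suppressWarnings(
        as.vector(cor(t(sub), sl, use = "pairwise.complete.obs")))
      np <- rowSums(!is.na(sweep(sub, 2, sl, function(a, b) a + b)))
      out <- tibble::tibble(protein_id = rownames(sub), r = r, n_pairs = np)
      out <- out[!is.na(out$r) & out$n_pairs >= min_pairs, , drop = FALSE]
      out$rank <- rank(-abs(out$r), ties.method = "first")
      out$top <- out$rank <= top_k
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "outcome_name", "r", "n_pairs", "rank", "top")
  attr(res, "top_union") <- unique(res$protein_id[res$top])
  res
}

#' Group-level regression of protein abundance on time to event
#'
#' Cross-sectional regression across converters of log2 abundance on each
#' subject's time-to-event in years (0 at the event, negative before it).
#' Proteins are ranked by p-value and the top `top_k` flagged for
#' visualization; intercept and slope define the fitted line.
#'
#' @param m log2 [abundance_matrix()] restricted to converters (columns).
#' @param tte_years numeric vector aligned to the samples of `m` (names used
#'   to align when present); 0 at the event, negative before.
#' @param top_k number of proteins flagged by smallest p-value.
#' @return tibble `protein_id`, `intercept`, `slope_per_year`, `t_stat`,
#'   `p_value`, `rank`, `top`.
#' @export
time_to_event_regression <- function(m, tte_years, top_k = 10) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  if (!is.null(names(tte_years))) tte_years <- tte_years[colnames(vals)]
  if (length(tte_years) != ncol(vals)) {
    rlang::abort("`tte_years` must align to the samples of `m`.")
  }
  if (ncol(vals) < 3L) rlang::abort("need at least 3 converters.")
  if (var(tte_years) == 0) rlang::abort("all `tte_years` are equal.")
  res <- ols_by_protein(vals, tte_years) |>
    dplyr::rename(slope_per_year = "coefficient") |>
    dplyr::mutate(rank = rank(.data$p_value, ties.method = "first"),
                  top = .data$rank <= top_k) |>
    dplyr::select("protein_id", "intercept", "slope_per_year", "t_stat",
                  "p_value", "rank", "top")
  res
}
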