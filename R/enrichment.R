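#' Permutation Z-score enrichment of protein p-values in modules
#'
#' Tests whether the proteins of each brain co-expression module have smaller
#' association p-values than random same-sized protein sets drawn from the
#' tested background. The observed statistic is the mean p-value of module
#' members present in the background; the null distribution is built from `B`
#' draws without replacement of equally many proteins. The Z score is the
#' difference between the permuted and observed mean p-values normalized by
#' the permutation standard deviation, oriented so that enrichment for small
#' p-values is positive. The permutation p-value uses the exact-test
#' convention `p = (count(perm <= observed) + 1) / (B + 1)`, which is bounded
#' below by `1/(B+1)`. When the number of distinct member subsets
#' `choose(n_background, n_members)` is at most `exhaustive_limit`, all
#' subsets are enumerated instead of sampled.
#'
#' @param p_values named numeric vector of protein-level p-values (the tested
#'   background).
#' @param membership tibble with `protein_id`, `module_id` (each protein in at
#'   most one module).
#' @param B number of Monte-Carlo permutations.
#' @param seed integer seed.
#' @param direction_subset `"all"`, `"increased"` or `"decreased"`; the latter
#'   two restrict the background and members to proteins whose association
#'   sign (given in `directions`) is positive or negative before testing.
#' @param directions named sign vector (+1/-1), required unless
#'   `direction_subset = "all"`.
#' @param min_members modules with fewer tested members are dropped.
#' @param exhaustive_limit enumerate all subsets when feasible.
#' @param replace sample the null with replacement instead (off by default).
#' @return an `enrichment_result` tibble: `module_id`, `n_members_tested`,
#'   `observed_mean_p`, `perm_mean`, `perm_sd`, `z`, `p_perm`, `degenerate`,
#'   `direction_subset`.
#' @export
module_enrichment_z <- function(p_values, membership, B = 10000, seed = 1L,
                                direction_subset = c("all", "increased",
                                                     "decreased"),
                                directions = NULL, min_members = 2,
                                exhaustive_limit = 10000, replace = FALSE) {
  direction_subset <- match.arg(direction_subset)
  if (is.null(names(p_values))) rlang::abort("`p_values` must be named.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  p_values <- p_values[!is.na(p_values)]
  if (direction_subset != "all") {
    if (is.null(directions)) {
      rlang::abort("`directions` is required for a signed subset.")
    }
    want <- if (direction_subset == "increased") 1 else -1
    keep <- names(directions)[sign(directions) == want]
    p_values <- p_values[names(p_values) %in% keep]
  }
  bg <- names(p_values)
  if (anyDuplicated(membership$protein_id)) {
    rlang::abort("each protein may belong to at most one module.")
  }

  mods <- membership |>
    dplyr::filter(!is.na(.data$module_id), .data$protein_id %in% bg) |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(members = list(.data$protein_id), .groups = "drop") |>
    dplyr::filter(lengths(.data$members) >= min_members)
  if (nrow(mods) == 0L) rlang::abort("no module has enough tested members.")

  pv <- unname(p_values)
  nbg <- length(pv)
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(mods)), function(i) {
      mem <- mods$members[[i]]
      msize <- length(mem)
      if (msize > nbg) {
        rlang::abort("background must be at least as large as the module.")
      }
      obs <- mean(p_values[mem])
      n_comb <- suppressWarnings(choose(nbg, msize))
      if (!replace && is.finite(n_comb) && n_comb <= exhaustive_limit) {
        perm <- colMeans(matrix(pv[combn(nbg, msize)], nrow = msize))
        B_eff <- length(perm)
        mode <- "exhaustive"
      } else {
        perm <- vapply(seq_len(B), function(b) {
          mean(pv[sample.int(nbg, msize, replace = replace)])
        }, numeric(1))
        B_eff <- B
        mode <- "monte_carlo"
      }
      pm <- mean(perm)
      psd <- sd(perm)
      degenerate <- !is.finite(psd) || psd == 0
      z <- if (degenerate) 0 else (pm - obs) / psd
      tibble::tibble(
        module_id = mods$module_id[i], n_members_tested = msize,
        observed_mean_p = obs, perm_mean = pm,
        perm_sd = ifelse(degenerate, 0, psd), z = z,
        p_perm = (sum(perm <= obs) + 1) / (B_eff + 1),
        degenerate = degenerate, mode = mode
      )
    })
  })
  res$direction_subset <- direction_subset
  class(res) <- c("enrichment_result", class(res))
  res
}

#' FDR control across modules
#'
#' Benjamini–Hochberg adjustment of the permutation p-values across modules;
#' modules with `q < alpha` are significant. The smallest Z among significant
#' modules (the plotted threshold line) is attached as attribute
#' `"z_threshold"`.
#'
#' @param results an `enrichment_result` table from [module_enrichment_z()].
#' @param alpha FDR level.
#' @return the table with `q_value` and `significant` columns added.
#' @export
fdr_over_modules <- function(results, alpha = 0.05) {
  if (nrow(results) < 1L) rlang::abort("need at least one module.")
  results$q_value <- bh_fdr(results$p_perm)
  results$significant <- results$q_value < alpha
  attr(results, "z_threshold") <-
    if (any(results$significant)) min(results$z[results$significant]) else NA_real_
  class(results) <- unique(c("enrichment_result", class(results)))
  results
}
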