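as_feature_df <- function(X, what = "X") {
  X <- as.data.frame(X)
  if (is.null(colnames(X)) || any(colnames(X) == "")) {
    rlang::abort(sprintf("`%s` must have column (feature) names.", what))
  }
  X
}

# stratified indices: for each class, `frac` of its members (at least 1)
stratified_test_idx <- function(y, frac) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    sample(idx, max(1L, round(frac * length(idx))))
  }), use.names = FALSE)
}

#' Default random-forest tuning grid
#'
#' Trees in \{100, 300, 500\} and maximum depth in \{3, 5, unlimited\}
#' (`0` codes unlimited).
#'
#' @return data frame with `num_trees` and `max_depth` columns.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100, 300, 500), max_depth = c(3, 5, 0))
}

fit_rf <- function(X, y, num_trees, max_depth, seed) {
  ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
    num.trees = num_trees,
    max.depth = if (max_depth > 0) max_depth else NULL,
    seed = seed, num.threads = 1
  )
}

rf_score <- function(model, X) {
  predict(model, data = X, num.threads = 1)$predictions[, "1"]
}

#' Bootstrap-stability LASSO panel selection
#'
#' On each of `n_boot` class-stratified bootstrap resamples, an L1-penalized
#' logistic regression is fit with the penalty chosen by internal
#' cross-validation (`lambda.1se`), and the features with nonzero coefficients
#' are recorded. A feature's selection frequency is the fraction of bootstraps
#' selecting it; the panel is the set with frequency at or above `threshold`.
#'
#' @param X complete samples x features matrix or data frame (impute first;
#'   see [knn_impute()]).
#' @param y binary labels (see [roc_auc()] for accepted encodings).
#' @param n_boot number of bootstrap resamples.
#' @param threshold selection-frequency cutoff (inclusive).
#' @param nfolds folds for the internal `cv.glmnet`.
#' @param seed integer seed.
#' @return a `panel_selection` tibble: `feature`, `frequency`, `selected`,
#'   with `n_boot` and `threshold` attributes.
#' @export
stability_select <- function(X, y, n_boot = 100, threshold = 0.9,
                             nfolds = 5, seed = 1L) {
  X <- as_feature_df(X)
  if (anyNA(X)) {
    rlang::abort("`X` contains missing values; run knn_impute() first.")
  }
  y <- coerce_binary(y)
  if (length(unique(y)) != 2L) rlang::abort("both classes must be present.")
  Xm <- as.matrix(X)
  counts <- setNames(numeric(ncol(Xm)), colnames(Xm))
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- unlist(lapply(split(seq_along(y), y), function(i) {
          sample(i, length(i), replace = TRUE)
        }), use.names = FALSE)
        if (length(unique(y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      fit <- tryCatch(
        glmnet::cv.glmnet(Xm[idx, , drop = FALSE], y[idx],
                          family = "binomial", alpha = 1, nfolds = nfolds),
        error = function(e) NULL
      )
      if (is.null(fit)) { n_redrawn <- n_redrawn + 1L; next }
      beta <- coef(fit, s = "lambda.1se")[-1, 1]
      counts[beta != 0] <- counts[beta != 0] + 1
    }
  })
  if (n_redrawn > 0L) {
    rlang::inform(sprintf("stability_select: %d degenerate bootstraps redrawn or skipped.",
                          n_redrawn))
  }
  res <- tibble::tibble(feature = names(counts),
                        frequency = unname(counts) / n_boot) |>
    dplyr::mutate(selected = .data$frequency >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  attr(res, "n_boot") <- n_boot
  attr(res, "threshold") <- threshold
  class(res) <- c("panel_selection", class(res))
  res
}

#' Evaluate a feature panel with random forests over repeated splits
#'
#' For each of `n_runs` seeded stratified splits, a random-forest classifier
#' is tuned by grid search with `cv_folds`-fold cross-validation on the
#' training portion only, refit on the full training set, and scored on the
#' held-out test set; ROC, AUC and the Youden threshold are recorded per run.
#' The summary is the median AUC with a 2.5–97.5 percentile interval over
#' runs. With `select_fun` supplied, the panel is re-selected inside every
#' training split (nested mode) instead of being fixed up front.
#'
#' @param X samples x features matrix or data frame (complete).
#' @param y binary labels.
#' @param n_runs number of permuted train/test splits.
#' @param test_frac held-out fraction (0.2 by default; 0.3 for small cohorts
#'   such as tau-PET).
#' @param cv_folds folds for hyperparameter tuning.
#' @param grid data frame of `num_trees`, `max_depth` combinations (a single
#'   row skips tuning).
#' @param seed integer seed; split indices are reproducible from it.
#' @param select_fun optional `function(X_train, y_train) -> feature names`
#'   for nested selection.
#' @param keep_models keep the fitted forest of each run (memory-heavy).
#' @param .split_seeds internal: explicit per-run seeds, used to synchronize
#'   splits across evaluations (see [compare_predictor_sets()]).
#' @return a `panel_eval` object; see [tidy.panel_eval()] and
#'   [glance.panel_eval()].
#' @export
evaluate_panel <- function(X, y, n_runs = 100, test_frac = 0.2, cv_folds = 5,
                           grid = default_rf_grid(), seed = 1L,
                           select_fun = NULL, keep_models = FALSE,
                           .split_seeds = NULL) {
  X <- as_feature_df(X)
  if (anyNA(X)) rlang::abort("`X` contains missing values; impute first.")
  if (ncol(X) < 1L) rlang::abort("panel must contain at least one feature.")
  y <- coerce_binary(y)
  split_seeds <- .split_seeds %||% derive_seeds(seed, n_runs)
  if (length(split_seeds) != n_runs) {
    rlang::abort("`.split_seeds` must have length `n_runs`.")
  }

  runs <- vector("list", n_runs)
  rocs <- vector("list", n_runs)
  models <- if (keep_models) vector("list", n_runs) else NULL
  for (r in seq_len(n_runs)) {
    out <- withr::with_seed(split_seeds[r], {
      test <- stratified_test_idx(y, test_frac)
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L) {
        rlang::abort("degenerate split: a class is absent from train or test.")
      }
      Xt <- X
      if (!is.null(select_fun)) {
        feats <- select_fun(X[train, , drop = FALSE], y[train])
        if (length(feats) == 0L) feats <- colnames(X)
        Xt <- X[, feats, drop = FALSE]
      }
      best <- grid[1, , drop = FALSE]
      if (nrow(grid) > 1L) {
        folds <- integer(length(train))
        for (cls in unique(y[train])) {
          i <- which(y[train] == cls)
          folds[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
        }
        cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
          aucs <- vapply(seq_len(cv_folds), function(f) {
            tr <- train[folds != f]
            va <- train[folds == f]
            if (length(unique(y[va])) < 2L) return(NA_real_)
            m <- fit_rf(Xt[tr, , drop = FALSE], y[tr],
                        grid$num_trees[g], grid$max_depth[g],
                        seed = split_seeds[r] %% 10000L + g * 100L + f)
            roc_auc(rf_score(m, Xt[va, , drop = FALSE]), y[va])$auc
          }, numeric(1))
          mean(aucs, na.rm = TRUE)
        }, numeric(1))
        best <- grid[which.max(cv_auc), , drop = FALSE]
      }
      model <- fit_rf(Xt[train, , drop = FALSE], y[train],
                      best$num_trees, best$max_depth,
                      seed = split_seeds[r] %% 10000L + 7L)
      scores <- rf_score(model, Xt[test, , drop = FALSE])
      rc <- roc_auc(scores, y[test])
      yj <- youden_threshold(rc)
      list(row = tibble::tibble(
             run = r, auc = rc$auc, youden_threshold = yj$threshold,
             youden_j = yj$j, num_trees = best$num_trees,
             max_depth = best$max_depth, n_test = length(test)),
           roc = dplyr::mutate(rc$roc, run = r),
           model = if (keep_models) model else NULL,
           test = test)
    })
    runs[[r]] <- out$row
    rocs[[r]] <- out$roc
    if (keep_models) models[[r]] <- out$model
  }
  runs <- dplyr::bind_rows(runs)
  structure(list(
    runs = runs,
    roc = dplyr::bind_rows(rocs),
    median_auc = median(runs$auc),
    auc_ci = unname(quantile(runs$auc, c(0.025, 0.975))),
    n_runs = n_runs, test_frac = test_frac, seed = seed,
    split_seeds = split_seeds,
    mode = if (is.null(select_fun)) "fixed" else "nested",
    models = models
  ), class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  cat(sprintf(
    "<panel_eval> %d runs (%s panel), median AUC %.3f [%.3f-%.3f]\n",
    x$n_runs, x$mode, x$median_auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @rdname evaluate_panel
#' @param x a `panel_eval`.
#' @param ... unused.
#' @export
tidy.panel_eval <- function(x, ...) x$runs

#' @rdname evaluate_panel
#' @export
glance.panel_eval <- function(x, ...) {
  tibble::tibble(median_auc = x$median_auc, auc_lo = x$auc_ci[1],
                 auc_hi = x$auc_ci[2], n_runs = x$n_runs,
                 test_frac = x$test_frac, mode = x$mode)
}

#' Synchronized permutation comparison of two predictor sets
#'
#' Evaluates two feature blocks over identical train/test splits and compares
#' their median AUCs. The observed statistic is `delta = median AUC(A) -
#' median AUC(B)`. Under the null, the participant-to-feature-row assignment
#' of both blocks is shuffled by the same random permutation (labels fixed)
#' and the synced evaluation re-run; the two-sided p-value is
#' `(count(|delta_b| >= |delta_obs|) + 1) / (B + 1)`.
#'
#' @param X_A,X_B row-aligned feature blocks (samples x features).
#' @param y binary labels.
#' @param n_runs splits per evaluation.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param ... passed to [evaluate_panel()] (e.g. `grid`, `test_frac`).
#' @return a `panel_comparison` list: `delta_observed`, `p_value`,
#'   `median_auc_a`, `median_auc_b`, `deltas_null`.
#' @export
compare_predictor_sets <- function(X_A, X_B, y, n_runs = 100, B = 100,
                                   seed = 1L, ...) {
  X_A <- as_feature_df(X_A, "X_A")
  X_B <- as_feature_df(X_B, "X_B")
  if (nrow(X_A) != nrow(X_B) || nrow(X_A) != length(y)) {
    rlang::abort("`X_A`, `X_B` and `y` must be row-aligned.")
  }
  seeds <- derive_seeds(seed, B + 2L)
  split_seeds <- derive_seeds(seeds[1], n_runs)
  eval_pair <- function(A, B2) {
    ea <- evaluate_panel(A, y, n_runs = n_runs, seed = seed,
                         .split_seeds = split_seeds, ...)
    eb <- evaluate_panel(B2, y, n_runs = n_runs, seed = seed,
                         .split_seeds = split_seeds, ...)
    c(a = ea$median_auc, b = eb$median_auc)
  }
  obs <- eval_pair(X_A, X_B)
  delta_obs <- obs["a"] - obs["b"]
  deltas <- vapply(seq_len(B), function(b) {
    perm <- withr::with_seed(seeds[b + 2L], sample(nrow(X_A)))
    pr <- eval_pair(X_A[perm, , drop = FALSE], X_B[perm, , drop = FALSE])
    unname(pr["a"] - pr["b"])
  }, numeric(1))
  structure(list(
    delta_observed = unname(delta_obs),
    p_value = (sum(abs(deltas) >= abs(delta_obs)) + 1) / (B + 1),
    median_auc_a = unname(obs["a"]), median_auc_b = unname(obs["b"]),
    deltas_null = deltas, n_runs = n_runs, B = B, seed = seed
  ), class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat(sprintf(
    "<panel_comparison> delta = %.4f (A %.3f vs B %.3f), p = %.4f (%d perms)\n",
    x$delta_observed, x$median_auc_a, x$median_auc_b, x$p_value, x$B))
  invisible(x)
}

#' @rdname compare_predictor_sets
#' @param x a `panel_comparison`.
#' @param ... unused.
#' @export
glance.panel_comparison <- function(x, ...) {
  tibble::tibble(delta_observed = x$delta_observed, p_value = x$p_value,
                 median_auc_a = x$median_auc_a, median_auc_b = x$median_auc_b,
                 n_permutations = x$B)
}

#' Append conventional biomarkers to a protein panel
#'
#' Column-concatenates a protein feature block with conventional predictors
#' (e.g. age, APOE ε4 dose, CSF Aβ42 and pTau181), panel columns first, with
#' per-column provenance tracked in the `"provenance"` attribute.
#'
#' @param X_panel samples x proteins block.
#' @param conventional samples x biomarkers block, row-aligned.
#' @return combined data frame.
#' @export
combine_with_conventional <- function(X_panel, conventional) {
  X_panel <- as_feature_df(X_panel, "X_panel")
  if (is.null(conventional) || NCOL(conventional) == 0L) {
    attr(X_panel, "provenance") <- rep("panel", ncol(X_panel))
    return(X_panel)
  }
  conventional <- as_feature_df(conventional, "conventional")
  if (nrow(conventional) != nrow(X_panel)) {
    rlang::abort("`conventional` must be row-aligned to `X_panel`.")
  }
  if (any(colnames(conventional) %in% colnames(X_panel))) {
    rlang::abort("duplicate column names between panel and conventional block.")
  }
  out <- cbind(X_panel, conventional)
  attr(out, "provenance") <- c(rep("panel", ncol(X_panel)),
                               rep("conventional", ncol(conventional)))
  out
}
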