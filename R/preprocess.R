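#' Sample-loading normalization of raw intensities
#'
#' Divides each protein intensity by the intensity sum of all observed
#' proteins in that sample, then multiplies by the maximum per-sample
#' intensity sum, so that after scaling every sample has the same total
#' observed intensity. Missing cells are untouched.
#'
#' @param m raw [abundance_matrix()].
#' @return raw [abundance_matrix()] with equalized column sums.
#' @export
scale_sample_loading <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "raw") rlang::abort("`m` must be on the raw scale.")
  cs <- colSums(m$values, na.rm = TRUE)
  if (any(cs <= 0)) {
    bad <- colnames(m$values)[cs <= 0][1]
    rlang::abort(sprintf(
      "sample '%s' has no positive observed intensity; cannot scale.", bad))
  }
  vals <- sweep(m$values, 2, max(cs) / cs, `*`)
  abundance_matrix(vals, scale = "raw")
}

#' Treat zero intensities as missing values
#'
#' Raw TMT exports encode unquantified cells as zeros; this marks them missing
#' (`NA`).
#'
#' @param m raw [abundance_matrix()].
#' @return [abundance_matrix()] with zeros converted to `NA`.
#' @export
zeros_to_missing <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "raw") rlang::abort("`m` must be on the raw scale.")
  vals <- m$values
  vals[!is.na(vals) & vals == 0] <- NA_real_
  abundance_matrix(vals, scale = "raw")
}

#' Keep proteins quantified in at least a given fraction of samples
#'
#' @param m an [abundance_matrix()].
#' @param min_frac minimum observed fraction; the boundary is inclusive
#'   (a protein observed in exactly `min_frac` of samples is retained).
#' @return filtered [abundance_matrix()].
#' @export
filter_quantified <- function(m, min_frac = 0.5) {
  stopifnot(inherits(m, "abundance_matrix"))
  keep <- rowMeans(!is.na(m$values)) >= min_frac
  abundance_matrix(m$values[keep, , drop = FALSE], scale = m$scale)
}

#' Keep proteins observed in more than a given fraction of samples
#'
#' Completeness filter applied before machine-learning input assembly. The
#' inequality is strict: a protein observed in exactly `min_frac` of samples
#' is dropped.
#'
#' @inheritParams filter_quantified
#' @export
filter_completeness <- function(m, min_frac = 0.95) {
  stopifnot(inherits(m, "abundance_matrix"))
  keep <- rowMeans(!is.na(m$values)) > min_frac
  abundance_matrix(m$values[keep, , drop = FALSE], scale = m$scale)
}

#' TAMPOR: batch harmonization by iterative median polish of ratios
#'
#' Removes inter-batch technical variance while preserving biological
#' variance. Per protein and batch, intensities are expressed as ratios to the
#' median over that batch's denominator samples (all batch samples by default,
#' or a designated reference set per batch), log2-transformed, and then
#' subjected to an iterative two-way median polish: each protein's median
#' across samples and each sample's median across proteins are alternately
#' subtracted until the largest absolute row/column median falls below `tol`
#' or `max_iter` is reached. Because the per-batch ratio step cancels any
#' per-batch scalar exactly, the output is invariant to multiplying all
#' intensities of a batch by a constant.
#'
#' @param m raw [abundance_matrix()]; zeros, if any remain, are treated as
#'   missing.
#' @param meta sample metadata with `sample_id` and `batch_id` columns
#'   covering every sample in `m`.
#' @param denominator_mode `"all_batch_samples"` (default) or
#'   `"designated_samples"` (use `designated`).
#' @param designated character vector of sample ids forming the reference set;
#'   each batch must contain at least one.
#' @param tol convergence tolerance on the maximum absolute row/column median.
#' @param max_iter maximum polish iterations; non-convergence triggers a
#'   warning reporting the final delta.
#' @return log2 [abundance_matrix()] with row and column medians ~ 0. The
#'   number of iterations used is attached as attribute `"iterations"`.
#' @export
tampor <- function(m, meta,
                   denominator_mode = c("all_batch_samples",
                                        "designated_samples"),
                   designated = NULL, tol = 1e-8, max_iter = 250) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "raw") rlang::abort("`m` must be on the raw scale.")
  denominator_mode <- match.arg(denominator_mode)
  if (tol <= 0) rlang::abort("`tol` must be positive.")
  vals <- m$values
  vals[!is.na(vals) & vals == 0] <- NA_real_

  batch <- setNames(meta$batch_id, meta$sample_id)[colnames(vals)]
  if (anyNA(batch)) rlang::abort("every sample in `m` must appear in `meta`.")

  n_dropped <- 0L
  for (b in unique(batch)) {
    cols <- which(batch == b)
    den_cols <- cols
    if (denominator_mode == "designated_samples") {
      den_cols <- cols[colnames(vals)[cols] %in% designated]
      if (length(den_cols) == 0L) {
        rlang::abort(sprintf("batch '%s' has no designated denominator sample.", b))
      }
    }
    med <- apply(vals[, den_cols, drop = FALSE], 1L, median, na.rm = TRUE)
    bad <- is.na(med) | med <= 0
    if (any(bad)) {
      vals[bad, cols] <- NA_real_
      n_dropped <- n_dropped + sum(bad)
      med[bad] <- 1
    }
    vals[, cols] <- vals[, cols, drop = FALSE] / med
  }
  if (n_dropped > 0L) {
    rlang::warn(sprintf(
      "tampor: %d protein/batch blocks had missing or zero denominator medians; set missing.",
      n_dropped))
  }

  lm2 <- log2(vals)
  delta <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rmed <- apply(lm2, 1L, median, na.rm = TRUE)
    rmed[is.na(rmed)] <- 0
    lm2 <- lm2 - rmed
    cmed <- apply(lm2, 2L, median, na.rm = TRUE)
    cmed[is.na(cmed)] <- 0
    lm2 <- sweep(lm2, 2L, cmed)
    delta <- max(abs(c(rmed, cmed)))
    if (delta < tol) break
  }
  if (delta >= tol) {
    rlang::warn(sprintf(
      "tampor: median polish did not converge in %d iterations (delta = %.3g).",
      max_iter, delta))
  }
  out <- abundance_matrix(lm2, scale = "log2")
  attr(out, "iterations") <- iter
  out
}

#' Remove covariate effects by bootstrap regression
#'
#' Per protein, ordinary least squares of log2 abundance on the covariates is
#' fit on `n_boot` bootstrap resamples of the samples; the corrected value
#' subtracts each covariate multiplied by the median of its estimated
#' coefficients over bootstraps. Missing cells are excluded from the fits and
#' left missing. Categorical covariates are dummy-coded.
#'
#' @param m log2 [abundance_matrix()].
#' @param design data frame of covariates, one row per sample in `m` (aligned
#'   to columns of `m`; a `sample_id` column, if present, is used to align).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return corrected log2 [abundance_matrix()]. Proteins with fewer observed
#'   samples than coefficients are left uncorrected (warning).
#' @export
bootstrap_regress_covariates <- function(m, design, n_boot = 100, seed = 1L) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$scale != "log2") rlang::abort("`m` must be on the log2 scale.")
  design <- as.data.frame(design)
  if ("sample_id" %in% names(design)) {
    rownames(design) <- design$sample_id
    design <- design[colnames(m$values), setdiff(names(design), "sample_id"),
                     drop = FALSE]
  }
  if (nrow(design) != ncol(m$values)) {
    rlang::abort("`design` must have one row per sample.")
  }
  X <- model.matrix(~ ., data = design)   # intercept + dummy-coded covariates
  k <- ncol(X)
  vals <- m$values
  p <- nrow(vals)
  n_skipped <- 0L

  withr::with_seed(seed, {
    boot_idx <- replicate(n_boot, sample.int(ncol(vals), replace = TRUE),
                          simplify = FALSE)
    for (i in seq_len(p)) {
      obs <- which(!is.na(vals[i, ]))
      if (length(obs) <= k) { n_skipped <- n_skipped + 1L; next }
      betas <- matrix(NA_real_, n_boot, k)
      y <- vals[i, ]
      for (b in seq_len(n_boot)) {
        idx <- boot_idx[[b]][boot_idx[[b]] %in% obs]
        if (length(idx) <= k) next
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank < k) next
        betas[b, ] <- .lm.fit(Xb, y[idx])$coefficients
      }
      med <- apply(betas, 2L, median, na.rm = TRUE)
      if (anyNA(med)) { n_skipped <- n_skipped + 1L; next }
      med[1] <- 0   # intercept (protein level) is not removed
      vals[i, obs] <- y[obs] - as.vector(X[obs, , drop = FALSE] %*% med)
    }
  })
  if (n_skipped > 0L) {
    rlang::warn(sprintf(
      "bootstrap_regress_covariates: %d proteins left uncorrected (too few observed samples or rank-deficient fits).",
      n_skipped))
  }
  abundance_matrix(vals, scale = "log2")
}

#' K-nearest-neighbor imputation of missing abundances
#'
#' Each missing cell is replaced by the mean of the `k` nearest samples
#' (Euclidean distance over mutually observed proteins, scaled by the number
#' of shared proteins) that observe the protein in question. Observed cells
#' are never changed.
#'
#' @param m an [abundance_matrix()].
#' @param k number of neighbors.
#' @return complete [abundance_matrix()] (no missing cells).
#' @export
knn_impute <- function(m, k = 5) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  obs <- !is.na(vals)
  if (any(colSums(obs) == 0L)) {
    bad <- colnames(vals)[colSums(obs) == 0L][1]
    rlang::abort(sprintf("sample '%s' has no observed proteins.", bad))
  }
  if (!anyNA(vals)) return(m)

  v0 <- vals
  v0[!obs] <- 0
  # pairwise scaled squared distances over mutually observed proteins:
  # sum((x - y)^2 * shared) / n_shared, computed with matrix products
  cross <- crossprod(v0)                      # sum x*y over shared (zeros elsewhere)
  sq <- crossprod(v0^2, obs)                  # sum x^2 over y-observed
  shared <- crossprod(obs)
  d2 <- (sq + t(sq) - 2 * cross) / pmax(shared, 1L)
  d2[shared == 0L] <- Inf
  diag(d2) <- Inf

  out <- vals
  for (j in which(colSums(!obs) > 0L)) {
    miss_rows <- which(!obs[, j])
    ord <- order(d2[, j], seq_len(ncol(vals)))  # distance, index tie-break
    for (i in miss_rows) {
      donors <- ord[obs[i, ord] & is.finite(d2[ord, j])]
      if (length(donors) == 0L) {
        out[i, j] <- mean(vals[i, ], na.rm = TRUE)
        next
      }
      out[i, j] <- mean(vals[i, donors[seq_len(min(k, length(donors)))]])
    }
  }
  abundance_matrix(out, scale = m$scale)
}
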