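#' Event-model configuration
#'
#' Parameters of the single-subtype event-based staging model: each biomarker
#' jumps from mean 0 (pre-event) to mean `z_event` (post-event) in z units,
#' with sd `sigma`.
#'
#' @param z_event post-event mean, scalar or per-biomarker (nonzero).
#' @param sigma sd around the pre/post-event means, scalar or per-biomarker
#'   (positive).
#' @param n_restarts greedy ascents from random starting permutations.
#' @param mcmc_iters Metropolis iterations for positional uncertainty.
#' @param seed integer seed.
#' @return an `event_model_config` list.
#' @export
event_model_config <- function(z_event = 2, sigma = 1, n_restarts = 25,
                               mcmc_iters = 10000, seed = 1L) {
  if (any(z_event == 0)) rlang::abort("`z_event` must be nonzero.",
                                      class = "csfprog_config_error")
  if (any(sigma <= 0)) rlang::abort("`sigma` must be positive.",
                                    class = "csfprog_config_error")
  structure(list(z_event = z_event, sigma = sigma,
                 n_restarts = check_count(n_restarts, "n_restarts"),
                 mcmc_iters = check_count(mcmc_iters, "mcmc_iters"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "event_model_config")
}

#' Z-score biomarkers against a reference group
#'
#' Standardizes each biomarker against the stable (reference) group and
#' orients it with `directions` (taken from differential-abundance coefficient
#' signs) so that every event is an increase.
#'
#' @param X subjects x biomarkers matrix or data frame.
#' @param reference rows of the reference group (matrix/data frame with the
#'   same columns; at least 3 rows, nonzero sd per biomarker).
#' @param directions named sign vector (+1/-1) per biomarker; defaults to +1.
#' @return z-scored matrix.
#' @export
zscore_biomarkers <- function(X, reference, directions = NULL) {
  X <- as.matrix(X)
  reference <- as.matrix(reference)
  if (nrow(reference) < 3L) rlang::abort("reference needs at least 3 rows.")
  mu <- colMeans(reference)
  sg <- apply(reference, 2L, sd)
  if (any(sg == 0)) {
    rlang::abort(sprintf("zero reference sd for biomarker '%s'.",
                         colnames(reference)[sg == 0][1]))
  }
  if (is.null(directions)) directions <- setNames(rep(1, ncol(X)), colnames(X))
  d <- sign(directions[colnames(X)])
  z <- sweep(sweep(sweep(X, 2L, mu), 2L, sg, `/`), 2L, d, `*`)
  dimnames(z) <- dimnames(X)
  z
}

# per-stage log likelihood matrix: subjects x (N+1) stages under `order`
stage_loglik <- function(Z, order, cfg, floor = -700) {
  Z <- as.matrix(Z)
  N <- ncol(Z)
  if (is.character(order)) order <- match(order, colnames(Z))
  if (length(order) != N || anyNA(order) || !setequal(order, seq_len(N))) {
    rlang::abort("`order` must be a permutation of all biomarkers.")
  }
  ze <- rep_len(cfg$z_event, N)
  sg <- rep_len(cfg$sigma, N)
  l0 <- pmax(dnorm(Z, 0, rep(sg, each = nrow(Z)), log = TRUE), floor)
  la <- pmax(dnorm(Z, rep(ze, each = nrow(Z)), rep(sg, each = nrow(Z)),
                   log = TRUE), floor)
  diffl <- (la - l0)[, order, drop = FALSE]
  cum <- t(apply(diffl, 1L, cumsum))
  cbind(rowSums(l0), rowSums(l0) + cum)   # stages 0..N
}

#' Log likelihood of an event ordering
#'
#' Each subject is a uniform mixture over stages `k = 0..N`; at stage k the
#' biomarkers whose event position is at most k are post-event. The total is
#' the sum over subjects of the log mixture probability. Log densities are
#' floored so that degenerate (near-noiseless) data yield finite values.
#'
#' @param Z subjects x biomarkers z-score matrix (events oriented as
#'   increases; see [zscore_biomarkers()]).
#' @param order permutation of biomarker columns (indices or names), earliest
#'   event first.
#' @param cfg an [event_model_config()].
#' @return total log likelihood (scalar).
#' @export
sequence_likelihood <- function(Z, order, cfg) {
  ll <- stage_loglik(Z, order, cfg)
  sum(row_log_sum_exp(ll) - log(ncol(ll)))
}

#' Fit the event sequence by greedy ascent and MCMC
#'
#' Runs `n_restarts` greedy ascents from random permutations (best
#' single-element relocation until no gain), then Metropolis MCMC with random
#' pairwise-swap proposals from the best order found. Returns the
#' maximum-likelihood order, the positional probability matrix estimated from
#' the MCMC samples, and stage posteriors under the MAP order.
#'
#' @param Z subjects x biomarkers z-score matrix.
#' @param cfg an [event_model_config()].
#' @return an `event_sequence` object: `order` (biomarker names, earliest
#'   first), `log_likelihood`, `positional_probability` (biomarker x position,
#'   rows sum to 1), `stage_posterior` (subject x stages 0..N, rows sum to 1),
#'   `map_stages`, `acceptance_rate`.
#' @export
fit_event_sequence <- function(Z, cfg = event_model_config()) {
  Z <- as.matrix(Z)
  N <- ncol(Z)
  if (N < 2L) rlang::abort("need at least 2 biomarkers.")
  if (is.null(colnames(Z))) colnames(Z) <- sprintf("BM%02d", seq_len(N))
  if (all(apply(Z, 2L, var) == 0)) {
    rlang::warn("all biomarkers identical across subjects; ordering is unidentifiable.")
  }
  ll_of <- function(ord) sum(row_log_sum_exp(stage_loglik(Z, ord, cfg)) -
                               log(N + 1))

  withr::with_seed(cfg$seed, {
    best_ord <- seq_len(N)
    best_ll <- -Inf
    for (r in seq_len(cfg$n_restarts)) {
      ord <- sample.int(N)
      ll <- ll_of(ord)
      repeat {
        improved <- FALSE
        for (i in seq_len(N)) {
          for (j in seq_len(N)) {
            if (i == j) next
            cand <- append(ord[-i], ord[i], after = j - 1L)
            cll <- ll_of(cand)
            if (cll > ll + 1e-12) {
              ord <- cand; ll <- cll; improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      if (ll > best_ll) { best_ll <- ll; best_ord <- ord }
    }

    samples <- matrix(0L, cfg$mcmc_iters, N)
    ord <- best_ord
    ll <- best_ll
    n_accept <- 0L
    for (it in seq_len(cfg$mcmc_iters)) {
      sw <- sample.int(N, 2L)
      cand <- ord
      cand[sw] <- cand[rev(sw)]
      cll <- ll_of(cand)
      if (log(runif(1)) < cll - ll) {
        ord <- cand; ll <- cll; n_accept <- n_accept + 1L
        if (ll > best_ll) { best_ll <- ll; best_ord <- ord }
      }
      samples[it, ] <- ord
    }

    pos_prob <- matrix(0, N, N,
                       dimnames = list(colnames(Z), seq_len(N)))
    for (pos in seq_len(N)) {
      tab <- tabulate(samples[, pos], nbins = N)
      pos_prob[, pos] <- tab / cfg$mcmc_iters
    }

    st <- stage_subjects(Z, best_ord, cfg)
    structure(list(
      order = colnames(Z)[best_ord],
      log_likelihood = best_ll,
      positional_probability = pos_prob,
      stage_posterior = st$stage_posterior,
      map_stages = st$map_stages,
      acceptance_rate = n_accept / cfg$mcmc_iters,
      cfg = cfg
    ), class = "event_sequence")
  })
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> logLik %.3f, MCMC acceptance %.2f\n",
              x$log_likelihood, x$acceptance_rate))
  cat("order:", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

#' @rdname fit_event_sequence
#' @param x an `event_sequence`.
#' @param ... unused.
#' @export
tidy.event_sequence <- function(x, ...) {
  tibble::as_tibble(x$positional_probability, rownames = "biomarker") |>
    tidyr::pivot_longer(-"biomarker", names_to = "position",
                        values_to = "probability") |>
    dplyr::mutate(position = as.integer(.data$position))
}

#' @rdname fit_event_sequence
#' @export
glance.event_sequence <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 acceptance_rate = x$acceptance_rate,
                 n_biomarkers = length(x$order),
                 n_subjects = nrow(x$stage_posterior))
}

#' Stage subjects under a fitted (or supplied) event order
#'
#' The posterior over stages `k = 0..N` is proportional to the per-stage
#' likelihood under a uniform stage prior; the MAP stage breaks ties toward
#' the lower stage.
#'
#' @param Z subjects x biomarkers z-score matrix.
#' @param order permutation of biomarker columns (indices or names).
#' @param cfg an [event_model_config()].
#' @return list with `stage_posterior` (subjects x N+1, rows sum to 1) and
#'   `map_stages` (integer vector, 0-based).
#' @export
stage_subjects <- function(Z, order, cfg = event_model_config()) {
  ll <- stage_loglik(Z, order, cfg)
  post <- exp(ll - row_log_sum_exp(ll))
  colnames(post) <- paste0("stage_", 0:(ncol(post) - 1L))
  rownames(post) <- rownames(Z)
  map <- max.col(post, ties.method = "first") - 1L
  list(stage_posterior = post, map_stages = setNames(map, rownames(Z)))
}
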