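#' Additive per-sample feature attributions (Shapley values)
#'
#' Computes Shapley-value attributions for each test sample by averaging
#' marginal contributions over feature orderings, with the value of a feature
#' subset defined as the mean model score over the background data with the
#' subset's columns replaced by the explained sample's values (marginal
#' expectation). Because each ordering's contributions telescope from the base
#' value (mean background score) to the sample's score, local accuracy —
#' `base_value + sum(attributions) = score` — holds exactly, regardless of the
#' number of orderings sampled; more orderings only reduce the variance of the
#' per-feature split. All orderings are enumerated when the number of features
#' is at most `exact_limit`.
#'
#' @param model fitted model (a `ranger` probability forest by default).
#' @param X_test samples x features data to explain (complete).
#' @param background reference data defining the base value (defaults to
#'   `X_test`).
#' @param predict_fun `function(model, newdata) -> numeric scores`; defaults
#'   to the positive-class probability of a `ranger` forest.
#' @param n_orderings sampled orderings when exact enumeration is infeasible.
#' @param exact_limit enumerate all `p!` orderings when `p <= exact_limit`.
#' @param seed integer seed for ordering sampling.
#' @param tol local-accuracy tolerance; a violation beyond it is an internal
#'   error.
#' @return an `attribution_matrix`: list with `attributions` (test samples x
#'   features), `base_value`, and `scores` (model scores of the explained
#'   rows). Global importance is the column mean of `abs(attributions)`.
#' @export
attribute_features <- function(model, X_test, background = X_test,
                               predict_fun = NULL, n_orderings = 50,
                               exact_limit = 5, seed = 1L, tol = 1e-6) {
  X_test <- as_feature_df(X_test, "X_test")
  background <- as_feature_df(background, "background")
  if (anyNA(X_test) || anyNA(background)) {
    rlang::abort("attribution requires complete data.")
  }
  if (is.null(predict_fun)) {
    if (!inherits(model, "ranger")) {
      rlang::abort("supply `predict_fun` for non-ranger models.")
    }
    predict_fun <- rf_score
  }
  p <- ncol(X_test)
  nb <- nrow(background)
  base_value <- mean(predict_fun(model, background))

  orderings <- if (factorial(p) <= factorial(exact_limit)) {
    all_permutations(p)
  } else {
    withr::with_seed(seed,
                     replicate(n_orderings, sample.int(p), simplify = FALSE))
  }

  scores <- predict_fun(model, X_test)
  attributions <- matrix(0, nrow(X_test), p,
                         dimnames = list(rownames(X_test), colnames(X_test)))
  for (i in seq_len(nrow(X_test))) {
    x <- X_test[i, , drop = FALSE]
    phi <- numeric(p)
    for (ord in orderings) {
      comp <- background
      v_prev <- base_value
      for (j in ord) {
        comp[[j]] <- rep(x[[j]], nb)
        v <- mean(predict_fun(model, comp))
        phi[j] <- phi[j] + (v - v_prev)
        v_prev <- v
      }
    }
    attributions[i, ] <- phi / length(orderings)
    gap <- abs(base_value + sum(attributions[i, ]) - scores[i])
    if (gap > tol) {
      rlang::abort(sprintf(
        "internal error: local accuracy violated (gap %.3g > tol).", gap))
    }
  }
  structure(list(attributions = attributions, base_value = base_value,
                 scores = scores),
            class = "attribution_matrix")
}

all_permutations <- function(p) {
  if (p == 1L) return(list(1L))
  out <- list()
  for (j in seq_len(p)) {
    rest <- all_permutations(p - 1L)
    out <- c(out, lapply(rest, function(r) c(j, setdiff(seq_len(p), j)[r])))
  }
  out
}

#' @export
print.attribution_matrix <- function(x, ...) {
  imp <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  cat(sprintf("<attribution_matrix> %d samples x %d features, base %.4f\n",
              nrow(x$attributions), ncol(x$attributions), x$base_value))
  cat("top features:", paste(head(names(imp), 5), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname attribute_features
#' @param x an `attribution_matrix`.
#' @param ... unused.
#' @export
tidy.attribution_matrix <- function(x, ...) {
  tibble::as_tibble(x$attributions, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "feature",
                        values_to = "attribution")
}
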