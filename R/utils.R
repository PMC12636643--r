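# internal validation + seeding helpers

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a single fraction in [0, 1].", name),
                 class = "csfprog_config_error")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min),
                 class = "csfprog_config_error")
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    rlang::abort(sprintf("`%s` must be a single non-negative number.", name),
                 class = "csfprog_config_error")
  }
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be TRUE or FALSE.", name),
                 class = "csfprog_config_error")
  }
  x
}

# Deterministic sub-seed expansion: one user-facing seed fans out into
# independent per-stage / per-run seeds without touching the global RNG.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp over a matrix (subjects x stages)
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
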