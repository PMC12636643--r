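test_that("sample-loading scaling equalizes observed column sums", {
  m <- make_abund(matrix(c(1, 3, 2, 2), 2))   # col sums 4, 4
  expect_equal(scale_sample_loading(m)$values, m$values)

  m2 <- make_abund(matrix(c(1, 1, 4, 0), 2))  # col sums 2, 4 (0 observed)
  out <- scale_sample_loading(m2)
  expect_equal(unname(out$values), matrix(c(2, 2, 4, 0), 2))

  set.seed(1)
  m3 <- make_abund(matrix(rexp(30), 5))
  s3 <- scale_sample_loading(m3)
  expect_equal(unname(colSums(s3$values)),
               rep(max(colSums(m3$values)), 6))

  m4 <- make_abund(matrix(c(1, 2, NA, NA), 2))
  expect_error(scale_sample_loading(m4), "s02")
})

test_that("zeros become missing and nothing else changes", {
  m <- make_abund(matrix(c(0, 5, 3, 0, 2, 7), 2))
  n_zero <- sum(m$values == 0)
  out <- zeros_to_missing(m)
  expect_equal(sum(is.na(out$values)), n_zero)
  expect_equal(out$values[!is.na(out$values)], m$values[m$values != 0])

  clean <- make_abund(matrix(1:6, 2))
  expect_identical(zeros_to_missing(clean)$values + 0, clean$values + 0)
})

test_that("quantification filter is inclusive, completeness filter strict", {
  vals <- matrix(1, 3, 100)
  vals[1, 1:50] <- NA    # observed 50%
  vals[2, 1:51] <- NA    # observed 49%
  m <- make_abund(vals, samples = sprintf("s%03d", 1:100))
  kept <- filter_quantified(m, 0.5)
  expect_setequal(rownames(kept$values), c("p01", "p03"))
  expect_lte(nrow(kept$values), nrow(m$values))

  vals2 <- matrix(1, 3, 100)
  vals2[1, 1:4] <- NA    # 96% observed -> kept
  vals2[2, 1:5] <- NA    # exactly 95% -> dropped
  m2 <- make_abund(vals2, samples = sprintf("s%03d", 1:100))
  kept2 <- filter_completeness(m2, 0.95)
  expect_setequal(rownames(kept2$values), c("p01", "p03"))
})

test_that("tampor removes per-batch scalars exactly and centers medians", {
  meta4 <- data.frame(sample_id = sprintf("s%02d", 1:4),
                      batch_id = rep(c("b1", "b2"), each = 2))
  # constant matrix -> all zeros
  const <- make_abund(matrix(5, 3, 4))
  out <- tampor(const, meta4)
  expect_true(all(abs(out$values) < 1e-8))

  # batch2 = batch1 x 2: per-batch ratios cancel the scalar exactly
  m <- make_abund(matrix(c(10, 5, 12, 4, 20, 10, 24, 8), 2))
  r <- tampor(m, meta4)
  expect_equal(r$values[, 3:4], r$values[, 1:2], ignore_attr = TRUE)

  # exact invariance to scaling any batch by a constant
  cfg <- small_cfg(seed = 5)
  ch <- generate_cohort(cfg)
  pr <- generate_proteome(ch$meta, ch$truth, cfg)
  m1 <- zeros_to_missing(pr$abundance)
  v2 <- pr$abundance$values
  sel <- ch$meta$batch_id == "B02"
  v2[, sel] <- v2[, sel] * 7.3
  m2 <- zeros_to_missing(abundance_matrix(v2, "raw"))
  t1 <- suppressWarnings(tampor(m1, ch$meta))
  t2 <- suppressWarnings(tampor(m2, ch$meta))
  expect_lt(max(abs(t1$values - t2$values), na.rm = TRUE), 1e-8)

  # row and column medians ~ 0 after polish
  expect_lt(max(abs(apply(t1$values, 1, median, na.rm = TRUE))), 1e-7)
  expect_lt(max(abs(apply(t1$values, 2, median, na.rm = TRUE))), 1e-7)
})

test_that("tampor polish is idempotent and removes per-sample offsets", {
  meta4 <- data.frame(sample_id = sprintf("s%02d", 1:4),
                      batch_id = rep(c("b1", "b2"), each = 2))
  set.seed(2)
  m <- make_abund(matrix(rexp(40, 0.1) + 1, 10, 4))
  t1 <- tampor(m, meta4)
  # the output is a fixed point of the polish stage: one further sweep of
  # row- and column-median subtraction moves nothing beyond tol
  v <- t1$values
  v <- v - apply(v, 1, median, na.rm = TRUE)
  v <- sweep(v, 2, apply(v, 2, median, na.rm = TRUE))
  expect_lt(max(abs(v - t1$values), na.rm = TRUE), 1e-7)

  # multiplying one non-denominator sample by 8 only shifts its column;
  # the column-median subtraction removes the shift exactly
  des <- c("s01", "s03")
  ta <- tampor(m, meta4, denominator_mode = "designated_samples",
               designated = des)
  v8 <- m$values
  v8[, "s02"] <- v8[, "s02"] * 8
  tb <- tampor(make_abund(v8), meta4, denominator_mode = "designated_samples",
               designated = des)
  expect_lt(max(abs(ta$values - tb$values)), 1e-7)
})

test_that("bootstrap covariate regression removes planted linear effects", {
  # exact dependence: L_ij = 2 x_j (+ protein offset) -> corrected is constant
  set.seed(3)
  x <- rnorm(40)
  L <- outer(c(1, -0.5, 2), x * 0) + outer(rep(2, 3), x) + c(1, 5, 9)
  m <- make_abund(L, scale = "log2", samples = sprintf("s%02d", 1:40))
  out <- bootstrap_regress_covariates(m, data.frame(x = x), n_boot = 25,
                                      seed = 1)
  expect_lt(max(abs(sweep(out$values, 1, rowMeans(out$values)))), 1e-9)

  # covariate orthogonal to the data (zero planted coefficient, no noise):
  # medians of bootstrap OLS coefficients are ~0, matrix unchanged
  const <- make_abund(matrix(rep(c(3, 7), 20), 2, 20, byrow = FALSE),
                      scale = "log2", samples = sprintf("s%02d", 1:20))
  keep <- bootstrap_regress_covariates(const, data.frame(x = rnorm(20)),
                                       n_boot = 25, seed = 2)
  expect_equal(keep$values, const$values, tolerance = 1e-8)

  # adding a constant to the covariate changes results only via the intercept
  out2 <- bootstrap_regress_covariates(m, data.frame(x = x + 100),
                                       n_boot = 25, seed = 1)
  d <- out2$values - out$values
  expect_lt(max(abs(sweep(d, 1, rowMeans(d)))), 1e-9)
})

test_that("knn imputation matches a brute-force neighbor oracle", {
  # constant protein row imputes its constant
  vals <- matrix(5, 3, 6)
  vals[1, 2] <- NA
  vals[2, ] <- c(1, 2, 3, 4, 5, 6)
  vals[3, ] <- c(6, 5, 4, 3, 2, 1)
  m <- make_abund(vals)
  imp <- knn_impute(m, k = 3)
  expect_equal(imp$values[1, 2], 5)
  expect_equal(imp$values[-1, ], m$values[-1, ])   # observed untouched

  # 3x3 with one missing cell, k = 2: hand-computed neighbor mean
  v <- matrix(c(1, 10, 100,
                2, 11, NA,
                9, 30, 140), 3, 3)
  m3 <- make_abund(v)
  # distances to s02 over mutually observed proteins (rows 1-2):
  # d(s01,s02)^2 = ((1-2)^2 + (10-11)^2)/2 = 1; d(s03,s02)^2 = ((9-2)^2+(30-11)^2)/2
  # nearest 2 samples observing p03 are s01 then s03 -> mean(100, 140)
  out3 <- knn_impute(m3, k = 2)
  expect_equal(out3$values[3, 2], mean(c(100, 140)))

  # error when a sample observes nothing
  v2 <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(knn_impute(make_abund(v2), k = 1), "s02")
})

test_that("knn imputation beats column-mean imputation on correlated data", {
  set.seed(11)
  n <- 60; p <- 40
  latent <- rnorm(n)
  truth <- outer(rnorm(p, 0, 0.3), rep(1, n)) +
    outer(runif(p, 0.5, 1.5), latent) + matrix(rnorm(p * n, 0, 0.3), p, n)
  mask <- matrix(runif(p * n) < 0.1, p, n)
  obs <- truth
  obs[mask] <- NA
  m <- make_abund(obs, scale = "log2", proteins = sprintf("p%03d", 1:p),
                  samples = sprintf("s%03d", 1:n))
  imp <- knn_impute(m, k = 5)
  rmse_knn <- sqrt(mean((imp$values[mask] - truth[mask])^2))
  rowmean <- rowMeans(obs, na.rm = TRUE)
  rmse_mean <- sqrt(mean((matrix(rowmean, p, n)[mask] - truth[mask])^2))
  expect_lte(rmse_knn, rmse_mean)
})
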