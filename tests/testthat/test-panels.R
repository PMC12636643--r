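test_that("AUC equals the Mann-Whitney pairwise count, with ties as half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.4), c(1, 0, 0, 1))$auc, 0.75)
  # reversing scores gives 1 - AUC
  s <- c(0.9, 0.3, 0.8, 0.4); y <- c(1, 0, 0, 1)
  expect_equal(roc_auc(-s, y)$auc, 1 - roc_auc(s, y)$auc)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  # property: 200 random instances, with ties, against brute force (and pROC)
  set.seed(10)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)   # frequent ties
    expect_equal(roc_auc(s, y)$auc, auc_brute(s, y))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(11)
    y <- rbinom(60, 1, 0.5); y[1:2] <- 0:1
    s <- rnorm(60)
    expect_equal(roc_auc(s, y)$auc,
                 as.numeric(suppressMessages(pROC::auc(y, s))))
  }
})

test_that("Youden threshold maximizes TPR - FPR, ties to higher sensitivity", {
  r <- roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  yt <- youden_threshold(r)
  expect_equal(yt$j, 0.5)
  expect_equal(yt$threshold, 0.4)   # ties with 0.9; 0.4 has TPR 1

  sep <- roc_auc(c(10, 9, 1, 0), c(1, 1, 0, 0))
  expect_equal(youden_threshold(sep)$j, 1)
  expect_true(all(abs(sep$roc$tpr - sep$roc$fpr) <= 1))
})

test_that("stability selection keeps the informative feature, drops noise", {
  set.seed(2)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(signal = y + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 15), n,
                    dimnames = list(NULL, sprintf("noise%02d", 1:15))))
  sel <- stability_select(X, y, n_boot = 30, seed = 9)
  expect_equal(sel$frequency[sel$feature == "signal"], 1.0)
  expect_true(sel$selected[sel$feature == "signal"])
  expect_true(all(sel$frequency[sel$feature != "signal"] < 0.9))
  # definition restated: selected set is exactly the >= threshold set
  expect_setequal(sel$feature[sel$selected],
                  sel$feature[sel$frequency >= attr(sel, "threshold")])

  Xna <- X; Xna[1, 1] <- NA
  expect_error(stability_select(Xna, y), "knn_impute")
})

test_that("pure-noise features are almost never stability-selected", {
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("f%02d", 1:10)))
    sel <- stability_select(X, y, n_boot = 20, seed = s)
    expect_length(sel$feature[sel$selected], 0)
  }
})

test_that("panel evaluation is deterministic and exact on separable data", {
  set.seed(3)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(f = c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 10, 0.5)))
  g1 <- data.frame(num_trees = 100, max_depth = 0)
  ev <- evaluate_panel(X, y, n_runs = 8, grid = g1, seed = 4)
  expect_true(all(ev$runs$auc == 1))
  expect_true(all(ev$runs$youden_j == 1))
  ev2 <- evaluate_panel(X, y, n_runs = 8, grid = g1, seed = 4)
  expect_identical(ev$runs, ev2$runs)
  expect_identical(ev$roc, ev2$roc)
  expect_equal(nrow(ev$runs), 8)
  expect_equal(glance(ev)$median_auc, 1)

  # shuffled labels: chance-level performance (null AUC sd at this n ~ 0.05)
  set.seed(13)
  n2 <- 300
  y2 <- rep(c(0, 1), each = n2 / 2)
  X2 <- data.frame(f = c(rnorm(n2 / 2, 0, 0.5), rnorm(n2 / 2, 10, 0.5)))
  yshuf <- withr::with_seed(5, sample(y2))
  evn <- evaluate_panel(X2, yshuf, n_runs = 10, grid = g1, seed = 6)
  expect_lt(abs(evn$median_auc - 0.5), 0.12)
})

test_that("nested re-selection does not beat the fixed panel by more than noise", {
  set.seed(6)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(signal = 1.5 * y + rnorm(n),
             matrix(rnorm(n * 8), n,
                    dimnames = list(NULL, sprintf("noise%02d", 1:8))))
  g1 <- data.frame(num_trees = 100, max_depth = 0)
  sel <- stability_select(X, y, n_boot = 20, threshold = 0.9, seed = 7)
  fixed <- evaluate_panel(X[, sel$feature[sel$selected], drop = FALSE], y,
                          n_runs = 6, grid = g1, seed = 8)
  nested <- evaluate_panel(X, y, n_runs = 6, grid = g1, seed = 8,
                           select_fun = function(Xtr, ytr) {
                             s <- stability_select(Xtr, ytr, n_boot = 15,
                                                   threshold = 0.9, seed = 7)
                             s$feature[s$selected]
                           })
  expect_equal(nested$mode, "nested")
  expect_lte(nested$median_auc, fixed$median_auc + 0.05)
})

test_that("attributions satisfy local accuracy and closed forms", {
  # constant model: all attributions zero
  Xt <- data.frame(a = rnorm(10), b = rnorm(10))
  const_fun <- function(model, d) rep(0.7, nrow(d))
  at0 <- attribute_features(NULL, Xt, predict_fun = const_fun)
  expect_true(all(abs(at0$attributions) < 1e-12))
  expect_equal(at0$base_value, 0.7)

  # additive model on independent features: phi_i = w_i (x_i - mean x_i)
  set.seed(4)
  Xb <- data.frame(a = rnorm(50), b = rnorm(50))
  lin_fun <- function(model, d) 2 * d$a - 3 * d$b
  at <- attribute_features(NULL, Xb, background = Xb, predict_fun = lin_fun)
  expect_equal(at$attributions[, "a"], 2 * (Xb$a - mean(Xb$a)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(at$attributions[, "b"], -3 * (Xb$b - mean(Xb$b)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # interaction model: sampled orderings match exact 2! enumeration
  int_fun <- function(model, d) d$a * d$b
  exact <- attribute_features(NULL, Xb[1:5, ], background = Xb,
                              predict_fun = int_fun)
  sampled <- attribute_features(NULL, Xb[1:5, ], background = Xb,
                                predict_fun = int_fun, exact_limit = 0,
                                n_orderings = 400, seed = 2)
  # Monte-Carlo over orderings: agreement within sampling error of the
  # per-ordering spread, while local accuracy stays exact
  expect_equal(sampled$attributions, exact$attributions, tolerance = 0.1)
  expect_equal(unname(sampled$base_value + rowSums(sampled$attributions)),
               unname(int_fun(NULL, Xb[1:5, ])), tolerance = 1e-6)

  # local accuracy on a real forest
  set.seed(9)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  Xr <- data.frame(u = y + rnorm(n), v = rnorm(n))
  rf <- ranger::ranger(x = Xr, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 50, seed = 1,
                       num.threads = 1)
  atr <- attribute_features(rf, Xr[1:4, ], background = Xr[1:30, ], seed = 3)
  recon <- atr$base_value + rowSums(atr$attributions)
  expect_equal(unname(recon), unname(atr$scores), tolerance = 1e-6)
  # the informative feature dominates global importance
  imp <- colMeans(abs(attribute_features(rf, Xr[1:20, ],
                                         background = Xr[1:30, ],
                                         seed = 3)$attributions))
  expect_gt(imp[["u"]], imp[["v"]])
})

test_that("synchronized comparison is null on identical blocks and antisymmetric", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  XA <- data.frame(a = y + rnorm(n))
  g1 <- data.frame(num_trees = 50, max_depth = 3)
  same <- compare_predictor_sets(XA, XA, y, n_runs = 2, B = 9, seed = 3,
                                 grid = g1)
  expect_equal(same$delta_observed, 0)
  expect_equal(same$p_value, 1)

  XB <- data.frame(b = rnorm(n))
  ab <- compare_predictor_sets(XA, XB, y, n_runs = 2, B = 9, seed = 3,
                               grid = g1)
  ba <- compare_predictor_sets(XB, XA, y, n_runs = 2, B = 9, seed = 3,
                               grid = g1)
  expect_equal(ab$delta_observed, -ba$delta_observed, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value)

  expect_error(compare_predictor_sets(XA[1:10, , drop = FALSE], XB, y),
               "row-aligned")
})

test_that("conventional biomarkers concatenate after the panel", {
  Xp <- data.frame(matrix(rnorm(60), 5, 12,
                          dimnames = list(NULL, sprintf("prot%02d", 1:12))))
  conv <- data.frame(abeta42 = rnorm(5), ptau181 = rnorm(5))
  comb <- combine_with_conventional(Xp, conv)
  expect_equal(ncol(comb), 14)
  expect_equal(colnames(comb), c(colnames(Xp), colnames(conv)))
  expect_equal(attr(comb, "provenance"),
               rep(c("panel", "conventional"), c(12, 2)))
  expect_equal(combine_with_conventional(Xp, NULL)[, 1:12], Xp)
  expect_error(combine_with_conventional(Xp, Xp[, 1, drop = FALSE]),
               "duplicate")
})
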