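make_classif_data <- function(n = 80, seed = 61, beta = 1.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("inf1", "inf2", "noise1", "noise2",
                                      "noise3", "noise4")))
  eta <- beta * X[, "inf1"] + beta * X[, "inf2"]
  y <- factor(ifelse(runif(n) < stats::plogis(eta), "case", "ctl"),
              levels = c("ctl", "case"))
  list(X = as.data.frame(X), y = y)
}

test_that("auc_rank equals the brute-force all-pairs AUC under ties", {
  set.seed(62)
  for (i in 1:5) {
    s <- sample(0:4, 30, replace = TRUE)
    cls <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(cls) || all(cls)) next
    expect_equal(auc_rank(s, cls), oracle_auc(s, cls))
  }
})

test_that("stratified folds balance classes within one count", {
  set.seed(63)
  y <- factor(rep(c("a", "b"), times = c(33, 27)))
  f <- stratified_folds(y, 10L)
  tab <- table(f, y)
  expect_true(all(apply(tab, 2, function(v) diff(range(v)) <= 1)))
  expect_equal(sum(tab), 60)
})

test_that("stepwise selection keeps the informative features", {
  d <- make_classif_data()
  rep_sw <- select_features(d$X, d$y, method = "stepwise", seed = 1L)
  expect_true(all(c("inf1", "inf2") %in% rep_sw$selected))
  expect_lt(length(setdiff(rep_sw$selected, c("inf1", "inf2"))), 3)
  expect_true(is.numeric(rep_sw$diagnostics$aic))
})

test_that("lasso selection keeps the informative features and records lambda", {
  d <- make_classif_data()
  rep_l <- select_features(d$X, d$y, method = "lasso", seed = 1L)
  expect_true(all(c("inf1", "inf2") %in% rep_l$selected))
  expect_true(rep_l$diagnostics$lambda_min > 0)
})

test_that("random forest keeps ceiling(m/2) features, informative on top", {
  d <- make_classif_data(n = 120)
  rep_rf <- select_features(d$X, d$y, method = "random_forest", seed = 1L)
  expect_equal(length(rep_rf$selected), 3L)   # ceiling(6/2)
  expect_true(all(c("inf1", "inf2") %in% rep_rf$selected))
  expect_setequal(names(rep_rf$diagnostics$importance)[1:2],
                  c("inf1", "inf2"))
})

test_that("perfect separation in stepwise is flagged, not fatal", {
  X <- data.frame(sep = c(rnorm(10, -5), rnorm(10, 5)), junk = rnorm(20))
  y <- factor(rep(c("ctl", "case"), each = 10), levels = c("ctl", "case"))
  expect_warning(rep_s <- select_features(X, y, method = "stepwise"),
                 "separation")
  expect_true("sep" %in% rep_s$selected)
  expect_true(rep_s$diagnostics$separation)
})

test_that("consensus_select applies the >= min_methods rule and the ranking", {
  reports <- list(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"))
  expect_identical(consensus_select(reports),            # >= 2 methods
                   c("B", "C"))                          # candidate order
  expect_identical(consensus_select(reports, min_methods = 3L), "C")
  rk <- c(A = 0.04, B = 0.03, C = 0.001, D = 0.2, E = 0.5)
  expect_identical(consensus_select(reports, ranking = rk), c("C", "B"))
  expect_identical(consensus_select(list(c("A"), c("B")), min_methods = 2L),
                   character(0))
  expect_error(consensus_select(list(c("A"))), ">= 2 reports")
})

test_that("k-fold CV AUC is high for signal and near 0.5 for noise", {
  d <- make_classif_data(n = 100, seed = 64, beta = 2)
  ev <- evaluate_kfold_auc(d$X, d$y, features = c("inf1", "inf2"), k = 5L,
                           seed = 2L)
  expect_gt(ev$mean_auc, 0.8)
  expect_length(ev$fold_auc, 5L)
  expect_true(ev$ci[1] <= ev$mean_auc && ev$mean_auc <= ev$ci[2])
  ev0 <- evaluate_kfold_auc(d$X, d$y, features = c("noise1", "noise2"),
                            k = 5L, seed = 2L)
  expect_lt(abs(ev0$mean_auc - 0.5), 0.15)
  expect_error(evaluate_kfold_auc(d$X, d$y, features = character(0)),
               "empty")
})

test_that("covariates enter the CV model", {
  d <- make_classif_data(n = 100, seed = 65, beta = 0)
  cov <- data.frame(strong = ifelse(d$y == "case", 1, 0) + rnorm(100, 0, 0.1))
  ev <- evaluate_kfold_auc(d$X, d$y, features = "noise1", k = 5L,
                           covariates = cov, seed = 2L)
  expect_gt(ev$mean_auc, 0.95)
})

test_that("LOOCV one-vs-rest separates three distinct classes", {
  set.seed(66)
  n <- 12
  X <- data.frame(f1 = c(rnorm(n, 0), rnorm(n, 6), rnorm(n, 0)),
                  f2 = c(rnorm(n, 0), rnorm(n, 0), rnorm(n, 6)))
  y <- rep(c("typeA", "typeB", "typeC"), each = n)
  res <- evaluate_loocv_one_vs_rest(X, y, features_per_type = c("f1", "f2"))
  expect_equal(res$type, c("typeA", "typeB", "typeC"))
  expect_true(all(res$accuracy > 0.85))
  expect_true(all(res$n == 3 * n))
})

test_that("AUC test power matches the closed-form expression", {
  # independent evaluation straight from the published variance model
  pow_direct <- function(A, n1, n0, alpha) {
    v <- function(a) {
      q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
      (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
    }
    z <- qnorm(1 - alpha / 2); d <- A - 0.5
    pnorm((d - z * sqrt(v(0.5))) / sqrt(v(A))) +
      pnorm((-d - z * sqrt(v(0.5))) / sqrt(v(A)))
  }
  for (A in c(0.6, 0.7, 0.8)) for (n in c(20, 50, 100))
    expect_equal(auc_test_power(A, 0.5, n, n, 0.05),
                 pow_direct(A, n, n, 0.05), tolerance = 1e-12)
  # at the null the power is exactly the test size
  expect_equal(auc_test_power(0.5 + 1e-12, 0.5, 50, 50, 0.05), 0.05,
               tolerance = 1e-6)
  # monotone in effect size and in sample size
  expect_gt(auc_test_power(0.8, 0.5, 50, 50, 0.05),
            auc_test_power(0.7, 0.5, 50, 50, 0.05))
  expect_gt(auc_test_power(0.7, 0.5, 100, 100, 0.05),
            auc_test_power(0.7, 0.5, 50, 50, 0.05))
  expect_warning(auc_test_power(0.45, 0.5, 20, 20, sided = "one"),
                 "one-sided")
})

test_that("auc_test_n returns the minimal n reaching the target power", {
  n <- auc_test_n(0.7, power = 0.9)
  expect_gte(auc_test_power(0.7, 0.5, n, n, 0.05), 0.9)
  expect_lt(auc_test_power(0.7, 0.5, n - 1, n - 1, 0.05), 0.9)
  n2 <- auc_test_n(0.7, power = 0.9, ratio = 2)
  expect_gte(auc_test_power(0.7, 0.5, n2, 2 * n2, 0.05), 0.9)
})
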