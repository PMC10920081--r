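# Rank-based AUC (Mann-Whitney U / (n1*n0)), fixed orientation:
# probability that a randomly chosen case scores above a random control,
# ties counted half.
auc_rank <- function(scores, labels_case) {
  n1 <- sum(labels_case); n0 <- sum(!labels_case)
  if (n1 == 0 || n0 == 0) stop("auc_rank: one class absent")
  r <- rank(scores)
  (sum(r[labels_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into k folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select features for a logistic classifier
#'
#' Three selectors over a small candidate set (in the study design, the top
#' 10 markers by ascending adjusted p): bidirectional stepwise AIC search
#' from the null logistic model; L1-penalized logistic regression with the
#' penalty chosen by stratified 10-fold CV deviance (minimum rule,
#' selection = nonzero coefficients); and a 500-tree random forest keeping
#' the top half (ceiling(m/2)) of features by impurity importance.
#'
#' @param X data.frame or matrix of candidate features (samples x features).
#' @param y binary outcome (two-level factor or 0/1).
#' @param method "stepwise", "lasso" or "random_forest".
#' @param seed integer seed (CV folds / forest).
#' @return object of class \code{feature_selection_report}: list with
#'   method, candidates, selected, diagnostics.
#' @export
select_features <- function(X, y, method = c("stepwise", "lasso", "random_forest"),
                            seed = 1L) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("select_features: 'y' must be binary")
  candidates <- colnames(X)
  set.seed(seed)
  diagnostics <- list()
  if (method == "stepwise") {
    dat <- data.frame(.y = y, X, check.names = FALSE)
    sep_warn <- FALSE
    wh <- function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
    fit <- withCallingHandlers({
      null <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
      upper <- stats::as.formula(paste("~", paste(sprintf("`%s`", candidates),
                                                  collapse = " + ")))
      stats::step(null, scope = list(lower = ~1, upper = upper),
                  direction = "both", trace = 0)
    }, warning = wh)
    selected <- gsub("`", "", attr(stats::terms(fit), "term.labels"))
    diagnostics$aic <- stats::AIC(fit)
    diagnostics$separation <- sep_warn
    if (sep_warn) {
      warning("select_features: perfect separation in stepwise fit; ",
              "coefficients refit with a ridge penalty")
      if (length(selected)) {
        xm <- as.matrix(X[, selected, drop = FALSE])
        rf <- glmnet::glmnet(cbind(xm, 0), y, family = "binomial",
                             alpha = 0, lambda = 1e-3)
        diagnostics$coefficients <- stats::coef(rf)[seq_len(length(selected) + 1)]
      }
    }
  } else if (method == "lasso") {
    xm <- as.matrix(X)
    foldid <- stratified_folds(y, 10L)
    cv <- glmnet::cv.glmnet(xm, y, family = "binomial", alpha = 1,
                            type.measure = "deviance", foldid = foldid)
    b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    selected <- candidates[b != 0]
    diagnostics$lambda_min <- cv$lambda.min
    diagnostics$penalty_path <- cv$lambda
  } else {
    rf <- randomForest::randomForest(x = X, y = y, ntree = 500L)
    imp <- rf$importance[, "MeanDecreaseGini"]
    keep <- ceiling(length(candidates) / 2)
    selected <- names(sort(imp, decreasing = TRUE))[seq_len(keep)]
    diagnostics$importance <- sort(imp, decreasing = TRUE)
  }
  structure(list(method = method, candidates = candidates,
                 selected = selected, diagnostics = diagnostics),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat("feature_selection_report [", x$method, "]: ",
      length(x$selected), "/", length(x$candidates), " selected: ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Consensus of feature-selection reports
#'
#' Features selected by at least \code{min_methods} of the reports, ordered
#' by the supplied marker ranking (ascending adjusted p) when given,
#' otherwise by candidate order.
#'
#' @param reports list of \code{\link{select_features}} reports (or plain
#'   character vectors of selected features).
#' @param min_methods minimum number of selecting methods (default 2).
#' @param ranking optional named numeric (e.g. adjusted p per feature) used
#'   to order the output ascending.
#' @return character vector (possibly empty).
#' @export
consensus_select <- function(reports, min_methods = 2L, ranking = NULL) {
  if (length(reports) < 2) stop("consensus_select: need >= 2 reports")
  sels <- lapply(reports, function(r)
    if (inherits(r, "feature_selection_report")) r$selected else as.character(r))
  tab <- table(unlist(lapply(sels, unique)))
  feats <- names(tab)[tab >= min_methods]
  if (!length(feats)) return(character(0))
  if (!is.null(ranking)) {
    feats <- feats[order(ranking[feats])]
  } else {
    cand <- unique(unlist(lapply(reports, function(r)
      if (inherits(r, "feature_selection_report")) r$candidates else as.character(r))))
    feats <- feats[order(match(feats, cand))]
  }
  feats
}

#' Stratified k-fold cross-validated logistic AUC
#'
#' Fits a logistic regression on the selected features (plus optional
#' covariates) on each training split and scores the held-out fold; the
#' mean test AUC and its normal-approximation 95% CI across folds are
#' reported.
#'
#' @param X data.frame/matrix of features (samples x features).
#' @param y binary outcome; the second factor level is the positive class.
#' @param features character vector of feature columns to use.
#' @param k number of folds (default 10).
#' @param covariates optional data.frame of extra columns appended to the
#'   model (e.g. smoking, drinking, family history).
#' @param seed integer seed for the fold assignment.
#' @return object of class \code{model_evaluation}: list with features,
#'   fold_auc, mean_auc, ci, k, seed.
#' @export
evaluate_kfold_auc <- function(X, y, features, k = 10L, covariates = NULL,
                               seed = 1L) {
  X <- as.data.frame(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("evaluate_kfold_auc: 'y' must be binary")
  if (!length(features)) stop("evaluate_kfold_auc: 'features' is empty")
  if (min(table(y)) < k)
    stop("evaluate_kfold_auc: k exceeds the smaller class size")
  dat <- X[, features, drop = FALSE]
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- data.frame(.y = y, dat, check.names = TRUE)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  pos <- levels(y)[2]
  fold_auc <- vapply(seq_len(k), function(f) {
    train <- dat[fold != f, , drop = FALSE]
    test <- dat[fold == f, , drop = FALSE]
    fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                       data = train))
    pr <- suppressWarnings(stats::predict(fit, newdata = test, type = "response"))
    auc_rank(pr, test$.y == pos)
  }, numeric(1))
  m <- mean(fold_auc)
  se <- stats::sd(fold_auc) / sqrt(k)
  structure(list(features = features, fold_auc = fold_auc, mean_auc = m,
                 ci = c(max(0, m - 1.96 * se), min(1, m + 1.96 * se)),
                 k = k, seed = seed),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("model_evaluation: mean CV AUC ", round(x$mean_auc, 3),
      " (95% CI ", round(x$ci[1], 3), "-", round(x$ci[2], 3), ") over ",
      x$k, " folds\n", sep = "")
  invisible(x)
}

#' Leave-one-out one-vs-rest classification accuracy
#'
#' For each class of a multi-class outcome, a binary logistic model (that
#' class vs the rest) is evaluated by leave-one-out cross-validation: each
#' sample is predicted by a model trained on all others, called positive at
#' probability 0.5, and the overall accuracy recorded.
#'
#' @param X data.frame/matrix of features.
#' @param y_type multi-class outcome (one entry per sample).
#' @param features_per_type named list: class -> character vector of
#'   feature columns (a single character vector is recycled to all
#'   classes).
#' @return data.frame with type, n, accuracy, n_degenerate (leave-one-out
#'   fits that failed and fell back to the training prior).
#' @export
evaluate_loocv_one_vs_rest <- function(X, y_type, features_per_type) {
  X <- as.data.frame(X)
  y_type <- factor(y_type)
  types <- levels(y_type)
  if (any(table(y_type) < 5))
    stop("evaluate_loocv_one_vs_rest: every class needs n >= 5")
  if (!is.list(features_per_type))
    features_per_type <- stats::setNames(rep(list(features_per_type),
                                             length(types)), types)
  rows <- lapply(types, function(tp) {
    feats <- features_per_type[[tp]]
    yb <- as.integer(y_type == tp)
    dat <- data.frame(.y = yb, X[, feats, drop = FALSE], check.names = TRUE)
    n <- nrow(dat)
    pred <- logical(n); degenerate <- logical(n)
    for (i in seq_len(n)) {
      p <- tryCatch({
        fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                           data = dat[-i, , drop = FALSE]))
        suppressWarnings(stats::predict(fit, newdata = dat[i, , drop = FALSE],
                                        type = "response"))
      }, error = function(e) NA_real_)
      if (is.na(p)) { p <- mean(yb[-i]); degenerate[i] <- TRUE }
      pred[i] <- p >= 0.5
    }
    data.frame(type = tp, n = n, accuracy = mean(pred == (yb == 1L)),
               n_degenerate = sum(degenerate), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Hanley-McNeil variance of an estimated AUC (exponential model).
hanley_mcneil_var <- function(A, n1, n0) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  (A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) / (n1 * n0)
}

#' Power of a one-ROC-curve z-test
#'
#' Power of the z-test of H0: AUC = \code{auc_null} against the alternative
#' \code{auc_alt}, with the Hanley-McNeil (exponential-model) variance
#' evaluated under each hypothesis.
#'
#' @param auc_alt alternative AUC in (0, 1).
#' @param auc_null null AUC (default 0.5).
#' @param n1,n0 cases and controls (each >= 2).
#' @param alpha significance level (default 0.05).
#' @param sided "two" (default) or "one".
#' @return power in [0, 1].
#' @export
auc_test_power <- function(auc_alt, auc_null = 0.5, n1, n0, alpha = 0.05,
                           sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(auc_alt > 0, auc_alt < 1, auc_null > 0, auc_null < 1,
            n1 >= 2, n0 >= 2, alpha > 0, alpha < 1)
  sd0 <- sqrt(hanley_mcneil_var(auc_null, n1, n0))
  sd1 <- sqrt(hanley_mcneil_var(auc_alt, n1, n0))
  delta <- auc_alt - auc_null
  if (sided == "one") {
    if (delta <= 0)
      warning("auc_test_power: alternative <= null with a one-sided test; power <= alpha")
    z <- stats::qnorm(1 - alpha)
    stats::pnorm((delta - z * sd0) / sd1)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm((delta - z * sd0) / sd1) +
      stats::pnorm((-delta - z * sd0) / sd1)
  }
}

#' Minimal per-class sample size for a target AUC-test power
#'
#' Inverse of \code{\link{auc_test_power}} with equal class sizes scaled by
#' \code{ratio}: the smallest n1 (n0 = ratio * n1) reaching the target.
#'
#' @param auc_alt,auc_null,alpha,sided as in \code{\link{auc_test_power}}.
#' @param power target power (default 0.9).
#' @param ratio n0 / n1 (default 1).
#' @return integer n1.
#' @export
auc_test_n <- function(auc_alt, auc_null = 0.5, power = 0.9, alpha = 0.05,
                       ratio = 1, sided = "two") {
  f <- function(n) auc_test_power(auc_alt, auc_null, n1 = n,
                                  n0 = max(2, ceiling(ratio * n)),
                                  alpha = alpha, sided = sided) - power
  n <- 2
  while (f(n) < 0 && n < 1e7) n <- n * 2
  if (f(n) < 0) stop("auc_test_n: target power unreachable")
  lo <- max(2, n %/% 2)
  while (lo < n) {                       # integer bisection
    mid <- (lo + n) %/% 2
    if (f(mid) >= 0) n <- mid else lo <- mid + 1
  }
  as.integer(n)
}
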