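#' Two-group differential tests over a feature matrix
#'
#' Runs a two-sided Wilcoxon rank-sum or Student's t test per feature,
#' adjusts p-values with Benjamini-Hochberg across all features in the
#' call, and (optionally) characterizes every feature with ROC/AUC, DeLong
#' 95% CI and the Youden-optimal threshold. Log2 fold change is computed
#' from group means with a +1 pseudocount, second group level over first.
#'
#' @param values numeric matrix, samples x features (colnames = feature
#'   names).
#' @param groups factor (or coercible) with exactly two levels, one entry
#'   per sample; fold change and direction are level 2 vs level 1.
#' @param method "wilcoxon" (default), "t", or "auto" (Shapiro-Wilk at
#'   alpha 0.05 in both groups per feature chooses t, otherwise Wilcoxon).
#' @param roc also compute ROC summaries per feature (default TRUE).
#' @param alpha significance level for the \code{significant} flag on
#'   adjusted p-values (default 0.05).
#' @return data.frame of class \code{marker_result}: feature, per-group
#'   means, log2fc, test, p, p_adj, significant, degenerate and (when
#'   \code{roc}) auc, auc_ci_low, auc_ci_high, threshold, sensitivity,
#'   specificity, direction.
#' @export
test_features <- function(values, groups, method = c("wilcoxon", "t", "auto"),
                          roc = TRUE, alpha = 0.05) {
  method <- match.arg(method)
  values <- as.matrix(values)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2)
    stop("test_features: 'groups' must have exactly two levels")
  if (any(table(groups) < 3))
    stop("test_features: each group needs n >= 3")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2

  n <- ncol(values)
  p <- numeric(n); test_used <- character(n); degenerate <- logical(n)
  m1 <- colMeans(values[i1, , drop = FALSE])
  m2 <- colMeans(values[i2, , drop = FALSE])
  for (j in seq_len(n)) {
    x <- values[i1, j]; y <- values[i2, j]
    if (stats::var(values[, j]) == 0) {      # constant across all samples
      p[j] <- 1; test_used[j] <- "none"; degenerate[j] <- TRUE
      next
    }
    meth <- method
    if (meth == "auto") {
      sw <- function(v) {
        v <- v[seq_len(min(length(v), 5000))]
        if (length(unique(v)) < 3) return(0)
        stats::shapiro.test(v)$p.value
      }
      meth <- if (sw(x) > 0.05 && sw(y) > 0.05) "t" else "wilcoxon"
    }
    p[j] <- if (meth == "t") {
      stats::t.test(x, y)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
    }
    test_used[j] <- meth
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = colnames(values),
                    mean_1 = m1, mean_2 = m2,
                    log2fc = log2((m2 + 1) / (m1 + 1)),
                    test = test_used, p = p, p_adj = p_adj,
                    significant = p_adj < alpha,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", c(g1, g2))
  if (roc) {
    rocs <- lapply(seq_len(n), function(j) {
      if (degenerate[j]) {
        return(list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    threshold = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, direction = NA_character_))
      }
      roc_analysis(values[, j], groups)
    })
    out$auc <- vapply(rocs, `[[`, numeric(1), "auc")
    out$auc_ci_low <- vapply(rocs, `[[`, numeric(1), "ci_low")
    out$auc_ci_high <- vapply(rocs, `[[`, numeric(1), "ci_high")
    out$threshold <- vapply(rocs, `[[`, numeric(1), "threshold")
    out$sensitivity <- vapply(rocs, `[[`, numeric(1), "sensitivity")
    out$specificity <- vapply(rocs, `[[`, numeric(1), "specificity")
    out$direction <- vapply(rocs, `[[`, character(1), "direction")
  }
  class(out) <- c("marker_result", "data.frame")
  out
}

#' ROC characterization of one score vector
#'
#' AUC by the Mann-Whitney rank statistic with tie correction (via pROC),
#' auto-oriented so the reported AUC is >= 0.5 with the direction recorded;
#' 95% CI by DeLong's method; the best threshold maximizes the Youden index
#' (sensitivity + specificity - 1), ties broken by the lowest threshold.
#'
#' @param scores numeric vector.
#' @param labels two-level factor/vector parallel to \code{scores}.
#' @return list: auc, ci_low, ci_high, threshold, sensitivity, specificity,
#'   direction (the group label with the higher scores).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2)
    stop("roc_analysis: both classes must be present")
  # orient explicitly so the reported AUC is >= 0.5 (pROC's "auto" picks
  # the direction from group medians, which can leave AUC below 0.5)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = levels(labels), direction = "<", quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5)
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = levels(labels), direction = ">", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  co <- pROC::coords(r, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(co$threshold), , drop = FALSE][1, ]
  # pROC direction "<": controls (level 1) < cases (level 2)
  higher <- if (r$direction == "<") levels(labels)[2] else levels(labels)[1]
  list(auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[3], auc),
       threshold = co$threshold, sensitivity = co$sensitivity,
       specificity = co$specificity, direction = higher)
}

#' Per-sample single-EV co-occurrence frequencies of protein pairs
#'
#' For each sample and unordered protein pair, the fraction of the sample's
#' EVs carrying at least one UMI of both proteins. With \code{pairs =
#' "all"}, pairs are enumerated sparsely as those co-occurring on >= 1 EV
#' anywhere in the data.
#'
#' @param sev a \code{\link{single_ev_matrix}}.
#' @param pairs "all", or a character vector of "A-B" pair names, or a
#'   2-column matrix of protein names.
#' @return matrix samples x pairs of frequencies in [0, 1]; pair columns are
#'   named "A-B" with members sorted alphabetically.
#' @export
pair_frequencies <- function(sev, pairs = "all") {
  stopifnot(inherits(sev, "single_ev_matrix"))
  B <- sev$counts
  B@x[] <- 1                                  # presence/absence
  prot <- colnames(B)
  if (identical(pairs, "all")) {
    CO <- Matrix::crossprod(B)
    CO <- methods::as(Matrix::triu(CO, k = 1), "TsparseMatrix")
    keep <- CO@x > 0
    pi_ <- CO@i[keep] + 1L; pj <- CO@j[keep] + 1L
  } else {
    pm <- if (is.matrix(pairs)) pairs else
      do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
    pi_ <- match(pmin(pm[, 1], pm[, 2]), prot)
    pj <- match(pmax(pm[, 1], pm[, 2]), prot)
    if (anyNA(pi_) || anyNA(pj))
      stop("pair_frequencies: pair references a protein outside the panel")
  }
  # order pairs deterministically (by first then second member)
  o <- order(prot[pi_], prot[pj])
  pi_ <- pi_[o]; pj <- pj[o]
  pnames <- paste(prot[pi_], prot[pj], sep = "-")

  sids <- sev$ev_info$sample_id
  usid <- sort(unique(sids))
  nev <- table(sids)[usid]
  if (any(nev == 0)) stop("pair_frequencies: sample with zero EVs: ",
                          paste(usid[nev == 0], collapse = ", "))
  out <- matrix(0, length(usid), length(pnames),
                dimnames = list(usid, pnames))
  for (s in usid) {
    Bs <- B[sids == s, , drop = FALSE]
    COs <- Matrix::crossprod(Bs)
    out[s, ] <- COs[cbind(pi_, pj)] / sum(sids == s)
  }
  out
}

#' Differential protein-combination (DEPC) test
#'
#' Wilcoxon rank-sum (default) with BH adjustment on per-sample pair
#' frequencies; a DEPC is a pair with adjusted p below alpha. Same contract
#' and code path as \code{\link{test_features}}.
#'
#' @param freq samples x pairs frequency matrix from
#'   \code{\link{pair_frequencies}}.
#' @param groups two-level factor per sample.
#' @param method,roc,alpha as in \code{\link{test_features}}.
#' @return a \code{marker_result} data.frame.
#' @export
test_depc <- function(freq, groups, method = "wilcoxon", roc = TRUE,
                      alpha = 0.05) {
  test_features(freq, groups, method = method, roc = roc, alpha = alpha)
}
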