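# Independent brute-force oracles, coded straight from the published
# definitions; deliberately naive and kept separate from the package's
# implementations.

# All-pairs Mann-Whitney AUC: P(case > control) + 0.5 P(tie).
oracle_auc <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Trimmed mean of M-values, per the published algorithm: library-size
# normalized log-ratios against a reference sample chosen by the
# upper-quartile rule, double trimming by ranks of M and A, inverse
# asymptotic-variance weights, geometric-mean-1 rescaling.
# `counts` is samples x proteins.
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- rowSums(counts)
  f75 <- apply(counts, 1, stats::quantile, probs = 0.75) / lib
  ref <- if (stats::median(f75) < 1e-20) {
    which.max(rowSums(sqrt(counts)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
  one <- function(obs, refv, nO, nR) {
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (is.na(f) || !is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(nrow(counts)), function(s)
    one(counts[s, ], counts[ref, ], lib[s], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- rownames(counts)
  f
}

# Adjusted Rand index by the contingency-table formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force per-sample pair co-occurrence frequencies: double loop over
# EVs and pairs on a dense matrix.
oracle_pair_freq <- function(sev, pair_names) {
  M <- as.matrix(sev$counts) > 0
  sids <- sev$ev_info$sample_id
  usid <- sort(unique(sids))
  pm <- do.call(rbind, strsplit(pair_names, "-", fixed = TRUE))
  out <- matrix(0, length(usid), length(pair_names),
                dimnames = list(usid, pair_names))
  for (s in usid) {
    rows <- which(sids == s)
    for (k in seq_len(nrow(pm))) {
      hits <- 0
      for (r in rows) if (M[r, pm[k, 1]] && M[r, pm[k, 2]]) hits <- hits + 1
      out[s, k] <- hits / length(rows)
    }
  }
  out
}
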