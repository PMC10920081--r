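#' Aggregate single-EV counts to per-sample bulk counts
#'
#' Sums deduplicated molecule counts over all EVs of each sample, giving the
#' sample x protein integer matrix used for bulk differential analysis.
#'
#' @param sev a \code{\link{single_ev_matrix}}.
#' @param sample_metadata optional data.frame with columns sample_id and any
#'   of group/batch; every sample present in the matrix must appear in it.
#' @return object of class \code{bulk_counts}: list with \code{counts}
#'   (samples x proteins integer matrix), \code{samples} (metadata incl.
#'   n_evs), \code{lib_size} (row sums).
#' @export
aggregate_bulk <- function(sev, sample_metadata = NULL) {
  stopifnot(inherits(sev, "single_ev_matrix"))
  sids <- sev$ev_info$sample_id
  usid <- sort(unique(sids))
  if (!is.null(sample_metadata)) {
    missing <- setdiff(usid, sample_metadata$sample_id)
    if (length(missing))
      stop("aggregate_bulk: samples absent from metadata: ",
           paste(missing, collapse = ", "))
  }
  ind <- Matrix::sparseMatrix(i = match(sids, usid), j = seq_along(sids), x = 1,
                              dims = c(length(usid), length(sids)))
  counts <- as.matrix(ind %*% sev$counts)
  storage.mode(counts) <- "integer"
  rownames(counts) <- usid
  samples <- data.table::data.table(sample_id = usid,
                                    n_evs = as.integer(table(sids)[usid]))
  if (!is.null(sample_metadata))
    samples <- merge(samples, data.table::as.data.table(sample_metadata),
                     by = "sample_id", sort = TRUE)
  bulk_counts(counts, samples)
}

#' Construct a bulk_counts object
#' @param counts integer matrix, samples x proteins (rownames = sample ids).
#' @param samples data.frame of per-sample metadata (sample_id first).
#' @return a \code{bulk_counts}.
#' @export
bulk_counts <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("bulk_counts: counts must be non-negative integers")
  samples <- data.table::as.data.table(samples)
  stopifnot(identical(samples$sample_id, rownames(counts)))
  structure(list(counts = counts, samples = samples,
                 lib_size = rowSums(counts)),
            class = "bulk_counts")
}

#' @export
print.bulk_counts <- function(x, ...) {
  cat("bulk_counts:", nrow(x$counts), "samples x", ncol(x$counts),
      "proteins; median library size", stats::median(x$lib_size), "\n")
  invisible(x)
}

#' Remove plate batch effects while preserving integer counts
#'
#' Negative-binomial batch adjustment via ComBat-seq, which maps each count
#' through its batch distribution to the batch-free quantile and therefore
#' keeps the data integer. The biological group is protected by default so
#' the case/control signal is not absorbed into the batch term.
#'
#' @param bulk a \code{\link{bulk_counts}}.
#' @param batch_col metadata column holding the plate label (default
#'   "batch").
#' @param group_col metadata column to protect (default "group"); NULL
#'   disables protection.
#' @return a \code{bulk_counts} with adjusted integer counts.
#' @export
adjust_batches <- function(bulk, batch_col = "batch", group_col = "group") {
  stopifnot(inherits(bulk, "bulk_counts"))
  batch <- bulk$samples[[batch_col]]
  if (is.null(batch)) stop("adjust_batches: no '", batch_col, "' column in metadata")
  tab <- table(batch)
  if (length(tab) == 1L) return(bulk)   # single plate: nothing to adjust
  if (any(tab < 2L))
    stop("adjust_batches: batch(es) with a single sample (",
         paste(names(tab)[tab < 2L], collapse = ", "),
         "); merge them into another plate or drop them")
  group <- if (!is.null(group_col)) bulk$samples[[group_col]] else NULL
  nz <- colSums(bulk$counts) > 0
  adj <- t(bulk$counts[, nz, drop = FALSE])
  adj <- sva::ComBat_seq(adj, batch = as.character(batch), group = group)
  out <- bulk$counts
  out[, nz] <- t(adj)
  storage.mode(out) <- "integer"
  bulk_counts(out, bulk$samples)
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (edgeR), with the canonical defaults:
#' reference sample chosen by the upper-quartile rule, 30% two-sided trim on
#' log-ratios, 5% on average log-abundance, precision-weighted mean, and
#' rescaling so the factors have geometric mean 1.
#'
#' @param bulk a \code{\link{bulk_counts}}.
#' @param trim_M two-sided trim fraction on M values (default 0.3).
#' @param trim_A two-sided trim fraction on A values (default 0.05).
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(bulk, trim_M = 0.3, trim_A = 0.05) {
  stopifnot(inherits(bulk, "bulk_counts"))
  if (nrow(bulk$counts) < 2) stop("tmm_factors: need >= 2 samples")
  if (any(bulk$lib_size <= 0)) stop("tmm_factors: sample(s) with zero library size")
  d <- edgeR::DGEList(counts = t(bulk$counts))
  # suppress edgeR internals (empty max() when samples share no proteins);
  # that case is reported below with a factor of 1
  d <- suppressWarnings(
    edgeR::calcNormFactors(d, method = "TMM",
                           logratioTrim = trim_M, sumTrim = trim_A))
  f <- d$samples$norm.factors
  names(f) <- rownames(bulk$counts)
  if (anyNA(f) || any(!is.finite(f))) {
    warning("tmm_factors: sample(s) share no positive proteins with the reference; factor set to 1")
    f[!is.finite(f) | is.na(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  f
}

#' TMM-normalized expression
#'
#' Counts scaled to counts-per-million of the effective library size
#' (library size x TMM factor), optionally log2(x + 1) transformed.
#'
#' @param bulk a \code{\link{bulk_counts}}.
#' @param log2 apply log2(x + 1).
#' @param trim_M,trim_A trim fractions passed to \code{\link{tmm_factors}}.
#' @return object of class \code{normalized_matrix}: list with \code{expr}
#'   (samples x proteins), \code{factors}, \code{effective_lib_size}.
#' @export
normalize_bulk <- function(bulk, log2 = FALSE, trim_M = 0.3, trim_A = 0.05) {
  f <- tmm_factors(bulk, trim_M, trim_A)
  eff <- bulk$lib_size * f
  expr <- bulk$counts / eff * 1e6
  if (log2) expr <- log2(expr + 1)
  structure(list(expr = expr, factors = f, effective_lib_size = eff,
                 log2 = log2, samples = bulk$samples),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$expr), "samples x", ncol(x$expr),
      "proteins; TMM factors in [", signif(min(x$factors), 3), ",",
      signif(max(x$factors), 3), "]\n")
  invisible(x)
}
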