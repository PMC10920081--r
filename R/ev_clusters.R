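#' Down-sample EVs per group
#'
#' Uniform sampling without replacement of \code{n_per_group} EVs within
#' each group (the group of an EV is its sample's group), so that
#' downstream composition tests have a known expected proportion.
#'
#' @param sev a \code{\link{single_ev_matrix}}.
#' @param sample_groups named vector mapping sample_id to group label.
#' @param n_per_group EVs to keep per group.
#' @param seed integer seed.
#' @return a \code{single_ev_matrix} with exactly
#'   \code{n_per_group x n_groups} EV rows.
#' @export
downsample_evs <- function(sev, sample_groups, n_per_group, seed) {
  stopifnot(inherits(sev, "single_ev_matrix"))
  grp <- unname(sample_groups[sev$ev_info$sample_id])
  if (anyNA(grp)) stop("downsample_evs: EV sample without a group label")
  set.seed(seed)
  keep <- integer(0)
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    if (length(idx) < n_per_group)
      stop("downsample_evs: group '", g, "' has only ", length(idx),
           " EVs (need ", n_per_group, ")")
    keep <- c(keep, sort(sample(idx, n_per_group)))
  }
  sev_subset(sev, keep)
}

# Per-EV normalization shared by clustering and marker finding:
# scale each EV's counts to a fixed total (median EV total by default),
# then log1p.
normalize_evs <- function(sev, scale_target = NULL, log1p = TRUE) {
  totals <- Matrix::rowSums(sev$counts)
  target <- scale_target %||% stats::median(totals)
  X <- as.matrix(sev$counts / totals * target)
  if (log1p) X <- log1p(X)
  X
}

#' Cluster single EVs into subpopulations
#'
#' Seurat-style pipeline on the EV x protein matrix: scale each EV to a
#' fixed total, log1p, PCA, cosine-metric kNN graph, and Leiden (or
#' Louvain) community detection at a given resolution. Labels are 0-based,
#' ordered by decreasing cluster size; the first two principal components
#' serve as a 2-D embedding.
#'
#' @param sev a \code{\link{single_ev_matrix}}.
#' @param dims number of principal components (capped at proteins - 1).
#' @param k neighbours for the kNN graph.
#' @param resolution community-detection resolution.
#' @param scale_target per-EV scaling target (default: median EV total).
#' @param log1p log-transform flag.
#' @param method "leiden" (default) or "louvain".
#' @param seed integer seed (required: community detection is stochastic).
#' @return object of class \code{cluster_model}: list with \code{labels}
#'   (integer, 0-based), \code{embedding} (n x 2), \code{params}.
#' @export
cluster_evs <- function(sev, dims = 20L, k = 15L, resolution = 1.0,
                        scale_target = NULL, log1p = TRUE,
                        method = c("leiden", "louvain"), seed) {
  stopifnot(inherits(sev, "single_ev_matrix"))
  method <- match.arg(method)
  n <- nrow(sev$counts); P <- ncol(sev$counts)
  if (n < 2) stop("cluster_evs: need >= 2 EVs")
  if (dims >= P) stop("cluster_evs: dims must be < number of proteins")
  if (missing(seed)) stop("cluster_evs: 'seed' is required")
  X <- normalize_evs(sev, scale_target, log1p)
  # EV protein profiles are highly discrete, so many EVs are exact
  # duplicates; a kNN graph over raw EVs would fragment into cliques of
  # identical points. The graph is therefore built over distinct profiles
  # and labels propagated back to the EVs.
  cs <- Matrix::summary(sev$counts)
  keys <- vapply(split(paste(cs$j, cs$x, sep = ":"), cs$i),
                 paste, character(1), collapse = ",")
  keys <- keys[as.character(seq_len(n))]
  prof <- match(keys, unique(keys))
  u <- which(!duplicated(prof))
  Xu <- X[u, , drop = FALSE]
  nu <- nrow(Xu)
  ku <- min(k, nu - 1L)
  set.seed(seed)
  pc <- stats::prcomp(Xu, rank. = dims, center = TRUE, scale. = FALSE)
  Y <- pc$x
  memb_u <- rep(1L, nu)
  if (nu > 1L && ku >= 1L) {
    # cosine metric: L2-normalize, then euclidean kNN has the same ordering
    nrm <- sqrt(rowSums(Y^2)); nrm[nrm == 0] <- 1
    Yn <- Y / nrm
    nn <- RANN::nn2(Yn, k = ku + 1L)$nn.idx[, -1, drop = FALSE]
    edges <- cbind(rep(seq_len(nu), ku), as.vector(nn))
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nu - igraph::vcount(g)))
    comm <- if (method == "leiden") {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution, n_iterations = 10)
    } else {
      igraph::cluster_louvain(g, resolution = resolution)
    }
    memb_u <- as.integer(igraph::membership(comm))
  }
  memb <- memb_u[prof]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  emb <- Y[prof, 1:2, drop = FALSE]
  colnames(emb) <- c("dim1", "dim2")
  structure(list(labels = as.integer(labels), embedding = emb,
                 params = list(dims = dims, k = k, resolution = resolution,
                               scale_target = scale_target, log1p = log1p,
                               method = method, seed = seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", length(x$labels), "EVs in",
      length(unique(x$labels)), "clusters (", x$params$method,
      ", resolution", x$params$resolution, ")\n")
  invisible(x)
}

#' Cluster-specific marker proteins
#'
#' One-vs-rest Wilcoxon rank-sum per protein per cluster on the per-EV
#' normalized expression (same normalization as the clustering), with BH
#' adjustment within each cluster. Markers are proteins with adjusted
#' p < alpha and average log2 fold change > 0 in the cluster.
#'
#' @param sev a \code{\link{single_ev_matrix}}.
#' @param labels integer cluster labels from \code{\link{cluster_evs}}.
#' @param scale_target,log1p normalization parameters (match the
#'   clustering).
#' @param alpha significance level (default 0.05).
#' @return data.frame with cluster, feature, avg_log2fc, p, p_adj, marker.
#' @export
find_cluster_markers <- function(sev, labels, scale_target = NULL,
                                 log1p = TRUE, alpha = 0.05) {
  stopifnot(inherits(sev, "single_ev_matrix"),
            length(labels) == nrow(sev$counts))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("find_cluster_markers: need >= 2 clusters")
  X <- normalize_evs(sev, scale_target, log1p)
  out <- list()
  for (cl in clusters) {
    inside <- labels == cl
    if (sum(inside) < 2) {
      warning("find_cluster_markers: singleton cluster ", cl, " skipped")
      next
    }
    grp <- factor(ifelse(inside, "cluster", "rest"),
                  levels = c("rest", "cluster"))
    res <- test_features(X, grp, method = "wilcoxon", roc = FALSE,
                         alpha = alpha)
    out[[as.character(cl)]] <- data.frame(
      cluster = cl, feature = res$feature, avg_log2fc = res$log2fc,
      p = res$p, p_adj = res$p_adj,
      marker = res$p_adj < alpha & res$log2fc > 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Binomial test of group composition per cluster
#'
#' Exact two-sided binomial test, per cluster, of the number of EVs from
#' one group against the expected proportion implied by the down-sampling
#' design, with BH adjustment across clusters.
#'
#' @param labels integer cluster labels.
#' @param ev_groups two-level factor/vector of per-EV group labels.
#' @param group which group's proportion is tested (default: first level).
#' @param expected_proportion expected proportion of that group (default:
#'   its overall proportion in \code{ev_groups}, i.e. the down-sample
#'   design).
#' @return data.frame of class \code{composition_result}: cluster, size,
#'   per-group counts, proportion, expected, p, p_adj.
#' @export
composition_test <- function(labels, ev_groups, group = NULL,
                             expected_proportion = NULL) {
  ev_groups <- droplevels(factor(ev_groups))
  if (nlevels(ev_groups) != 2)
    stop("composition_test: exactly two groups required")
  stopifnot(length(labels) == length(ev_groups))
  group <- group %||% levels(ev_groups)[1]
  expected <- expected_proportion %||% mean(ev_groups == group)
  clusters <- sort(unique(labels))
  rows <- lapply(clusters, function(cl) {
    inside <- labels == cl
    n <- sum(inside)
    k <- sum(ev_groups[inside] == group)
    data.frame(cluster = cl, size = n, n_group = k, n_other = n - k,
               proportion = k / n, expected = expected,
               p = stats::binom.test(k, n, p = expected)$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("composition_result", "data.frame")
  out
}
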