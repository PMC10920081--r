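#' Default pipeline configuration
#'
#' Flat stage-keyed configuration for \code{\link{run_pipeline}}. The bare
#' default reproduces a study-scale synthetic replica (100 cancer + 100
#' control samples); tests and examples override the simulate block with
#' small sizes.
#'
#' @param seed global seed.
#' @return nested list of stage blocks.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    alpha = 0.05,
    stages = list(simulate = TRUE, decode = TRUE, preprocess = TRUE,
                  dep = TRUE, depc = TRUE, cluster = TRUE,
                  classify = TRUE, power = TRUE),
    simulate = list(design = NULL),   # NULL: default_design(seed = seed)
    decode = list(min_mean_phred = 20, max_hamming = 0L),
    preprocess = list(batch_col = "batch", group_col = "phenotype",
                      trim_M = 0.3, trim_A = 0.05),
    dep = list(method = "wilcoxon"),
    depc = list(method = "wilcoxon"),
    cluster = list(n_per_group = 20000L, dims = 20L, k = 15L,
                   resolution = 1.0, method = "leiden"),
    classify = list(top = 10L, k = 10L, min_methods = 2L),
    power = list(auc_alt = 0.8, auc_null = 0.5, alpha = 0.05)
  )
}

# Coerce a plain (e.g. YAML-parsed) list into a simulation_design:
# named-vector fields arrive as named lists and need unlisting.
design_from_list <- function(x) {
  if (inherits(x, "simulation_design")) return(x)
  num <- function(v) if (is.null(v)) NULL else unlist(v)
  x$n_samples_per_group <- num(x$n_samples_per_group)
  x$mean_proteins_per_ev <- num(x$mean_proteins_per_ev)
  x$subpopulations <- lapply(x$subpopulations, function(sp) {
    sp$weight <- num(sp$weight); sp$incl <- num(sp$incl); sp
  })
  x$planted_deps <- lapply(x$planted_deps %||% list(), num)
  x$planted_pairs <- lapply(x$planted_pairs %||% list(), function(pp) {
    pp$excess <- num(pp$excess); pp
  })
  x$proteins <- unlist(x$proteins)
  if (!is.null(x$quality_law)) x$quality_law <- lapply(x$quality_law, unlist)
  do.call(simulation_design, x[!vapply(x, is.null, logical(1))])
}

# cancer/control phenotype from group labels (control vs everything else)
phenotype_of <- function(group) {
  factor(ifelse(group == "control", "control", "cancer"),
         levels = c("control", "cancer"))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate, decode, preprocess, DEP, DEPC, cluster, classify
#' and power stages in dependency order under a single configuration,
#' writing every artifact plus a JSON manifest (file md5 hashes,
#' parameters, seed, package version) into the run directory. A stage
#' failure halts downstream stages and still writes the partial manifest.
#'
#' @param config a list as returned by \code{\link{default_pipeline_config}}
#'   (missing entries are filled with defaults), or a path to a YAML file
#'   holding one.
#' @param out_dir run directory (created).
#' @return invisible list of stage results; artifacts under \code{out_dir}.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config(seed = config$seed %||% 1L)
  config <- utils::modifyList(base, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pbaev")),
                   config = config[setdiff(names(config), "simulate")],
                   stages = list(), files = list())
  log_msg <- function(...) message("[pbaev] ", ...)
  write_manifest <- function() {
    fls <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    fls <- setdiff(fls, file.path(out_dir, "manifest.json"))
    manifest$files <<- lapply(stats::setNames(fls, sub(paste0(out_dir, "/"), "", fls)),
                              function(f) list(md5 = unname(tools::md5sum(f)),
                                               bytes = file.size(f)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(write_manifest())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    log_msg("stage ", name)
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    results[[name]] <<- res
    res
  }

  sim_dir <- file.path(out_dir, "simulate")
  run_stage("simulate", function() {
    design <- if (is.null(config$simulate$design)) {
      default_design(seed = config$seed)
    } else {
      design_from_list(config$simulate$design)
    }
    truth <- simulate_truth(design)
    panel <- panel_design(design$proteins, truth$samples$sample_id,
                          seed = config$seed + 7L)
    paths <- emit_reads(truth, panel, dir = sim_dir)
    list(design = design, truth = truth, panel = panel, paths = paths)
  })

  run_stage("decode", function() {
    sim <- results$simulate
    dec <- build_matrix(sim$paths$fastq, sim$panel,
                        min_mean_phred = config$decode$min_mean_phred,
                        max_hamming = config$decode$max_hamming)
    write_sev(dec$matrix, file.path(out_dir, "decode"))
    jsonlite::write_json(dec$report[c("reads_in", "rejected_low_quality",
                                      "rejected_sample_tag",
                                      "rejected_protein_tag", "accepted",
                                      "molecules")],
                         file.path(out_dir, "decode", "decode_report.json"),
                         auto_unbox = TRUE)
    log_msg("decode: ", dec$report$accepted, "/", dec$report$reads_in,
            " reads accepted, ", nrow(dec$matrix$counts), " EVs")
    dec
  })

  run_stage("preprocess", function() {
    sim <- results$simulate
    meta <- data.table::copy(sim$truth$samples)
    meta[, phenotype := phenotype_of(group)]
    bulk <- aggregate_bulk(results$decode$matrix, meta)
    n_batches <- length(unique(bulk$samples[[config$preprocess$batch_col]]))
    if (n_batches > 1)
      bulk <- adjust_batches(bulk, config$preprocess$batch_col,
                             config$preprocess$group_col)
    norm <- normalize_bulk(bulk, trim_M = config$preprocess$trim_M,
                           trim_A = config$preprocess$trim_A)
    dir.create(file.path(out_dir, "preprocess"), showWarnings = FALSE)
    utils::write.table(bulk$counts,
                       file.path(out_dir, "preprocess", "bulk_counts.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(as.list(norm$factors),
                         file.path(out_dir, "preprocess", "tmm_factors.json"),
                         auto_unbox = TRUE, digits = NA)
    list(bulk = bulk, norm = norm)
  })

  run_stage("dep", function() {
    norm <- results$preprocess$norm
    groups <- phenotype_of(norm$samples$group)
    res <- test_features(norm$expr, groups, method = config$dep$method,
                         alpha = config$alpha)
    dir.create(file.path(out_dir, "dep"), showWarnings = FALSE)
    utils::write.table(res, file.path(out_dir, "dep", "dep_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("dep: ", sum(res$significant), "/", nrow(res), " significant")
    res
  })

  run_stage("depc", function() {
    sev <- results$decode$matrix
    freq <- pair_frequencies(sev, pairs = "all")
    meta <- results$simulate$truth$samples
    groups <- phenotype_of(meta$group[match(rownames(freq), meta$sample_id)])
    res <- test_depc(freq, groups, method = config$depc$method,
                     alpha = config$alpha)
    dir.create(file.path(out_dir, "depc"), showWarnings = FALSE)
    utils::write.table(res, file.path(out_dir, "depc", "depc_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("depc: ", sum(res$significant), "/", nrow(res), " significant")
    list(freq = freq, result = res)
  })

  run_stage("cluster", function() {
    sev <- results$decode$matrix
    meta <- results$simulate$truth$samples
    grp <- stats::setNames(as.character(phenotype_of(meta$group)), meta$sample_id)
    npg <- min(config$cluster$n_per_group,
               min(table(grp[sev$ev_info$sample_id])))
    ds <- downsample_evs(sev, grp, npg, seed = config$seed)
    cm <- cluster_evs(ds, dims = min(config$cluster$dims, ncol(ds$counts) - 1L),
                      k = config$cluster$k,
                      resolution = config$cluster$resolution,
                      method = config$cluster$method, seed = config$seed)
    ev_grp <- grp[ds$ev_info$sample_id]
    comp <- composition_test(cm$labels, ev_grp, group = "cancer")
    markers <- find_cluster_markers(ds, cm$labels, alpha = config$alpha)
    dir.create(file.path(out_dir, "cluster"), showWarnings = FALSE)
    utils::write.table(data.frame(ds$ev_info, cluster = cm$labels, cm$embedding),
                       file.path(out_dir, "cluster", "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comp, file.path(out_dir, "cluster", "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(markers, file.path(out_dir, "cluster", "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(model = cm, composition = comp, markers = markers)
  })

  run_stage("classify", function() {
    norm <- results$preprocess$norm
    dep <- results$dep
    groups <- phenotype_of(norm$samples$group)
    top <- dep$feature[order(dep$p_adj)][seq_len(min(config$classify$top,
                                                     nrow(dep)))]
    Xd <- as.data.frame(norm$expr[, top, drop = FALSE])
    reports <- lapply(c("stepwise", "lasso", "random_forest"), function(m)
      select_features(Xd, groups, method = m, seed = config$seed))
    ranking <- stats::setNames(dep$p_adj, dep$feature)
    consensus <- consensus_select(reports, config$classify$min_methods, ranking)
    eval_res <- if (length(consensus)) {
      evaluate_kfold_auc(Xd, groups, consensus, k = config$classify$k,
                         seed = config$seed)
    } else NULL
    dir.create(file.path(out_dir, "classify"), showWarnings = FALSE)
    jsonlite::write_json(
      list(candidates = top,
           selected = lapply(stats::setNames(reports, vapply(reports, `[[`,
                                                             "", "method")),
                             `[[`, "selected"),
           consensus = consensus,
           mean_cv_auc = if (!is.null(eval_res)) eval_res$mean_auc else NA,
           cv_auc_ci = if (!is.null(eval_res)) eval_res$ci else NA),
      file.path(out_dir, "classify", "model.json"),
      auto_unbox = TRUE, digits = NA)
    list(reports = reports, consensus = consensus, evaluation = eval_res)
  })

  run_stage("power", function() {
    sim <- results$simulate
    tab <- table(phenotype_of(sim$truth$samples$group))
    pw <- auc_test_power(config$power$auc_alt, config$power$auc_null,
                         n1 = tab[["cancer"]], n0 = tab[["control"]],
                         alpha = config$power$alpha)
    jsonlite::write_json(list(auc_alt = config$power$auc_alt,
                              n1 = tab[["cancer"]], n0 = tab[["control"]],
                              power = pw),
                         file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)
    pw
  })

  invisible(results)
}
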