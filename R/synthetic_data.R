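#' Simulation design for PBA-style single-EV data
#'
#' A \code{simulation_design} captures every generative choice needed to
#' emulate a plasma proximity-barcoding-assay (PBA) experiment: per-group
#' sample counts, a log-normal law for EVs per sample, a mixture of EV
#' subpopulations (each a per-protein inclusion-probability profile with a
#' mean molecule load), planted differential proteins (fold changes on
#' inclusion probability), planted protein pairs (excess co-occurrence),
#' plate batch effects, PCR duplication, substitution errors and a per-base
#' quality law.
#'
#' @param n_samples_per_group named integer vector, samples per group label.
#' @param ev_count_law named list (one entry per group) of
#'   \code{list(meanlog, sdlog)} log-normal parameters for EVs per sample.
#' @param subpopulations list of subpopulations, each
#'   \code{list(weight, incl, lambda)}: \code{weight} a named per-group
#'   mixture weight, \code{incl} a base per-protein inclusion-probability
#'   vector (length = number of proteins), \code{lambda} the mean molecule
#'   count per included protein (zero-truncated Poisson).
#' @param proteins character vector of panel protein identifiers.
#' @param mean_proteins_per_ev optional named per-group target for the mean
#'   number of distinct proteins per EV (conditional on >= 1). When given,
#'   inclusion profiles are rescaled per group to hit the target exactly in
#'   expectation.
#' @param planted_deps named list: protein -> named per-group fold change
#'   applied to its inclusion probability (after calibration).
#' @param planted_pairs list of \code{list(a, b, mode, excess)} entries;
#'   \code{mode} is \code{"couple"} (margin-preserving joint distribution,
#'   \code{excess} = signed per-group excess of P(A and B) over independence)
#'   or \code{"inject"} (with per-group probability \code{excess} force joint
#'   inclusion of both proteins, adding events beyond the independent margins).
#' @param batch_size samples per plate (round-robin assignment), default 96.
#' @param batch_effect_sdlog log-normal sd of per-plate per-protein
#'   multiplicative factors on expected molecule counts; 0 disables.
#' @param pcr_duplication_mean expected sequencing reads per molecule (>= 1).
#' @param substitution_rate per-base substitution error probability in [0, 0.2].
#' @param quality_law \code{list(q, p)}: discrete Phred score values and
#'   their probabilities, applied i.i.d. per base.
#' @param seed integer seed; identical designs give bit-identical output.
#' @return object of class \code{simulation_design}.
#' @export
simulation_design <- function(n_samples_per_group,
                              ev_count_law,
                              subpopulations,
                              proteins,
                              mean_proteins_per_ev = NULL,
                              planted_deps = list(),
                              planted_pairs = list(),
                              batch_size = 96L,
                              batch_effect_sdlog = 0,
                              pcr_duplication_mean = 1,
                              substitution_rate = 0,
                              quality_law = list(q = 37L, p = 1),
                              seed = 1L) {
  groups <- names(n_samples_per_group)
  if (is.null(groups) || any(groups == ""))
    stop("simulation_design: 'n_samples_per_group' must be a named vector")
  if (any(n_samples_per_group < 1))
    stop("simulation_design: 'n_samples_per_group' entries must be >= 1")
  if (!setequal(names(ev_count_law), groups))
    stop("simulation_design: 'ev_count_law' must name every group")
  for (k in seq_along(subpopulations)) {
    sp <- subpopulations[[k]]
    if (length(sp$incl) != length(proteins))
      stop("simulation_design: 'subpopulations[[", k, "]]$incl' length != number of proteins")
    if (any(sp$incl < 0 | sp$incl > 1))
      stop("simulation_design: 'subpopulations' inclusion probabilities outside [0,1]")
    if (sp$lambda <= 0)
      stop("simulation_design: 'subpopulations[[", k, "]]$lambda' must be > 0")
    if (!all(groups %in% names(sp$weight)))
      stop("simulation_design: 'subpopulations[[", k, "]]$weight' must name every group")
  }
  for (g in groups) {
    w <- vapply(subpopulations, function(sp) sp$weight[[g]], numeric(1))
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop("simulation_design: 'subpopulations' mixture weights for group '",
           g, "' must be non-negative and sum to 1")
  }
  for (p in names(planted_deps)) {
    if (!p %in% proteins)
      stop("simulation_design: 'planted_deps' names unknown protein '", p, "'")
    if (any(unlist(planted_deps[[p]]) <= 0))
      stop("simulation_design: 'planted_deps' fold changes must be > 0")
  }
  for (pp in planted_pairs) {
    if (!all(c(pp$a, pp$b) %in% proteins))
      stop("simulation_design: 'planted_pairs' references unknown protein")
    if (!pp$mode %in% c("couple", "inject"))
      stop("simulation_design: 'planted_pairs' mode must be 'couple' or 'inject'")
  }
  if (pcr_duplication_mean < 1)
    stop("simulation_design: 'pcr_duplication_mean' must be >= 1")
  if (substitution_rate < 0 || substitution_rate > 0.2)
    stop("simulation_design: 'substitution_rate' must be in [0, 0.2]")
  if (abs(sum(quality_law$p) - 1) > 1e-8 || any(quality_law$p < 0))
    stop("simulation_design: 'quality_law' probabilities must sum to 1")
  structure(list(
    n_samples_per_group = n_samples_per_group,
    group_labels = groups,
    ev_count_law = ev_count_law,
    subpopulations = subpopulations,
    proteins = proteins,
    mean_proteins_per_ev = mean_proteins_per_ev,
    planted_deps = planted_deps,
    planted_pairs = planted_pairs,
    batch_size = as.integer(batch_size),
    batch_effect_sdlog = batch_effect_sdlog,
    pcr_duplication_mean = pcr_duplication_mean,
    substitution_rate = substitution_rate,
    quality_law = quality_law,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Default design emulating the plasma pan-cancer PBA study
#'
#' Two phenotypes: 100 controls and 100 cancer samples (five cancer types,
#' 20 each). Per-sample EV counts are log-normal with group medians 134,291
#' (cancer) and 61,569 (control); the mean number of distinct proteins per
#' EV is calibrated to 2.85 (cancer) and 3.40 (control) over a 207-protein
#' panel organised into six overlapping subpopulation profiles.
#'
#' @param n_samples_per_group optionally override the per-group sample
#'   counts (names must be a subset of control/ES/ST/CR/LI/LU).
#' @param ev_median_cancer,ev_median_control median EVs per sample.
#' @param ev_sdlog log-normal sdlog of EVs per sample.
#' @param n_proteins panel size.
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{simulation_design}}
#'   (planted_deps, planted_pairs, substitution_rate, ...).
#' @return a \code{simulation_design}.
#' @export
default_design <- function(n_samples_per_group = c(control = 100L, ES = 20L,
                                                   ST = 20L, CR = 20L,
                                                   LI = 20L, LU = 20L),
                           ev_median_cancer = 134291,
                           ev_median_control = 61569,
                           ev_sdlog = 0.5,
                           n_proteins = 207L,
                           seed = 1L, ...) {
  groups <- names(n_samples_per_group)
  cancer <- setdiff(groups, "control")
  proteins <- sprintf("EVP%03d", seq_len(n_proteins))
  law <- lapply(groups, function(g) {
    med <- if (g == "control") ev_median_control else ev_median_cancer
    list(meanlog = log(med), sdlog = ev_sdlog)
  })
  names(law) <- groups
  K <- 6L
  block <- ceiling(n_proteins / K)
  subpops <- lapply(seq_len(K), function(k) {
    incl <- rep(0.02, n_proteins)                    # ubiquitous background
    core <- ((k - 1L) * block + 1L):min(k * block, n_proteins)
    incl[core] <- 0.30                               # subpopulation signature
    w <- if (k <= 2) {
      c(control = 1 / K, stats::setNames(rep(0.25, length(cancer)), cancer))
    } else {
      c(control = 1 / K, stats::setNames(rep(0.5 / (K - 2), length(cancer)), cancer))
    }
    list(weight = w, incl = incl, lambda = 1.3)
  })
  target <- stats::setNames(ifelse(groups == "control", 3.40, 2.85), groups)
  simulation_design(
    n_samples_per_group = n_samples_per_group,
    ev_count_law = law,
    subpopulations = subpops,
    proteins = proteins,
    mean_proteins_per_ev = target,
    batch_size = 96L,
    batch_effect_sdlog = 0.15,
    pcr_duplication_mean = 1.8,
    substitution_rate = 0.005,
    quality_law = list(q = c(37L, 25L, 11L), p = c(0.88, 0.09, 0.03)),
    seed = seed, ...)
}

# Conditional (on >= 1 inclusion) mean number of distinct proteins per EV
# for one subpopulation profile scaled by s.
cond_mean_proteins <- function(incl, s) {
  q <- pmin(incl * s, 1)
  mu <- sum(q)
  p0 <- prod(1 - q)
  if (p0 >= 1) return(0)
  mu / (1 - p0)
}

# Per-group inclusion scale factors hitting mean_proteins_per_ev targets.
calibrate_scales <- function(design) {
  groups <- design$group_labels
  out <- stats::setNames(rep(1, length(groups)), groups)
  tg <- design$mean_proteins_per_ev
  if (is.null(tg)) return(out)
  for (g in groups) {
    w <- vapply(design$subpopulations, function(sp) sp$weight[[g]], numeric(1))
    f <- function(s) {
      sum(w * vapply(design$subpopulations,
                     function(sp) cond_mean_proteins(sp$incl, s), numeric(1))) - tg[[g]]
    }
    smax <- 1 / max(vapply(design$subpopulations, function(sp) max(sp$incl), numeric(1)))
    if (f(smax) < 0)
      stop("simulation_design: mean_proteins_per_ev target for group '", g,
           "' is unreachable with the given inclusion profiles")
    out[g] <- stats::uniroot(f, c(1e-9, smax), tol = 1e-12)$root
  }
  out
}

# Resolved per-(group, subpopulation) inclusion probabilities after
# calibration and planted fold changes.
resolve_inclusion <- function(design) {
  scales <- calibrate_scales(design)
  groups <- design$group_labels
  P <- length(design$proteins)
  out <- list()
  for (g in groups) {
    out[[g]] <- lapply(design$subpopulations, function(sp) {
      q <- pmin(sp$incl * scales[[g]], 1)
      q
    })
    for (p in names(design$planted_deps)) {
      fc <- design$planted_deps[[p]]
      fcg <- if (g %in% names(fc)) fc[[g]] else 1
      j <- match(p, design$proteins)
      for (k in seq_along(out[[g]]))
        out[[g]][[k]][j] <- min(out[[g]][[k]][j] * fcg, 0.999)
    }
  }
  out
}

# Draw the inclusion matrix (m EVs x P proteins) for one (group, subpop),
# honouring planted pairs, then redraw all-zero EVs.
draw_inclusion <- function(m, q, design, g) {
  P <- length(q)
  draw_once <- function(mm) {
    inc <- matrix(stats::runif(mm * P) < rep(q, each = mm), mm, P)
    for (pp in design$planted_pairs) {
      e <- if (g %in% names(pp$excess)) pp$excess[[g]] else 0
      if (e == 0) next
      ia <- match(pp$a, design$proteins); ib <- match(pp$b, design$proteins)
      pa <- q[ia]; pb <- q[ib]
      if (pp$mode == "couple") {
        p11 <- pa * pb + e
        lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
        if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
          stop("planted_pairs: excess ", e, " for pair (", pp$a, ",", pp$b,
               ") in group '", g, "' gives joint probability ", signif(p11, 4),
               " outside the feasible range [", signif(lo, 4), ", ",
               signif(hi, 4), "]")
        a <- stats::runif(mm) < pa
        pb_given <- ifelse(a, p11 / pa, (pb - p11) / (1 - pa))
        b <- stats::runif(mm) < pb_given
        inc[, ia] <- a; inc[, ib] <- b
      } else {                         # inject: joint events beyond margins
        w <- stats::runif(mm) < e
        inc[w, ia] <- TRUE; inc[w, ib] <- TRUE
      }
    }
    inc
  }
  inc <- draw_once(m)
  for (it in 1:100) {
    zero <- which(rowSums(inc) == 0L)
    if (!length(zero)) break
    inc[zero, ] <- draw_once(length(zero))
  }
  zero <- which(rowSums(inc) == 0L)
  if (length(zero)) {                   # pathological profiles: force one protein
    j <- sample.int(P, length(zero), replace = TRUE, prob = pmax(q, 1e-12))
    inc[cbind(zero, j)] <- TRUE
  }
  inc
}

#' Simulate ground-truth single-EV populations
#'
#' Draws, for every sample, its EV count from the group's log-normal law,
#' assigns each EV to a subpopulation, includes proteins per the (calibrated,
#' fold-change-modified) inclusion probabilities with planted pair
#' co-occurrence, and draws molecule counts from a zero-truncated Poisson
#' whose mean is modulated by the sample's plate batch factor. Every molecule
#' receives a UMI (uniform over 4^8, collisions allowed); every EV receives
#' a 15-nt EV tag unique within its sample.
#'
#' @param design a \code{\link{simulation_design}}.
#' @return object of class \code{pba_truth}: list with \code{samples}
#'   (sample_id, group, batch), \code{evs} (sample_id, ev_id, subpop,
#'   ev_tag integer code), \code{molecules} (sample_id, ev_id, protein, umi
#'   integer code; one row per molecule), \code{batch_factors}, and the
#'   design.
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  groups <- design$group_labels
  P <- length(design$proteins)
  incl <- resolve_inclusion(design)
  lambda_k <- vapply(design$subpopulations, `[[`, numeric(1), "lambda")
  K <- length(design$subpopulations)

  samples <- data.table::data.table(
    sample_id = sprintf("S%03d", seq_len(sum(design$n_samples_per_group))),
    group = rep(groups, design$n_samples_per_group)
  )
  samples[, batch := sprintf("plate%d", ((seq_len(.N) - 1L) %/% design$batch_size) + 1L)]
  plates <- unique(samples$batch)
  bf <- matrix(1, length(plates), P, dimnames = list(plates, design$proteins))
  if (design$batch_effect_sdlog > 0)
    bf[] <- stats::rlnorm(length(plates) * P, 0, design$batch_effect_sdlog)

  ev_list <- vector("list", nrow(samples))
  mol_list <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    g <- samples$group[i]
    law <- design$ev_count_law[[g]]
    n_ev <- max(1L, as.integer(round(stats::rlnorm(1, law$meanlog, law$sdlog))))
    w <- vapply(design$subpopulations, function(sp) sp$weight[[g]], numeric(1))
    subpop <- sample.int(K, n_ev, replace = TRUE, prob = w)
    ev_tag <- sample.int(4^15, n_ev) - 1  # unique within sample
    bfac <- bf[samples$batch[i], ]
    sub_mols <- vector("list", K)
    for (k in seq_len(K)) {
      rows <- which(subpop == k)
      if (!length(rows)) next
      inc <- draw_inclusion(length(rows), incl[[g]][[k]], design, g)
      hit <- which(inc, arr.ind = TRUE)
      if (!nrow(hit)) next
      lam <- lambda_k[k] * bfac[hit[, 2]]
      nm <- rztpois(nrow(hit), lam)
      sub_mols[[k]] <- data.table::data.table(
        ev_id = rows[hit[, 1]],
        protein = design$proteins[hit[, 2]],
        n = nm)
    }
    mols <- data.table::rbindlist(sub_mols)
    mols <- mols[rep(seq_len(.N), n)]
    mols[, n := NULL]
    mols[, umi := sample.int(4^8, .N, replace = TRUE) - 1L]
    mols[, sample_id := sid]
    ev_list[[i]] <- data.table::data.table(
      sample_id = sid, ev_id = seq_len(n_ev), subpop = subpop, ev_tag = ev_tag)
    mol_list[[i]] <- mols
  }
  structure(list(
    samples = samples,
    evs = data.table::rbindlist(ev_list),
    molecules = data.table::rbindlist(mol_list)[, .(sample_id, ev_id, protein, umi)],
    batch_factors = bf,
    design = design
  ), class = "pba_truth")
}

#' Ground-truth deduplicated molecule counts
#'
#' Counts per (sample, EV, protein): total molecules and distinct UMIs (the
#' quantity a perfect decoder recovers; UMI collisions within a group make
#' the two differ).
#'
#' @param truth a \code{pba_truth}.
#' @return data.table with sample_id, ev_id, ev_tag, protein, n_molecules,
#'   n_umis.
#' @export
truth_counts <- function(truth) {
  stopifnot(inherits(truth, "pba_truth"))
  ev_id <- protein <- umi <- sample_id <- NULL
  cnt <- truth$molecules[, .(n_molecules = .N,
                             n_umis = data.table::uniqueN(umi)),
                         by = .(sample_id, ev_id, protein)]
  out <- merge(cnt, truth$evs[, c("sample_id", "ev_id", "ev_tag")],
               by = c("sample_id", "ev_id"))
  data.table::setorder(out, sample_id, ev_id, protein)
  out[]
}

#' Ground-truth single-EV matrix (perfect decode)
#'
#' The \code{\link{single_ev_matrix}} a perfect decoder would produce from
#' this truth: deduplicated (distinct-UMI) counts per (sample, EV tag,
#' protein).
#'
#' @param truth a \code{pba_truth}.
#' @return a \code{single_ev_matrix}.
#' @export
truth_matrix <- function(truth) {
  tc <- truth_counts(truth)
  cnt <- data.table::data.table(sample_id = tc$sample_id,
                                ev_tag = int_to_dna(tc$ev_tag, 15L),
                                protein = tc$protein,
                                count = tc$n_umis)
  single_ev_matrix(cnt, proteins = truth$design$proteins)
}

#' @export
print.pba_truth <- function(x, ...) {
  cat("pba_truth:", nrow(x$samples), "samples,", nrow(x$evs), "EVs,",
      nrow(x$molecules), "molecules\n")
  invisible(x)
}

#' Emit PBA-style FASTQ reads from a ground truth
#'
#' Each molecule yields a shifted-Poisson number of reads (mean =
#' \code{pcr_duplication_mean}); the read sequence concatenates the sample
#' tag, 15-nt EV tag, 8-nt protein tag and 8-nt UMI per the layout, with
#' i.i.d. per-base substitution errors and qualities drawn from the design's
#' quality law. A per-read truth table, the panel, sample metadata, truth
#' count tables and a JSON run manifest are written alongside the FASTQ.
#'
#' @param truth a \code{pba_truth}.
#' @param panel a \code{\link{panel_design}} covering every simulated
#'   protein and sample.
#' @param layout a \code{\link{read_layout}} (defaults to the canonical
#'   contiguous layout for the panel's sample-tag length).
#' @param dir output directory (created if needed).
#' @param gzip write FASTQ gzipped.
#' @return invisible list of file paths plus the number of reads written.
#' @export
emit_reads <- function(truth, panel, layout = NULL, dir, gzip = FALSE) {
  stopifnot(inherits(truth, "pba_truth"), inherits(panel, "panel_design"))
  design <- truth$design
  if (is.null(layout))
    layout <- read_layout(sample_tag_len = nchar(names(panel$sample_tag_map)[1]))
  orphans <- setdiff(unique(truth$molecules$protein), unname(panel$protein_tag_map))
  if (length(orphans))
    stop("emit_reads: proteins without a panel tag: ", paste(orphans, collapse = ", "))
  missing_s <- setdiff(truth$samples$sample_id, unname(panel$sample_tag_map))
  if (length(missing_s))
    stop("emit_reads: samples without a sample tag: ", paste(missing_s, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(design$seed + 1L)

  prot_tag <- stats::setNames(names(panel$protein_tag_map), unname(panel$protein_tag_map))
  samp_tag <- stats::setNames(names(panel$sample_tag_map), unname(panel$sample_tag_map))

  mols <- merge(truth$molecules,
                truth$evs[, c("sample_id", "ev_id", "ev_tag")],
                by = c("sample_id", "ev_id"), sort = FALSE)
  n_mol <- nrow(mols)
  nreads <- 1L + stats::rpois(n_mol, design$pcr_duplication_mean - 1)
  idx <- rep(seq_len(n_mol), nreads)

  seqs <- paste0(samp_tag[mols$sample_id[idx]],
                 int_to_dna(mols$ev_tag[idx], 15L),
                 prot_tag[mols$protein[idx]],
                 int_to_dna(mols$umi[idx], 8L))
  mut <- mutate_bases(seqs, design$substitution_rate)
  quals <- random_quality_strings(length(seqs), nchar(seqs[1]) %||% layout$read_length,
                                  design$quality_law)
  read_id <- sprintf("pba:%08d", seq_along(seqs))

  fq <- file.path(dir, if (gzip) "reads.fastq.gz" else "reads.fastq")
  con <- if (gzip) gzfile(fq, "wb") else file(fq, "wb")
  writeLines(as.vector(rbind(paste0("@", read_id), mut$seq, "+", quals)), con)
  close(con)

  read_truth <- data.table::data.table(
    read_id = read_id,
    sample_id = mols$sample_id[idx],
    ev_id = mols$ev_id[idx],
    protein = mols$protein[idx],
    umi = int_to_dna(mols$umi[idx], 8L),
    n_errors = mut$n_errors)
  paths <- list(fastq = fq,
                read_truth = file.path(dir, "truth_reads.tsv"),
                truth_counts = file.path(dir, "truth_counts.tsv"),
                panel = file.path(dir, "panel.tsv"),
                sample_tags = file.path(dir, "sample_tags.tsv"),
                samples = file.path(dir, "samples.tsv"),
                manifest = file.path(dir, "manifest.json"))
  data.table::fwrite(read_truth, paths$read_truth, sep = "\t")
  data.table::fwrite(truth_counts(truth), paths$truth_counts, sep = "\t")
  data.table::fwrite(data.table::data.table(protein = unname(panel$protein_tag_map),
                                            tag = names(panel$protein_tag_map)),
                     paths$panel, sep = "\t")
  data.table::fwrite(data.table::data.table(sample_id = unname(panel$sample_tag_map),
                                            tag = names(panel$sample_tag_map)),
                     paths$sample_tags, sep = "\t")
  data.table::fwrite(truth$samples, paths$samples, sep = "\t")
  jsonlite::write_json(list(seed = design$seed,
                            design_hash = design_hash(design),
                            n_molecules = n_mol,
                            n_reads = length(seqs)),
                       paths$manifest, auto_unbox = TRUE)
  invisible(c(paths, list(n_reads = length(seqs), n_molecules = n_mol)))
}

# Stable md5 of a design (serialization v2 written to a scratch file).
design_hash <- function(design) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(design, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}
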