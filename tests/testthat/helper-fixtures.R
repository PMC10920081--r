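# Small fixtures built in code.

# A compact two-group design over `p` proteins (first half favoured in
# group a, second half in group b), overridable via ...
small_design <- function(n_a = 3L, n_b = 3L, evs = 200, p = 20L,
                         seed = 42L, ...) {
  proteins <- sprintf("EVP%02d", seq_len(p))
  half <- p %/% 2
  simulation_design(
    n_samples_per_group = c(a = n_a, b = n_b),
    ev_count_law = list(a = list(meanlog = log(evs), sdlog = 0.3),
                        b = list(meanlog = log(evs), sdlog = 0.3)),
    subpopulations = list(
      list(weight = c(a = 0.5, b = 0.5),
           incl = c(rep(0.3, half), rep(0.02, p - half)), lambda = 1.3),
      list(weight = c(a = 0.5, b = 0.5),
           incl = c(rep(0.02, half), rep(0.3, p - half)), lambda = 1.3)),
    proteins = proteins,
    mean_proteins_per_ev = c(a = 2.85, b = 3.40),
    seed = seed, ...)
}

# Build a single_ev_matrix directly from an inclusion matrix (count 1 per
# included protein); row i of `inc` is one EV of sample `sample_ids[i]`.
sev_from_inc <- function(inc, sample_ids, proteins = NULL) {
  stopifnot(nrow(inc) == length(sample_ids))
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(ncol(inc)))
  inc[rowSums(inc) == 0, 1] <- TRUE
  w <- which(inc, arr.ind = TRUE)
  cnt <- data.table::data.table(sample_id = sample_ids[w[, 1]],
                                ev_tag = sprintf("ev%06d", w[, 1]),
                                protein = proteins[w[, 2]],
                                count = 1L)
  sev <- single_ev_matrix(cnt, proteins = proteins)
  # restore original EV order
  key <- paste(sample_ids, sprintf("ev%06d", seq_len(nrow(inc))), sep = ":")
  sev_subset(sev, match(key, rownames(sev$counts)))
}

# Random inclusion matrix: n EVs, per-protein probabilities `probs`.
random_inc <- function(n, probs) {
  matrix(stats::runif(n * length(probs)) < rep(probs, each = n), n)
}

# Hand-written FASTQ from explicit fields, canonical 8/15/8/8 layout.
write_test_fastq <- function(path, sample_tag, ev_tag, protein_tag, umi,
                             qual_char = "F") {
  seqs <- paste0(sample_tag, ev_tag, protein_tag, umi)
  quals <- strrep(qual_char, nchar(seqs))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", quals)),
             path)
  path
}
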