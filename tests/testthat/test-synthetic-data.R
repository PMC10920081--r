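test_that("invalid designs are rejected with the offending field named", {
  base <- small_design()
  expect_error(simulation_design(
    n_samples_per_group = c(a = 2L, b = 2L),
    ev_count_law = list(a = list(meanlog = 3, sdlog = 0.3),
                        b = list(meanlog = 3, sdlog = 0.3)),
    subpopulations = list(list(weight = c(a = 0.6, b = 1), incl = rep(0.1, 5),
                               lambda = 1),
                          list(weight = c(a = 0.6, b = 0), incl = rep(0.1, 5),
                               lambda = 1)),
    proteins = sprintf("p%d", 1:5)), "weights")
  expect_error(simulation_design(
    n_samples_per_group = c(a = 2L), ev_count_law = list(a = list(meanlog = 3, sdlog = 1)),
    subpopulations = list(list(weight = c(a = 1), incl = rep(0.1, 5), lambda = 1)),
    proteins = sprintf("p%d", 1:5),
    planted_deps = list(p1 = c(a = -2))), "fold changes")
  expect_error(simulation_design(
    n_samples_per_group = c(a = 2L), ev_count_law = list(a = list(meanlog = 3, sdlog = 1)),
    subpopulations = list(list(weight = c(a = 1), incl = rep(0.1, 5), lambda = 1)),
    proteins = sprintf("p%d", 1:5),
    pcr_duplication_mean = 0.5), "pcr_duplication_mean")
  expect_error(simulation_design(
    n_samples_per_group = c(a = 2L), ev_count_law = list(a = list(meanlog = 3, sdlog = 1)),
    subpopulations = list(list(weight = c(a = 1), incl = rep(0.1, 5), lambda = 1)),
    proteins = sprintf("p%d", 1:5),
    substitution_rate = 0.5), "substitution_rate")
  expect_s3_class(base, "simulation_design")
})

test_that("deterministic limit: inclusion probability 1 on 3 proteins gives exactly those, count 1", {
  d <- simulation_design(
    n_samples_per_group = c(a = 2L),
    ev_count_law = list(a = list(meanlog = log(100), sdlog = 0)),
    subpopulations = list(list(weight = c(a = 1),
                               incl = c(1, 1, 1, 0, 0), lambda = 1e-8)),
    proteins = sprintf("p%d", 1:5), seed = 7L)
  tr <- simulate_truth(d)
  tc <- truth_counts(tr)
  expect_setequal(unique(tc$protein), c("p1", "p2", "p3"))
  expect_true(all(tc$n_molecules == 1L))
  per_ev <- tc[, .N, by = .(sample_id, ev_id)]
  expect_true(all(per_ev$N == 3L))
})

test_that("injected pair planting raises joint inclusion by e*(1 - pA*pB)", {
  p <- 0.1; e <- 0.5
  d <- simulation_design(
    n_samples_per_group = c(a = 1L),
    ev_count_law = list(a = list(meanlog = log(50000), sdlog = 0)),
    subpopulations = list(list(weight = c(a = 1),
                               incl = c(p, p, 1), lambda = 0.5)),
    proteins = c("A", "B", "C"),
    planted_pairs = list(list(a = "A", b = "B", mode = "inject",
                              excess = c(a = e))),
    seed = 11L)
  tr <- simulate_truth(d)
  tc <- truth_counts(tr)
  n_ev <- nrow(tr$evs)
  has <- tc[, .(a = any(protein == "A"), b = any(protein == "B")),
            by = .(ev_id)]
  p_ab <- sum(has$a & has$b) / n_ev
  # expected excess over the configured-margin product, from the generative
  # definition: P(A and B) = e + (1-e) pA pB, so P(A and B) - pA pB = e(1 - pA pB)
  expect_equal(p_ab - p * p, e * (1 - p * p), tolerance = 0.01 / (e * (1 - p^2)))
})

test_that("coupled pair planting preserves margins while shifting co-occurrence", {
  p <- 0.35; e <- 0.12
  d <- simulation_design(
    n_samples_per_group = c(a = 1L),
    ev_count_law = list(a = list(meanlog = log(50000), sdlog = 0)),
    subpopulations = list(list(weight = c(a = 1),
                               incl = c(p, p, 1, 0.9), lambda = 0.5)),
    proteins = c("A", "B", "C", "D"),
    planted_pairs = list(list(a = "A", b = "B", mode = "couple",
                              excess = c(a = e))),
    seed = 12L)
  tr <- simulate_truth(d)
  tc <- truth_counts(tr)
  n_ev <- nrow(tr$evs)
  has <- tc[, .(a = any(protein == "A"), b = any(protein == "B")), by = .(ev_id)]
  expect_equal(sum(has$a) / n_ev, p, tolerance = 0.03)
  expect_equal(sum(has$b) / n_ev, p, tolerance = 0.03)
  expect_equal(sum(has$a & has$b) / n_ev, p * p + e, tolerance = 0.02)
  # infeasible excess errors out naming the pair
  d_bad <- simulation_design(
    n_samples_per_group = c(a = 1L),
    ev_count_law = list(a = list(meanlog = log(100), sdlog = 0)),
    subpopulations = list(list(weight = c(a = 1),
                               incl = c(p, p, 1, 0.9), lambda = 0.5)),
    proteins = c("A", "B", "C", "D"),
    planted_pairs = list(list(a = "A", b = "B", mode = "couple",
                              excess = c(a = 0.5))),
    seed = 12L)
  expect_error(simulate_truth(d_bad), "feasible range")
})

test_that("mean distinct proteins per EV is calibrated to the group targets", {
  d <- simulation_design(
    n_samples_per_group = c(cancer = 1L, control = 1L),
    ev_count_law = list(cancer = list(meanlog = log(1e5), sdlog = 0),
                        control = list(meanlog = log(1e5), sdlog = 0)),
    subpopulations = list(
      list(weight = c(cancer = 0.5, control = 0.5),
           incl = c(rep(0.3, 15), rep(0.02, 15)), lambda = 1.3),
      list(weight = c(cancer = 0.5, control = 0.5),
           incl = c(rep(0.02, 15), rep(0.3, 15)), lambda = 1.3)),
    proteins = sprintf("p%02d", 1:30),
    mean_proteins_per_ev = c(cancer = 2.85, control = 3.40),
    seed = 5L)
  tr <- simulate_truth(d)
  tc <- truth_counts(tr)
  per_ev <- merge(tc[, .N, by = .(sample_id, ev_id)], tr$samples,
                  by = "sample_id")
  means <- per_ev[, mean(N), by = group]
  expect_equal(means[group == "cancer", V1], 2.85, tolerance = 0.1 / 2.85)
  expect_equal(means[group == "control", V1], 3.40, tolerance = 0.1 / 3.40)
})

test_that("identical seed gives identical truth and byte-identical FASTQ", {
  d <- small_design(evs = 100, pcr_duplication_mean = 1.5,
                    substitution_rate = 0.01,
                    quality_law = list(q = c(37L, 12L), p = c(0.9, 0.1)))
  tr1 <- simulate_truth(d)
  tr2 <- simulate_truth(d)
  expect_identical(tr1, tr2)
  panel <- panel_design(d$proteins, tr1$samples$sample_id, seed = 3L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_reads(tr1, panel, dir = d1)
  p2 <- emit_reads(tr2, panel, dir = d2)
  expect_identical(readBin(p1$fastq, "raw", file.size(p1$fastq)),
                   readBin(p2$fastq, "raw", file.size(p2$fastq)))
})

test_that("read emission conserves molecules and respects the duplication law", {
  d <- small_design(evs = 150, pcr_duplication_mean = 1,
                    substitution_rate = 0)
  tr <- simulate_truth(d)
  panel <- panel_design(d$proteins, tr$samples$sample_id, seed = 3L)
  out <- emit_reads(tr, panel, dir = withr::local_tempdir())
  # mean 1 duplication: one read per molecule, exactly
  expect_identical(out$n_reads, nrow(tr$molecules))

  d2 <- small_design(evs = 150, pcr_duplication_mean = 2.5, seed = 9L)
  tr2 <- simulate_truth(d2)
  out2 <- emit_reads(tr2, panel_design(d2$proteins, tr2$samples$sample_id,
                                       seed = 3L),
                     dir = withr::local_tempdir())
  expect_gte(out2$n_reads, out2$n_molecules)
  expect_equal(out2$n_reads / out2$n_molecules, 2.5, tolerance = 0.05)
})

test_that("substitution errors hit the 8-nt protein tag at the binomial rate", {
  d <- small_design(n_a = 2L, n_b = 2L, evs = 2000,
                    substitution_rate = 0.01, seed = 21L)
  tr <- simulate_truth(d)
  panel <- panel_design(d$proteins, tr$samples$sample_id, seed = 3L)
  dir <- withr::local_tempdir()
  out <- emit_reads(tr, panel, dir = dir)
  fq <- readLines(out$fastq)
  seqs <- fq[seq(2, length(fq), by = 4)]
  truth <- data.table::fread(out$read_truth)
  tag_of <- stats::setNames(names(panel$protein_tag_map),
                            unname(panel$protein_tag_map))
  obs_tag <- substr(seqs, 24, 31)
  frac_err <- mean(obs_tag != tag_of[truth$protein])
  expect_equal(frac_err, 1 - 0.99^8, tolerance = 0.005 / (1 - 0.99^8))
})

test_that("configured group medians of per-sample EV counts are ordered", {
  d <- simulation_design(
    n_samples_per_group = c(cancer = 50L, control = 50L),
    ev_count_law = list(cancer = list(meanlog = log(268), sdlog = 0.5),
                        control = list(meanlog = log(123), sdlog = 0.5)),
    subpopulations = list(list(weight = c(cancer = 1, control = 1),
                               incl = rep(0.3, 10), lambda = 1.2)),
    proteins = sprintf("p%d", 1:10), seed = 33L)
  tr <- simulate_truth(d)
  n_ev <- tr$evs[, .N, by = sample_id]
  m <- merge(n_ev, tr$samples, by = "sample_id")
  med <- m[, stats::median(N), by = group]
  expect_gt(med[group == "cancer", V1], med[group == "control", V1])
  # sign test: cancer sample EV counts exceed the pooled median more often
  pooled <- stats::median(m$N)
  k <- sum(m[group == "cancer", N] > pooled)
  pv <- stats::binom.test(k, 50, 0.5, alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("a protein without a panel tag is reported as orphan", {
  d <- small_design(evs = 50)
  tr <- simulate_truth(d)
  panel <- panel_design(d$proteins[1:10], tr$samples$sample_id, seed = 3L)
  expect_error(emit_reads(tr, panel, dir = withr::local_tempdir()),
               "without a panel tag")
})
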