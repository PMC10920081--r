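#' Panel design: tag dictionaries for decoding
#'
#' Maps 8-nt protein tags to protein identifiers and sample tags to sample
#' identifiers. When 1-mismatch correction is requested at decode time the
#' panel must guarantee a minimum pairwise Hamming distance of 3 so that
#' corrections are unambiguous.
#'
#' @param proteins character vector of protein identifiers.
#' @param sample_ids character vector of sample identifiers.
#' @param protein_tags optional character vector of 8-nt tags (parallel to
#'   \code{proteins}); generated when NULL.
#' @param sample_tags optional character vector of tags (parallel to
#'   \code{sample_ids}); generated when NULL.
#' @param sample_tag_len length of generated sample tags (default 8).
#' @param min_pairwise_hamming minimum pairwise Hamming distance enforced
#'   when generating tags (default 3).
#' @param seed seed for tag generation.
#' @return object of class \code{panel_design} with named-character fields
#'   \code{protein_tag_map} (tag -> protein) and \code{sample_tag_map}
#'   (tag -> sample id).
#' @export
panel_design <- function(proteins, sample_ids,
                         protein_tags = NULL, sample_tags = NULL,
                         sample_tag_len = 8L,
                         min_pairwise_hamming = 3L, seed = 99L) {
  stopifnot(length(proteins) >= 1, length(sample_ids) >= 1)
  if (anyDuplicated(proteins)) stop("panel_design: duplicated protein identifiers")
  if (anyDuplicated(sample_ids)) stop("panel_design: duplicated sample identifiers")
  if (is.null(protein_tags) || is.null(sample_tags)) set.seed(seed)
  if (is.null(protein_tags))
    protein_tags <- make_tag_set(length(proteins), 8L, min_pairwise_hamming)
  if (is.null(sample_tags))
    sample_tags <- make_tag_set(length(sample_ids), sample_tag_len, min_pairwise_hamming)
  if (any(nchar(protein_tags) != 8L)) stop("panel_design: protein tags must be 8 nt")
  if (anyDuplicated(protein_tags)) stop("panel_design: duplicated protein tags")
  if (anyDuplicated(sample_tags)) stop("panel_design: duplicated sample tags")
  if (length(unique(nchar(sample_tags))) != 1L)
    stop("panel_design: sample tags must share one length")
  structure(list(
    protein_tag_map = stats::setNames(proteins, protein_tags),
    sample_tag_map = stats::setNames(sample_ids, sample_tags),
    min_pairwise_hamming = as.integer(min_pairwise_hamming)
  ), class = "panel_design")
}

#' Read layout: where each tag lives in the read
#'
#' The canonical PBA read is a contiguous concatenation
#' [sample tag | 15-nt EV tag | 8-nt protein tag | 8-nt UMI] with no
#' spacers; alternative offsets can be supplied for other dialects.
#'
#' @param sample_tag_len sample-tag length (default 8).
#' @param segments optional data.frame with columns \code{name}
#'   (sample_tag/ev_tag/protein_tag/umi), \code{start} (1-based),
#'   \code{length}; overrides the canonical layout.
#' @return object of class \code{read_layout}.
#' @export
read_layout <- function(sample_tag_len = 8L, segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(
      name = c("sample_tag", "ev_tag", "protein_tag", "umi"),
      start = cumsum(c(1L, sample_tag_len, 15L, 8L)),
      length = c(sample_tag_len, 15L, 8L, 8L))
    segments$start <- c(1L, 1L + sample_tag_len, 1L + sample_tag_len + 15L,
                        1L + sample_tag_len + 15L + 8L)
  }
  need <- c("sample_tag", "ev_tag", "protein_tag", "umi")
  if (!setequal(segments$name, need))
    stop("read_layout: segments must be exactly ", paste(need, collapse = ", "))
  if (segments$length[segments$name == "ev_tag"] != 15L)
    stop("read_layout: ev_tag must be 15 nt")
  if (segments$length[segments$name == "protein_tag"] != 8L)
    stop("read_layout: protein_tag must be 8 nt")
  if (segments$length[segments$name == "umi"] != 8L)
    stop("read_layout: umi must be 8 nt")
  ends <- segments$start + segments$length - 1L
  o <- order(segments$start)
  if (any(segments$start[o][-1] <= ends[o][-length(o)]))
    stop("read_layout: segments overlap")
  structure(list(segments = segments, read_length = max(ends)),
            class = "read_layout")
}

layout_segment <- function(layout, name) {
  i <- match(name, layout$segments$name)
  c(start = layout$segments$start[i], length = layout$segments$length[i])
}

#' Mean-quality read filter
#'
#' Keeps a read iff its mean Phred score is at least the threshold
#' (boundary inclusive); this is the per-read reading of the study's
#' "quality score < 20" removal rule.
#'
#' @param qualities a numeric vector of per-base Phred scores for one read,
#'   or a character vector of Phred+33-encoded quality strings (one per
#'   read).
#' @param min_mean_phred threshold (default 20).
#' @return logical: keep (TRUE) or reject, vectorized over reads when
#'   \code{qualities} is a character vector.
#' @export
filter_quality <- function(qualities, min_mean_phred = 20) {
  if (is.character(qualities)) {
    means <- vapply(qualities, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE)
    return(means >= min_mean_phred)
  }
  mean(qualities) >= min_mean_phred
}

#' Match an observed tag against a dictionary
#'
#' Exact match, or unique match within Hamming distance 1 when
#' \code{max_hamming = 1}; ties at the minimal distance are no-matches.
#'
#' @param observed character vector of observed tag sequences.
#' @param dictionary named character vector: tag sequence -> identifier.
#' @param max_hamming 0 (exact) or 1.
#' @return character vector of identifiers, NA where unmatched.
#' @export
match_tag <- function(observed, dictionary, max_hamming = 0L) {
  if (!length(dictionary)) stop("match_tag: empty dictionary")
  tag_len <- nchar(names(dictionary)[1])
  if (any(nchar(observed) != tag_len))
    stop("match_tag: observed tags must have length ", tag_len)
  if (!max_hamming %in% c(0L, 1L)) stop("match_tag: max_hamming must be 0 or 1")
  ids <- unname(dictionary[observed])
  if (max_hamming == 1L) {
    lut <- hamming1_lookup(dictionary)
    miss <- which(is.na(ids))
    if (length(miss)) ids[miss] <- unname(lut[observed[miss]])
  }
  ids
}

# Lookup table mapping Hamming-1 neighbours of dictionary tags to their
# identifier; neighbours claimed by two entries, or equal to another exact
# tag, are dropped (ambiguous / dominated by the exact match).
hamming1_lookup <- function(dictionary) {
  nb <- lapply(names(dictionary), hamming1_neighbours)
  variant <- unlist(nb)
  id <- rep(unname(dictionary), lengths(nb))
  keep <- !(variant %in% names(dictionary))
  variant <- variant[keep]; id <- id[keep]
  dup <- variant %in% variant[duplicated(variant)]
  amb <- variant[dup]
  # a variant reachable from two entries is ambiguous even if both map to it
  drop <- variant %in% amb
  stats::setNames(id[!drop], variant[!drop])
}

#' Decode PBA FASTQ reads into a single-EV count matrix
#'
#' Applies the mean-quality filter, extracts the layout segments, matches
#' sample and protein tags, groups accepted reads by (sample, EV tag,
#' protein) and counts distinct UMIs per group. Returns the sparse EV x
#' protein matrix together with a full rejection report.
#'
#' @param fastq path to a FASTQ or FASTQ.gz file.
#' @param panel a \code{\link{panel_design}}.
#' @param layout a \code{\link{read_layout}}.
#' @param min_mean_phred mean-Phred acceptance threshold (default 20).
#' @param max_hamming tag-correction radius, 0 or 1 (1 requires panel
#'   \code{min_pairwise_hamming >= 3}).
#' @return list with \code{matrix} (a \code{\link{single_ev_matrix}}) and
#'   \code{report} (a \code{decode_report}).
#' @export
build_matrix <- function(fastq, panel, layout = NULL,
                         min_mean_phred = 20, max_hamming = 0L) {
  stopifnot(inherits(panel, "panel_design"))
  if (is.null(layout))
    layout <- read_layout(sample_tag_len = nchar(names(panel$sample_tag_map)[1]))
  if (max_hamming > 0L && panel$min_pairwise_hamming < 3L)
    stop("build_matrix: 1-mismatch correction requires pairwise Hamming distance >= 3")
  # suppressWarnings: the reader warns about dropping FASTQ metadata columns
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- as.character(reads)
  if (any(nchar(seqs) < layout$read_length))
    stop("build_matrix: reads shorter than the layout (", layout$read_length, " nt)")
  quals <- as(Biostrings::quality(reads), "IntegerList")
  mean_q <- sum(quals) / lengths(quals)

  n_in <- length(seqs)
  keep_q <- mean_q >= min_mean_phred
  seqs <- seqs[keep_q]

  seg <- function(nm) {
    s <- layout_segment(layout, nm)
    substr(seqs, s["start"], s["start"] + s["length"] - 1L)
  }
  sample_id <- match_tag(seg("sample_tag"), panel$sample_tag_map, max_hamming)
  ok_s <- !is.na(sample_id)
  protein <- match_tag(seg("protein_tag"), panel$protein_tag_map, max_hamming)
  ok_p <- !is.na(protein)
  ok <- ok_s & ok_p
  rej_sample <- sum(!ok_s)
  rej_protein <- sum(ok_s & !ok_p)

  dt <- data.table::data.table(
    sample_id = sample_id[ok],
    ev_tag = seg("ev_tag")[ok],
    protein = protein[ok],
    umi = seg("umi")[ok])

  report <- structure(list(
    reads_in = n_in,
    rejected_low_quality = sum(!keep_q),
    rejected_sample_tag = rej_sample,
    rejected_protein_tag = rej_protein,
    accepted = nrow(dt),
    molecules = NA_integer_,
    evs_per_sample = NULL
  ), class = "decode_report")

  if (nrow(dt) == 0L) {
    cond <- structure(class = c("pbaev_empty_decode", "error", "condition"),
                      list(message = "build_matrix: zero accepted reads",
                           call = sys.call(), report = report))
    stop(cond)
  }
  umi <- ev_tag <- NULL
  counts <- dt[, .(count = data.table::uniqueN(umi)),
               by = .(sample_id, ev_tag, protein)]
  sev <- single_ev_matrix(counts, proteins = unname(panel$protein_tag_map))
  report$molecules <- sum(counts$count)
  report$evs_per_sample <- table(sev$ev_info$sample_id)
  list(matrix = sev, report = report)
}

#' @export
print.decode_report <- function(x, ...) {
  cat("decode_report:", x$reads_in, "reads in;",
      x$rejected_low_quality, "low-quality,",
      x$rejected_sample_tag, "bad sample tag,",
      x$rejected_protein_tag, "bad protein tag;",
      x$accepted, "accepted;", x$molecules, "molecules\n")
  invisible(x)
}

#' Sparse single-EV protein count matrix
#'
#' Rows are EVs (keyed by sample x EV tag), columns are panel proteins,
#' values are deduplicated molecule counts (distinct UMIs). EV tags are
#' scoped per sample: the same tag in two samples is two EVs.
#'
#' @param counts data.frame/data.table with columns sample_id, ev_tag,
#'   protein, count (one row per nonzero entry).
#' @param proteins full protein universe for the columns (defaults to the
#'   proteins present).
#' @return object of class \code{single_ev_matrix}: list with \code{counts}
#'   (dgCMatrix, EVs x proteins) and \code{ev_info} (sample_id, ev_tag).
#' @export
single_ev_matrix <- function(counts, proteins = NULL) {
  counts <- data.table::as.data.table(counts)
  stopifnot(all(c("sample_id", "ev_tag", "protein", "count") %in% names(counts)))
  if (any(counts$count <= 0)) stop("single_ev_matrix: counts must be positive")
  if (is.null(proteins)) proteins <- sort(unique(counts$protein))
  key <- paste(counts$sample_id, counts$ev_tag, sep = ":")
  ev_keys <- unique(key)
  i <- match(key, ev_keys)
  j <- match(counts$protein, proteins)
  if (anyNA(j)) stop("single_ev_matrix: protein outside the given universe")
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(counts$count),
                            dims = c(length(ev_keys), length(proteins)),
                            dimnames = list(ev_keys, proteins))
  first <- !duplicated(key)
  ev_info <- data.table::data.table(sample_id = counts$sample_id[first],
                                    ev_tag = counts$ev_tag[first])
  structure(list(counts = m, ev_info = ev_info), class = "single_ev_matrix")
}

#' @export
print.single_ev_matrix <- function(x, ...) {
  cat("single_ev_matrix:", nrow(x$counts), "EVs x", ncol(x$counts),
      "proteins;", length(unique(x$ev_info$sample_id)), "samples\n")
  invisible(x)
}

#' @export
dim.single_ev_matrix <- function(x) dim(x$counts)

#' Subset a single-EV matrix by EV rows
#' @param sev a \code{single_ev_matrix}.
#' @param rows integer or logical row index.
#' @return a \code{single_ev_matrix}.
#' @export
sev_subset <- function(sev, rows) {
  structure(list(counts = sev$counts[rows, , drop = FALSE],
                 ev_info = sev$ev_info[rows, ]),
            class = "single_ev_matrix")
}

#' Write / read a single-EV matrix in MatrixMarket convention
#'
#' Writes \code{matrix.mtx} plus \code{barcodes.tsv} (sample_id, ev_tag)
#' and \code{features.tsv} (protein) annotation files.
#'
#' @param sev a \code{single_ev_matrix}.
#' @param dir output directory.
#' @return invisible vector of paths (\code{write_sev}); a
#'   \code{single_ev_matrix} (\code{read_sev}).
#' @export
write_sev <- function(sev, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sev$counts, file.path(dir, "matrix.mtx"))
  data.table::fwrite(sev$ev_info, file.path(dir, "barcodes.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(protein = colnames(sev$counts)),
                     file.path(dir, "features.tsv"), sep = "\t")
  invisible(file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv")))
}

#' @rdname write_sev
#' @export
read_sev <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # writeMM stores an all-ones matrix as a binary pattern; restore numeric
  m <- methods::as(m * 1, "CsparseMatrix")
  ev_info <- data.table::fread(file.path(dir, "barcodes.tsv"))
  feats <- data.table::fread(file.path(dir, "features.tsv"))
  dimnames(m) <- list(paste(ev_info$sample_id, ev_info$ev_tag, sep = ":"),
                      feats$protein)
  structure(list(counts = m, ev_info = ev_info), class = "single_ev_matrix")
}
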