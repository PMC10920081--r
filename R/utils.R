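DNA_BASES <- c("A", "C", "G", "T")

#' Convert integers to fixed-length DNA tags
#'
#' Encodes integers in \code{0 .. 4^len - 1} as DNA strings base-4
#' (A=0, C=1, G=2, T=3), most-significant base first.
#'
#' @param x integer (or double-valued integer) vector.
#' @param len tag length in nucleotides.
#' @return character vector of DNA strings of length \code{len}.
#' @keywords internal
int_to_dna <- function(x, len) {
  stopifnot(all(x >= 0), all(x < 4^len))
  cols <- vector("list", len)
  x <- as.double(x)
  for (j in len:1) {
    cols[[j]] <- DNA_BASES[(x %% 4) + 1]
    x <- x %/% 4
  }
  do.call(paste0, cols)
}

#' @rdname int_to_dna
#' @keywords internal
dna_to_int <- function(s) {
  m <- vapply(strsplit(s, ""), function(ch) {
    sum((match(ch, DNA_BASES) - 1) * 4^(rev(seq_along(ch)) - 1))
  }, numeric(1))
  m
}

#' Hamming distance between equal-length strings
#' @param a,b character scalars of equal nchar.
#' @return integer distance.
#' @keywords internal
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings of unequal length")
  sum(charToRaw(a) != charToRaw(b))
}

# All DNA strings at Hamming distance exactly 1 from `tag`
hamming1_neighbours <- function(tag) {
  ch <- strsplit(tag, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(DNA_BASES, ch[i])) {
      v <- ch
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Generate a random tag dictionary with a minimum pairwise Hamming distance
#'
#' Greedy rejection sampling over 4^len; used to build protein/sample tag
#' panels whose spacing supports optional 1-mismatch correction.
#'
#' @param n number of tags.
#' @param len tag length (nt).
#' @param min_hamming minimum pairwise Hamming distance to enforce.
#' @return character vector of \code{n} distinct tags.
#' @keywords internal
make_tag_set <- function(n, len = 8, min_hamming = 3) {
  if (n > 4^len) stop("make_tag_set(): more tags requested than 4^len")
  acc <- matrix(character(0), nrow = 0, ncol = len)
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n) stop("make_tag_set(): could not satisfy Hamming constraint")
    cand <- DNA_BASES[sample.int(4L, len, replace = TRUE)]
    ok <- nrow(acc) == 0L ||
      all(rowSums(acc != matrix(cand, nrow(acc), len, byrow = TRUE)) >= min_hamming)
    if (ok) acc <- rbind(acc, cand)
  }
  apply(acc, 1, paste, collapse = "")
}

# Zero-truncated Poisson draws; lambda may be a vector recycled to n.
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  out <- stats::qpois(u, lambda)
  out[out < 1L] <- 1L  # numerical guard for tiny lambda
  out
}

# Mutate characters of a character vector of equal-length strings at i.i.d.
# per-base rate; returns list(seq = mutated vector, n_errors = per-string count).
mutate_bases <- function(strings, rate) {
  if (rate <= 0 || length(strings) == 0) {
    return(list(seq = strings, n_errors = integer(length(strings))))
  }
  len <- nchar(strings[1])
  big <- paste(strings, collapse = "")
  codes <- utf8ToInt(big)
  n_tot <- length(codes)
  idx <- which(stats::runif(n_tot) < rate)
  n_err <- integer(length(strings))
  if (length(idx)) {
    base_codes <- utf8ToInt(paste(DNA_BASES, collapse = ""))
    # replace with a uniformly chosen *different* base
    cur <- codes[idx]
    repl <- vapply(cur, function(cc) sample(setdiff(base_codes, cc), 1L), integer(1))
    codes[idx] <- repl
    tab <- tabulate(((idx - 1L) %/% len) + 1L, nbins = length(strings))
    n_err <- tab
  }
  big2 <- intToUtf8(codes)
  starts <- seq(1L, n_tot, by = len)
  list(seq = substring(big2, starts, starts + len - 1L), n_errors = n_err)
}

# Draw random per-base Phred qualities (Phred+33 encoding) for n reads of
# length len, from a discrete quality law list(q = scores, p = probabilities).
random_quality_strings <- function(n, len, quality_law) {
  if (n == 0) return(character(0))
  pick <- sample.int(length(quality_law$q), n * len, replace = TRUE,
                     prob = quality_law$p)
  codes <- quality_law$q[pick] + 33L
  big <- intToUtf8(codes)
  starts <- seq(1L, n * len, by = len)
  substring(big, starts, starts + len - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
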