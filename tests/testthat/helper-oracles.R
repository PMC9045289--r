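# Independent reference implementations used to cross-check the package.
# These are deliberately naive (quadratic scans, exponential recursion,
# regular expressions) and share no code with the implementation.

# Greedy sliding-window peak picking by repeated full scans: at each step
# pick the remaining candidate with the highest value (ties: smallest
# position), then remove every remaining candidate within < window bp.
oracle_cluster <- function(pos, value, window) {
  accepted <- integer(0)
  remaining <- seq_along(pos)
  while (length(remaining) > 0) {
    v <- value[remaining]
    p <- pos[remaining]
    best <- remaining[order(-v, p)[1]]
    accepted <- c(accepted, best)
    remaining <- remaining[abs(pos[remaining] - pos[best]) >= window]
  }
  sort(pos[accepted])
}

# Plain recursive global alignment (linear gap penalty).
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0) return(gap * nchar(b))
  if (nchar(b) == 0) return(gap * nchar(a))
  ha <- substring(a, 1, 1); ta <- substring(a, 2)
  hb <- substring(b, 1, 1); tb <- substring(b, 2)
  max(oracle_nw(ta, tb, match, mismatch, gap) +
        (if (ha == hb) match else mismatch),
      oracle_nw(ta, b, match, mismatch, gap) + gap,
      oracle_nw(a, tb, match, mismatch, gap) + gap)
}

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pattern) {
  paste(IUPAC_CLASS[strsplit(pattern, "", fixed = TRUE)[[1]]], collapse = "")
}

# Non-overlapping leftmost regex matching of an exact (no-indel) IUPAC
# pattern on one strand; gregexpr's successive-match semantics are exactly
# greedy left-to-right non-overlap for fixed-length patterns.
oracle_iupac_exact <- function(sequence, pattern) {
  m <- gregexpr(iupac_to_regex(pattern), sequence)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Both-strand oracle in forward coordinates: the reverse strand is matched
# on the reverse complement and mapped back.
oracle_iupac_both <- function(sequence, pattern) {
  revcomp_chr <- function(s) {
    chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }
  fwd <- oracle_iupac_exact(sequence, pattern)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- oracle_iupac_exact(revcomp_chr(sequence), pattern)
  len <- nchar(sequence)
  rev <- data.frame(start = len - rc$end + 1L, end = len - rc$start + 1L,
                    strand = rep("-", nrow(rc)))
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random candidate table on one contig/strand for clustering tests.
random_candidates <- function(n_max = 200, span = 500) {
  n <- sample.int(n_max, 1)
  pos <- sample.int(span, n)
  data.frame(contig = "c", strand = "+", pos = pos,
             rpm = round(stats::runif(n, 0.1, 100), 3))
}

tss_key <- function(df) paste(df$contig, df$pos, df$strand)
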