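#' Per-TSS descriptive layers: 5' UTRs, promoters, initiating bases,
#' summaries and degenerate motif scanning
#'
#' @name transcript_features
NULL

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' 5' UTR lengths and leaderless calls for InterS TSSs
#'
#' The 5' UTR length of an InterS TSS is its distance to the associated
#' gene's translated start along the gene strand (`upstream_of_cds`).
#' Transcripts with a UTR strictly shorter than `leaderless_max` (default
#' 6 bp) are called leaderless: too short to carry a ribosome binding
#' site.
#'
#' @param records TSS data.frame; every record must be category `InterS`.
#' @param leaderless_max exclusive leaderless bound in bp.
#' @return `records` with `utr_length` and `leaderless` columns appended.
#' @export
utr_length <- function(records, leaderless_max = 6) {
  if (nrow(records) > 0 && any(records$category != "InterS"))
    stop("5' UTR lengths are defined for InterS TSSs only")
  records$utr_length <- records$upstream_of_cds
  records$leaderless <- records$utr_length < leaderless_max
  records
}

wrap_positions <- function(pos, len) ((pos - 1L) %% len) + 1L

#' Extract promoter windows upstream of TSSs
#'
#' The promoter of a TSS is the `promoter_len` nucleotides immediately
#' upstream, excluding the TSS base itself, reported 5'->3' on the TSS
#' strand: plus-strand positions `[pos - promoter_len, pos - 1]`;
#' minus-strand positions `[pos + 1, pos + promoter_len]`
#' reverse-complemented.  On circular contigs the window wraps around the
#' origin; on linear contigs it is clipped at the edge and flagged
#' `truncated`.
#'
#' @param records TSS data.frame.
#' @param genome a `genome` object.
#' @param promoter_len window length in bp.
#' @return data.frame with `promoter_id`, `tss_id`, `contig`, `pos`,
#'   `strand`, `gene_id`, `seq`, `truncated`.
#' @export
extract_promoters <- function(records, genome, promoter_len = 50) {
  n <- nrow(records)
  seqs <- character(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    contig <- records$contig[i]
    len <- contig_length(genome, contig)
    if (is.null(genome$contigs[[contig]]))
      stop("TSS on unknown contig: ", contig)
    pos <- records$pos[i]
    span <- if (records$strand[i] == "+")
      seq.int(pos - promoter_len, pos - 1L)
    else
      seq.int(pos + 1L, pos + promoter_len)
    if (genome$circular[[contig]]) {
      span <- wrap_positions(span, len)
    } else {
      inb <- span >= 1L & span <= len
      truncated[i] <- !all(inb)
      span <- span[inb]
    }
    chars <- substring(genome$contigs[[contig]], span, span)
    s <- paste(chars, collapse = "")
    seqs[i] <- if (records$strand[i] == "+") s else revcomp(s)
  }
  ids <- if ("tss_id" %in% names(records)) records$tss_id
         else sprintf("TSS_%d", seq_len(n))
  data.frame(promoter_id = ids, tss_id = ids,
             contig = records$contig, pos = records$pos,
             strand = records$strand,
             gene_id = if ("gene_id" %in% names(records)) records$gene_id
                       else NA_character_,
             seq = seqs, truncated = truncated, stringsAsFactors = FALSE)
}

#' Initiating nucleotide composition of a TSS set
#'
#' Reads the genomic base at each TSS position on the TSS strand
#' (complemented for minus-strand TSSs) and tabulates it.  Bacterial
#' transcription initiates overwhelmingly at purines, so the purine
#' fraction `(A + G) / total` is a quick sanity check of a TSS set.
#'
#' @param records TSS data.frame.
#' @param genome a `genome` object.
#' @return list with `counts` (named A/C/G/T/N vector), `total` and
#'   `purine_fraction` (NA for an empty input).
#' @export
initiating_base_stats <- function(records, genome) {
  if (nrow(records) == 0)
    return(list(counts = stats::setNames(integer(5), VALID_BASES),
                total = 0L, purine_fraction = NA_real_))
  base <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    b <- substring(genome$contigs[[records$contig[i]]],
                   records$pos[i], records$pos[i])
    base[i] <- if (records$strand[i] == "+") b else complement_base(b)
  }
  counts <- stats::setNames(integer(5), VALID_BASES)
  tab <- table(base)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, total = nrow(records),
       purine_fraction = (counts[["A"]] + counts[["G"]]) / nrow(records))
}

#' Summary tables for a classified TSS set
#'
#' @param records TSS data.frame (classified).
#' @param ann gene annotation data.frame.
#' @return list with:
#'   * `categories`: per-category TSS counts and the fraction of total
#'     read mass (normalized RPM) each category carries;
#'   * `inters_per_gene`: histogram of InterS TSS counts per gene (genes
#'     with at least one);
#'   * `genes_with_inters`: count and fraction of annotated genes with at
#'     least one InterS TSS.
#' @export
summarize_tss <- function(records, ann) {
  cats <- c("InterS", "InterA", "IntraS", "IntraA", "unassigned")
  counts <- stats::setNames(integer(length(cats)), cats)
  mass <- stats::setNames(numeric(length(cats)), cats)
  if (nrow(records) > 0) {
    tab <- table(factor(records$category, levels = cats))
    counts[] <- as.integer(tab)
    value <- if ("normalized_rpm" %in% names(records))
      records$normalized_rpm else records$rpm
    m <- tapply(value, factor(records$category, levels = cats), sum,
                default = 0)
    mass[] <- if (sum(m) > 0) m / sum(m) else 0
  }
  categories <- data.frame(category = cats, n = as.integer(counts),
                           read_mass_fraction = as.numeric(mass))
  inters <- records[nrow(records) > 0 & records$category == "InterS", ,
                    drop = FALSE]
  per_gene <- if (nrow(inters) > 0) table(inters$gene_id) else table(character())
  hist <- if (length(per_gene) > 0)
    as.data.frame(table(n_tss = as.integer(per_gene)),
                  stringsAsFactors = FALSE)
  else data.frame(n_tss = character(), Freq = integer())
  names(hist) <- c("n_tss", "n_genes")
  n_genes_inters <- length(per_gene)
  list(categories = categories,
       inters_per_gene = hist,
       genes_with_inters = data.frame(
         n = n_genes_inters,
         fraction = if (nrow(ann) > 0) n_genes_inters / nrow(ann) else NA_real_))
}

## ---- IUPAC motif scanning --------------------------------------------

#' Read a motif list
#'
#' Tab-separated file with columns `name`, `iupac` and optionally
#' `max_indels` (default 1), e.g. the sigma-factor and sporulation
#' regulator binding motifs curated from the literature.
#'
#' @param path motif TSV.
#' @return data.frame `name`, `iupac`, `max_indels`.
#' @export
read_motifs <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "iupac") %in% names(tab)))
  if (!"max_indels" %in% names(tab)) tab$max_indels <- 1L
  tab$iupac <- toupper(tab$iupac)
  for (p in tab$iupac) check_iupac(p)
  tab
}

check_iupac <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop("empty IUPAC pattern")
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ", "))
  invisible(chars)
}

# Enumerate pattern variants reachable with <= max_indels single-base
# edits: deletion of any pattern position, or insertion of an unmatched
# subject base (N) strictly inside the pattern.  Returns a named integer
# vector: variant string -> minimal number of indels.
indel_variants <- function(pattern, max_indels) {
  vars <- stats::setNames(0L, pattern)
  frontier <- pattern
  for (k in seq_len(max_indels)) {
    nxt <- character(0)
    for (v in frontier) {
      chars <- strsplit(v, "", fixed = TRUE)[[1]]
      m <- length(chars)
      if (m >= 2)
        nxt <- c(nxt, vapply(seq_len(m), function(i)
          paste(chars[-i], collapse = ""), character(1)))
      if (m >= 2)
        nxt <- c(nxt, vapply(seq_len(m - 1), function(i)
          paste(c(chars[seq_len(i)], "N", chars[seq.int(i + 1, m)]),
                collapse = ""), character(1)))
    }
    nxt <- setdiff(unique(nxt), names(vars))
    if (length(nxt) == 0) break
    vars <- c(vars, stats::setNames(rep(k, length(nxt)), nxt))
    frontier <- nxt
  }
  vars
}

scan_one_strand <- function(subject, pattern, max_indels) {
  vars <- indel_variants(pattern, max_indels)
  res <- list()
  for (v in names(vars)) {
    m <- Biostrings::matchPattern(v, subject, fixed = FALSE)
    if (length(m) > 0)
      res[[length(res) + 1]] <- data.frame(
        start = BiocGenerics::start(m), end = BiocGenerics::end(m),
        n_indels = vars[[v]])
  }
  if (length(res) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_indels = integer()))
  hits <- do.call(rbind, res)
  # a span reachable with several variants keeps its minimal edit count
  hits <- hits[order(hits$start, hits$n_indels, hits$end), , drop = FALSE]
  hits[!duplicated(hits[c("start", "end")]), , drop = FALSE]
}

greedy_nonoverlap <- function(hits) {
  hits <- hits[order(hits$start, hits$n_indels, hits$end), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits[keep, , drop = FALSE]
}

#' Scan a sequence for a degenerate IUPAC motif allowing indels
#'
#' A match aligns the pattern to a subsequence such that every aligned
#' base is compatible with the pattern's IUPAC code (degeneracy is free),
#' with at most `max_indels` insertions plus deletions and no mismatches
#' beyond degeneracy.  Overlap of successive matches on the same strand
#' is prevented greedily left to right (exact matches win ties at the
#' same start).  With `both_strands` the reverse strand is scanned with
#' the reverse-complemented pattern, independently, and reported in
#' forward coordinates.
#'
#' Each strand is scanned 5' to 3' in its own reading direction (the
#' reverse strand is scanned on the reverse complement of the subject),
#' and `match` reports the matched span as read on that strand;
#' `start`/`end` are always forward-strand coordinates.
#'
#' @param sequence subject nucleotide string.
#' @param pattern IUPAC pattern string.
#' @param max_indels maximum insertions + deletions (default 1).
#' @param both_strands scan the reverse strand too?
#' @return data.frame `start`, `end`, `strand`, `match` (the matched
#'   span, 5'->3' on the match strand), `n_indels`.
#' @export
iupac_scan <- function(sequence, pattern, max_indels = 1,
                       both_strands = TRUE) {
  check_iupac(toupper(pattern))
  pattern <- toupper(pattern)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- lapply(strands, function(s) {
    subj <- if (s == "+") sequence else revcomp(sequence)
    hits <- greedy_nonoverlap(
      scan_one_strand(Biostrings::DNAString(subj), pattern, max_indels))
    if (nrow(hits) == 0)
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), match = character(),
                        n_indels = integer()))
    matched <- substring(subj, hits$start, hits$end)
    if (s == "-") {
      fstart <- len - hits$end + 1L
      fend <- len - hits$start + 1L
      hits$start <- fstart
      hits$end <- fend
    }
    data.frame(start = hits$start, end = hits$end, strand = s,
               match = matched, n_indels = hits$n_indels,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a promoter set for a list of motifs
#'
#' @param promoters promoter data.frame from [extract_promoters()].
#' @param motifs motif data.frame from [read_motifs()].
#' @param both_strands scan both strands of each promoter?
#' @return data.frame with one row per match: `promoter_id`, `motif`,
#'   `start`, `end`, `strand`, `match`, `n_indels`; plus a per-motif
#'   summary in attribute `motif_summary` (number of promoters with at
#'   least one match).
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  rows <- list()
  for (j in seq_len(nrow(motifs))) {
    for (i in seq_len(nrow(promoters))) {
      hits <- iupac_scan(promoters$seq[i], motifs$iupac[j],
                         max_indels = motifs$max_indels[j],
                         both_strands = both_strands)
      if (nrow(hits) > 0)
        rows[[length(rows) + 1]] <- cbind(
          promoter_id = promoters$promoter_id[i], motif = motifs$name[j],
          hits, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(promoter_id = character(), motif = character(),
                         start = integer(), end = integer(),
                         strand = character(), match = character(),
                         n_indels = integer())
  rownames(res) <- NULL
  summary <- data.frame(
    motif = motifs$name,
    n_promoters = vapply(motifs$name, function(m)
      length(unique(res$promoter_id[res$motif == m])), integer(1)),
    row.names = NULL)
  attr(res, "motif_summary") <- summary
  res
}
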