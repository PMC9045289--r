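#' Genomic data model and format I/O
#'
#' The package works on four light-weight containers, all built on plain
#' data frames so they print, subset and serialize transparently:
#'
#' * `genome`: named list of uppercase contig sequences plus a per-contig
#'   circularity flag.  Coordinates everywhere in the package are 1-based
#'   inclusive (GFF convention); BED/bedGraph are converted at the boundary.
#' * gene annotation: one row per gene with `gene_id`, `contig`, `start`,
#'   `end`, `strand` and `cds_start` (the translated start: `start` on the
#'   plus strand, `end` on the minus strand).
#' * read-start track: sparse per-(contig, strand, position) counts of read
#'   5' ends, with the library size (total mapped read starts) attached.
#' * TSS table: called TSSs with gene association, category and raw /
#'   normalized read-per-million (RPM) strengths.
#'
#' @name genome_io
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' @param contigs named character vector of nucleotide sequences
#'   (uppercased on construction; alphabet restricted to A, C, G, T, N).
#' @param circular logical, recycled over contigs: does the contig wrap?
#'   Bacterial chromosomes and plasmids usually do, but the flag only
#'   affects promoter extraction at contig edges, so the conservative
#'   default is `FALSE`.
#' @return an object of class `genome`.
#' @export
genome <- function(contigs, circular = FALSE) {
  if (length(contigs) == 0L)
    stop("genome must contain at least one contig")
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L))
    stop("empty contig sequence")
  bad <- vapply(contigs, function(s)
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% VALID_BASES), logical(1))
  if (any(bad))
    stop("non-nucleotide characters in contig(s): ",
         paste(names(contigs)[bad], collapse = ", "))
  circular <- rep_len(as.logical(circular), length(contigs))
  names(circular) <- names(contigs)
  structure(list(contigs = contigs, circular = circular), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x$contigs), "contig(s):\n")
  for (nm in names(x$contigs))
    cat(sprintf("  %s  %d bp  %s\n", nm, nchar(x$contigs[[nm]]),
                if (x$circular[[nm]]) "circular" else "linear"))
  invisible(x)
}

contig_length <- function(genome, contig) nchar(genome$contigs[[contig]])

#' Read a genome from a FASTA file
#'
#' @param path FASTA file, one record per contig.
#' @param circular logical circularity flag(s) passed to [genome()].
#' @return a `genome` object.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  contigs <- stats::setNames(as.character(seqs), ids)
  genome(contigs, circular = circular)
}

#' Write a genome to a FASTA file
#' @param genome a `genome` object.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), filepath = path)
  invisible(path)
}

#' Reverse-complement a nucleotide string (IUPAC-aware)
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Read a gene annotation from GFF3
#'
#' One row per feature of the selected type.  `cds_start` is the strand-aware
#' translated start: the feature `start` on plus-strand genes and the feature
#' `end` on minus-strand genes.  When both `gene` and `CDS` features exist,
#' the convention in this package is that gene bounds define intragenic /
#' intergenic localization and the CDS start anchors 5' UTR lengths; by
#' default `gene` features are read.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to select (default `"gene"`).
#' @param id_attribute attribute used as gene id (default `"ID"`).
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `cds_start`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene",
                                 id_attribute = "ID") {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  ids <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  if (is.null(ids) || anyNA(ids))
    stop("missing ", id_attribute, " attribute on ", feature_type, " features")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("feature(s) without a defined strand: ",
         paste(ids[!strand %in% c("+", "-")], collapse = ", "))
  ann <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

#' Build an annotation table from vectors
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param gene_id,contig,start,end,strand per-gene vectors (1-based
#'   inclusive coordinates).
#' @return annotation data.frame (see [read_gene_annotation()]).
#' @export
gene_annotation <- function(gene_id, contig, start, end, strand) {
  validate_annotation(data.frame(
    gene_id = as.character(gene_id), contig = as.character(contig),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), stringsAsFactors = FALSE))
}

validate_annotation <- function(ann) {
  if (any(ann$start > ann$end))
    stop("gene(s) with start > end: ",
         paste(ann$gene_id[ann$start > ann$end], collapse = ", "))
  if (any(!ann$strand %in% c("+", "-")))
    stop("invalid strand value(s)")
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene ids")
  ann$cds_start <- ifelse(ann$strand == "+", ann$start, ann$end)
  rownames(ann) <- NULL
  ann
}

#' Write an annotation table as GFF3
#' @param ann annotation data.frame.
#' @param path output path.
#' @param feature_type GFF3 feature type to emit.
#' @export
write_gene_annotation <- function(ann, path, feature_type = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tcapptss\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$contig, feature_type, ann$start, ann$end,
                     ann$strand, ann$gene_id), con)
  invisible(path)
}

## ---- read-start tracks ------------------------------------------------

new_track <- function(df, library_size, scaled = FALSE) {
  df <- df[order(df$contig, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, library_size = library_size, scaled = scaled,
            class = c("read_start_track", "data.frame"))
}

#' Build a read-start track from per-position counts
#'
#' @param contig,strand,pos,count parallel vectors; `pos` is 1-based.
#' @param library_size total mapped read starts; defaults to `sum(count)`
#'   (the raw-track invariant).
#' @return a `read_start_track` (data.frame with attributes `library_size`
#'   and `scaled`).
#' @export
read_start_track_from_counts <- function(contig, strand, pos, count,
                                         library_size = sum(count)) {
  if (any(count < 0)) stop("negative read-start counts")
  df <- data.frame(contig = as.character(contig), strand = as.character(strand),
                   pos = as.integer(pos), count = as.numeric(count),
                   stringsAsFactors = FALSE)
  df <- df[df$count > 0, , drop = FALSE]
  if (anyDuplicated(df[c("contig", "strand", "pos")]))
    stop("duplicate (contig, strand, position) entries in track")
  new_track(df, library_size = library_size)
}

#' Library size of a read-start track
#' @param track a `read_start_track`.
#' @export
library_size <- function(track) attr(track, "library_size")

read_bedgraph_positions <- function(path, strand) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), count = numeric()))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), count = numeric()))
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0)) stop("negative value in bedGraph ", path)
  # expand intervals to single 1-based positions
  w <- BiocGenerics::width(gr)
  df <- data.frame(
    contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
    strand = strand,
    pos = unlist(lapply(seq_along(gr), function(i)
      seq.int(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i]))),
    count = rep(as.numeric(score), w),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[c("contig", "pos")]))
    stop("overlapping intervals define a position twice in ", path)
  df[df$count > 0, , drop = FALSE]
}

#' Read a strand-specific read-start track from two bedGraph files
#'
#' bedGraph intervals are 0-based half-open and are converted to internal
#' 1-based positions; an interval of width w assigns its value to each of
#' the w positions.  The library size is the sum of all counts.
#'
#' @param path_fwd bedGraph of plus-strand read-start counts.
#' @param path_rev bedGraph of minus-strand read-start counts.
#' @return a `read_start_track`.
#' @export
read_start_track <- function(path_fwd, path_rev) {
  df <- rbind(read_bedgraph_positions(path_fwd, "+"),
              read_bedgraph_positions(path_rev, "-"))
  new_track(df, library_size = sum(df$count))
}

#' Write a read-start track as a pair of bedGraph files
#' @param track a `read_start_track` with integer counts.
#' @param path_fwd,path_rev output paths for the two strands.
#' @export
write_start_track <- function(track, path_fwd, path_rev) {
  for (s in c("+", "-")) {
    path <- if (s == "+") path_fwd else path_rev
    sub <- track[track$strand == s, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s", sub$contig, sub$pos - 1L, sub$pos,
                     format(sub$count, scientific = FALSE, trim = TRUE))
    writeLines(lines, path)
  }
  invisible(c(path_fwd, path_rev))
}

## ---- TSS tables -------------------------------------------------------

TSS_COLUMNS <- c("tss_id", "contig", "pos", "strand", "rpm", "normalized_rpm",
                 "gene_id", "localization", "orientation", "distance",
                 "upstream_of_cds", "category")

sort_tss <- function(records) {
  records <- records[order(records$contig, records$pos, records$strand), ,
                     drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Write a TSS table as TSV and BED6
#'
#' Records are sorted deterministically by contig, position, strand and
#' written twice: a TSV carrying every field, and a BED6 file whose score
#' column is the rounded normalized RPM (BED coordinates are 0-based
#' half-open, so a TSS at 1-based position p spans `[p-1, p)`).
#'
#' @param records TSS data.frame (as returned by [call_tss()]).
#' @param prefix output prefix; `<prefix>.tsv` and `<prefix>.bed` are
#'   written.
#' @return invisibly, the two paths.
#' @export
write_tss_table <- function(records, prefix) {
  records <- sort_tss(as.data.frame(records))
  if (nrow(records) > 0 && !"tss_id" %in% names(records))
    records$tss_id <- sprintf("TSS_%d", seq_len(nrow(records)))
  cols <- intersect(TSS_COLUMNS, names(records))
  if (nrow(records) == 0) cols <- TSS_COLUMNS
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  empty <- records[0, ]
  tab <- if (nrow(records) == 0)
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  else records[cols]
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(records) == 0) {
    writeLines(character(0), bed)
  } else {
    score <- round(records$normalized_rpm)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", records$contig,
                       records$pos - 1L, records$pos, records$tss_id,
                       as.integer(score), records$strand), bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' Read back a TSS table written by [write_tss_table()]
#' @param path the `.tsv` file.
#' @return TSS data.frame.
#' @export
read_tss_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(contig = "character", gene_id = "character"))
  sort_tss(tab)
}

#' Write promoter sequences as FASTA (e.g. for MEME motif discovery)
#'
#' @param promoters promoter data.frame from [extract_promoters()].
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$seq)
  names(seqs) <- promoters$promoter_id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
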