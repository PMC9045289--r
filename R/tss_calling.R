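#' TSS candidate calling: RPM scaling, replicate intersection,
#' gene association and 4-way classification
#'
#' Candidate TSSs are genomic positions carrying read 5' ends in every
#' replicate.  Each candidate is associated with a single gene and
#' classified into one of four categories crossing localization
#' (intergenic / intragenic) with orientation (sense / antisense):
#' `InterS`, `InterA`, `IntraS`, `IntraA`.  An `InterS` call additionally
#' requires the associated gene to lie downstream of the TSS on the shared
#' strand (positive `upstream_of_cds`); an intergenic sense TSS past the
#' gene's 3' end is reported as `InterA`.
#'
#' @name tss_calling
NULL

#' Scale a read-start track to reads per million (RPM)
#'
#' @param track a raw `read_start_track`.
#' @return the track with counts replaced by `count * 1e6 / library_size`
#'   (summing to 1e6) and the `scaled` attribute set.
#' @export
to_rpm <- function(track) {
  ls <- library_size(track)
  if (is.null(ls) || ls <= 0)
    stop("cannot scale to RPM: library size is zero")
  df <- as.data.frame(track)
  df$count <- df$count * 1e6 / ls
  new_track(df, library_size = ls, scaled = TRUE)
}

#' Intersect replicate tracks into TSS candidates
#'
#' Keeps exactly the (contig, strand, position) triples carrying a nonzero
#' value in every replicate; positions not detected in both duplicates are
#' discarded.  The candidate RPM is the arithmetic mean of the replicate
#' RPMs.  Passing a single track (`rep2 = NULL`) returns its positions
#' unchanged, supporting single-replicate designs.
#'
#' @param rep1,rep2 RPM-scaled `read_start_track`s (see [to_rpm()]).
#' @return data.frame of candidates: `contig`, `strand`, `pos`, `rpm`.
#' @export
intersect_replicates <- function(rep1, rep2 = NULL) {
  cand <- function(df, value_col = "count") {
    data.frame(contig = df$contig, strand = df$strand, pos = df$pos,
               rpm = df[[value_col]], stringsAsFactors = FALSE)
  }
  if (is.null(rep2)) return(cand(as.data.frame(rep1)))
  a <- as.data.frame(rep1); b <- as.data.frame(rep2)
  m <- merge(a, b, by = c("contig", "strand", "pos"), suffixes = c("_1", "_2"))
  out <- data.frame(contig = m$contig, strand = m$strand, pos = m$pos,
                    rpm = (m$count_1 + m$count_2) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- gene association -------------------------------------------------

# Resolve a set of tied gene hits per TSS: prefer the same-strand gene with
# the TSS upstream of its cds_start, then the smaller gene start.
resolve_hits <- function(hits) {
  pref <- hits$sense & hits$upstream_of_cds > 0
  ord <- order(hits$tss_idx, !pref, hits$gene_start)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$tss_idx), , drop = FALSE]
}

#' Associate TSS candidates with their closest genes
#'
#' A candidate inside a gene (bounds inclusive) is intragenic with distance
#' 0; otherwise it is intergenic and associated with the gene minimizing
#' the distance to the nearest gene boundary, `min(|pos - start|,
#' |pos - end|)`.  Ties (equidistant genes, or containment in overlapping
#' genes) are broken by preferring the same-strand gene whose translated
#' start lies downstream of the TSS, then the gene with the smaller start
#' coordinate, which is deterministic and favors canonical promoter calls.
#' Candidates on contigs without any gene are reported as orphans
#' (`gene_id` NA).
#'
#' `upstream_of_cds` is the signed distance from the TSS to the gene's
#' translated start measured along the gene strand: `cds_start - pos` on
#' plus-strand genes, `pos - cds_start` on minus-strand genes; positive
#' values mean the TSS lies upstream of the coding start.
#'
#' @param cands candidate data.frame (from [intersect_replicates()]).
#' @param ann annotation data.frame (see [read_gene_annotation()]).
#' @return `cands` with columns `gene_id`, `localization`, `orientation`,
#'   `distance`, `upstream_of_cds` appended.
#' @export
associate_genes <- function(cands, ann) {
  n <- nrow(cands)
  out <- cands
  out$gene_id <- rep(NA_character_, n)
  out$localization <- rep(NA_character_, n)
  out$orientation <- rep(NA_character_, n)
  out$distance <- rep(NA_real_, n)
  out$upstream_of_cds <- rep(NA_real_, n)
  if (n == 0L) return(out)

  lev <- union(unique(cands$contig), unique(ann$contig))
  tss_gr <- GenomicRanges::GRanges(
    factor(cands$contig, levels = lev),
    IRanges::IRanges(cands$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    factor(ann$contig, levels = lev),
    IRanges::IRanges(ann$start, ann$end))

  hit_frame <- function(tss_idx, gene_idx) {
    g <- ann[gene_idx, , drop = FALSE]
    pos <- cands$pos[tss_idx]
    upstream <- ifelse(g$strand == "+", g$cds_start - pos, pos - g$cds_start)
    data.frame(tss_idx = tss_idx, gene_idx = gene_idx,
               gene_start = g$start,
               sense = g$strand == cands$strand[tss_idx],
               upstream_of_cds = upstream,
               bdist = pmin(abs(pos - g$start), abs(pos - g$end)))
  }

  fill <- function(chosen, localization) {
    i <- chosen$tss_idx
    g <- ann[chosen$gene_idx, , drop = FALSE]
    out$gene_id[i] <<- g$gene_id
    out$localization[i] <<- localization
    out$orientation[i] <<- ifelse(chosen$sense, "sense", "antisense")
    out$distance[i] <<- if (localization == "intragenic") 0 else chosen$bdist
    out$upstream_of_cds[i] <<- chosen$upstream_of_cds
  }

  ov <- GenomicRanges::findOverlaps(tss_gr, gene_gr, ignore.strand = TRUE)
  if (length(ov) > 0) {
    hits <- hit_frame(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    fill(resolve_hits(hits), "intragenic")
  }

  # Intergenic candidates: find every gene whose nearest boundary attains
  # the minimal distance (binary search over sorted gene boundaries), so
  # the tie rule sees all equidistant genes.
  inter <- setdiff(seq_len(n), unique(S4Vectors::queryHits(ov)))
  for (ctg in unique(cands$contig[inter])) {
    idx <- inter[cands$contig[inter] == ctg]
    gsel <- which(ann$contig == ctg)
    if (length(gsel) == 0) next  # orphan contig
    b <- c(ann$start[gsel], ann$end[gsel])
    gi <- rep(gsel, 2)
    ord <- order(b)
    b <- b[ord]
    gi <- gi[ord]
    pos <- cands$pos[idx]
    k <- findInterval(pos, b)
    dl <- ifelse(k >= 1, pos - b[pmax(k, 1L)], Inf)
    dr <- ifelse(k < length(b), b[pmin(k + 1L, length(b))] - pos, Inf)
    d <- pmin(dl, dr)
    boundary_hits <- function(v) {
      lo <- findInterval(v - 1L, b) + 1L
      hi <- findInterval(v, b)
      runs <- pmax(hi - lo + 1L, 0L)
      data.frame(
        tss_idx = rep(idx, runs),
        gene_idx = gi[unlist(Map(function(l, h)
          if (h >= l) seq.int(l, h) else integer(0), lo, hi))])
    }
    hits <- rbind(boundary_hits(pos - d), boundary_hits(pos + d))
    hits <- hits[!duplicated(hits), , drop = FALSE]
    fill(resolve_hits(hit_frame(hits$tss_idx, hits$gene_idx)), "intergenic")
  }
  out
}

#' Classify associated TSS candidates into the four categories
#'
#' * `IntraS` / `IntraA`: intragenic, same / opposite strand as the gene.
#' * `InterS`: intergenic, same strand, and the TSS lies upstream of the
#'   gene's translated start (`upstream_of_cds > 0`).
#' * `InterA`: every other intergenic candidate (opposite strand, or a
#'   same-strand gene lying upstream of the TSS).
#' * `unassigned`: orphan candidates on contigs without genes.
#'
#' @param cands data.frame from [associate_genes()].
#' @return `cands` with a `category` column appended.
#' @export
classify_tss <- function(cands) {
  loc <- cands$localization
  sense <- cands$orientation == "sense"
  category <- rep("unassigned", nrow(cands))
  intra <- !is.na(loc) & loc == "intragenic"
  inter <- !is.na(loc) & loc == "intergenic"
  category[intra & sense] <- "IntraS"
  category[intra & !sense] <- "IntraA"
  category[inter & sense & cands$upstream_of_cds > 0] <- "InterS"
  category[inter & (!sense | cands$upstream_of_cds <= 0)] <- "InterA"
  cands$category <- category
  cands
}
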