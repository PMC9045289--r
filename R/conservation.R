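#' Cross-strain promoter conservation
#'
#' Promoters under selective pressure tend to be conserved between close
#' strains.  The comparison here aligns, for a pair of strains, all
#' cross-strain promoter pairs globally (Needleman-Wunsch), splits the
#' scores into an ortholog group (promoters of genes that are orthologs)
#' and a non-ortholog null group, picks a score threshold from the null
#' distribution, and reports one-to-one promoter matches among ortholog
#' pairs scoring at or above the threshold.
#'
#' @name promoter_conservation
NULL

#' Alignment scoring scheme
#'
#' Linear gap penalty; the defaults (+1 match, -1 mismatch, -2 gap) are a
#' simple standard choice for short fixed-length promoter windows.
#'
#' @param match,mismatch,gap per-column scores; `match > mismatch`,
#'   `gap < 0`.
#' @return an `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(match > mismatch, gap < 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

#' Filter TSS records for the conservation analysis
#'
#' InterS TSSs enter the comparison only when their distance to the
#' associated gene start is strictly below `max_dist` (default 200 bp);
#' IntraS TSSs carry no distance filter.
#'
#' @param records classified TSS data.frame.
#' @param category `"InterS"` or `"IntraS"`.
#' @param max_dist exclusive distance bound for InterS.
#' @return the retained subset.
#' @export
filter_for_conservation <- function(records, category = c("InterS", "IntraS"),
                                    max_dist = 200) {
  category <- match.arg(category)
  out <- records[records$category == category, , drop = FALSE]
  if (category == "InterS")
    out <- out[out$upstream_of_cds < max_dist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

nw_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
}

#' Global (Needleman-Wunsch) alignment score of two sequences
#'
#' Optimal global alignment under `scoring` with a linear gap penalty.
#' An empty sequence aligns entirely to gaps, scoring
#' `gap * nchar(other)`.
#'
#' @param a,b nucleotide strings.
#' @param scoring an [alignment_scoring()].
#' @param alignment also return one optimal alignment (aligned strings)?
#' @return the score, or (with `alignment = TRUE`) a list `score`,
#'   `aligned_a`, `aligned_b`.
#' @export
nw_score <- function(a, b, scoring = alignment_scoring(), alignment = FALSE) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    score <- scoring$gap * (nchar(a) + nchar(b))
    if (!alignment) return(score)
    return(list(score = score,
                aligned_a = paste(c(strsplit(a, "")[[1]],
                                    rep("-", nchar(b))), collapse = ""),
                aligned_b = paste(c(rep("-", nchar(a)),
                                    strsplit(b, "")[[1]]), collapse = "")))
  }
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = nw_matrix(scoring),
    gapOpening = 0, gapExtension = -scoring$gap)
  if (!alignment) return(Biostrings::score(pa))
  list(score = Biostrings::score(pa),
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

# Vectorized scores of many sequences against one subject.
nw_scores_vec <- function(avec, b, scoring) {
  if (length(avec) == 0) return(numeric(0))
  empty <- nchar(avec) == 0 | nchar(b) == 0
  out <- numeric(length(avec))
  out[empty] <- scoring$gap * (nchar(avec[empty]) + nchar(b))
  if (any(!empty))
    out[!empty] <- Biostrings::score(Biostrings::pairwiseAlignment(
      avec[!empty], b, type = "global",
      substitutionMatrix = nw_matrix(scoring),
      gapOpening = 0, gapExtension = -scoring$gap))
  out
}

#' Read an ortholog pair table
#'
#' Tab-separated file with columns `gene_a`, `gene_b`, `identity`
#' (percent amino-acid identity in `[0, 100]`), e.g. exported from an
#' orthology resource.
#'
#' @param path ortholog TSV.
#' @return data.frame `gene_a`, `gene_b`, `identity`.
#' @export
read_orthologs <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "identity") %in% names(tab)))
  if (any(tab$identity < 0 | tab$identity > 100))
    stop("percent identity outside [0, 100]")
  if (anyDuplicated(tab[c("gene_a", "gene_b")]))
    stop("duplicate ortholog pairs")
  tab
}

#' Alignment score distributions of ortholog and non-ortholog promoter
#' pairs
#'
#' Aligns cross-strain promoter pairs and splits the scores into two
#' groups: pairs whose associated genes are orthologs (percent identity
#' strictly above `identity_min`) and the non-ortholog remainder, which
#' serves as the null distribution for threshold selection.  Above
#' `max_nonortholog` pairs the null group is subsampled (using the
#' current RNG state) for tractability; ortholog pairs are always
#' exhaustive.
#'
#' @param promoters_a,promoters_b promoter data.frames (from
#'   [extract_promoters()]) with `gene_id` set.
#' @param orthologs ortholog table (see [read_orthologs()]); `gene_a`
#'   refers to strain A, `gene_b` to strain B.
#' @param identity_min exclusive identity bound for calling a gene pair
#'   orthologous (default 60).
#' @param scoring an [alignment_scoring()].
#' @param max_nonortholog cap on the number of non-ortholog pairs scored.
#' @return list with data.frames `ortholog` and `nonortholog`, each with
#'   `promoter_a`, `promoter_b`, `score`.
#' @export
score_distributions <- function(promoters_a, promoters_b, orthologs,
                                identity_min = 60,
                                scoring = alignment_scoring(),
                                max_nonortholog = 5000) {
  orth <- orthologs[orthologs$identity > identity_min, , drop = FALSE]
  key <- paste(orth$gene_a, orth$gene_b, sep = "\r")
  pairs <- expand.grid(i = seq_len(nrow(promoters_a)),
                       j = seq_len(nrow(promoters_b)))
  pairs$ortholog <- paste(promoters_a$gene_id[pairs$i],
                          promoters_b$gene_id[pairs$j], sep = "\r") %in% key
  if (!any(pairs$ortholog))
    stop("no ortholog promoter pairs: threshold selection is undefined")
  non <- which(!pairs$ortholog)
  if (length(non) > max_nonortholog)
    pairs <- pairs[c(which(pairs$ortholog),
                     sort(sample(non, max_nonortholog))), , drop = FALSE]
  score_group <- function(sub) {
    if (nrow(sub) == 0)
      return(data.frame(promoter_a = character(), promoter_b = character(),
                        score = numeric()))
    sub$score <- NA_real_
    for (j in unique(sub$j)) {
      rows <- sub$j == j
      sub$score[rows] <- nw_scores_vec(promoters_a$seq[sub$i[rows]],
                                       promoters_b$seq[j], scoring)
    }
    data.frame(promoter_a = promoters_a$promoter_id[sub$i],
               promoter_b = promoters_b$promoter_id[sub$j],
               score = sub$score, stringsAsFactors = FALSE)
  }
  list(ortholog = score_group(pairs[pairs$ortholog, , drop = FALSE]),
       nonortholog = score_group(pairs[!pairs$ortholog, , drop = FALSE]))
}

#' Select an alignment score threshold from the null distribution
#'
#' The threshold is the `quantile`-th empirical percentile (linear
#' interpolation) of the non-ortholog score distribution: by default the
#' 95th percentile, i.e. at most ~5% of unrelated promoter pairs would
#' pass.  The fraction of ortholog pairs exceeding the threshold is
#' reported as a separation diagnostic.
#'
#' @param ortholog_scores,nonortholog_scores numeric score vectors.
#' @param quantile percentile of the null distribution (default 0.95).
#' @return list `threshold`, `ortholog_pass_fraction`.
#' @export
select_threshold <- function(ortholog_scores, nonortholog_scores,
                             quantile = 0.95) {
  if (length(ortholog_scores) == 0 || length(nonortholog_scores) == 0)
    stop("both score groups must be non-empty")
  thr <- unname(stats::quantile(nonortholog_scores, probs = quantile,
                                type = 7))
  list(threshold = thr,
       ortholog_pass_fraction = mean(ortholog_scores > thr))
}

#' One-to-one promoter matching above the threshold
#'
#' Candidate pairs are the ortholog-gene promoter pairs scoring at least
#' `threshold`.  Pairs are accepted greedily by decreasing score (ties:
#' lexicographic promoter ids) under the constraint that each promoter is
#' used at most once, partitioning both promoter sets into conserved and
#' non-conserved.
#'
#' @param ortholog_pairs data.frame `promoter_a`, `promoter_b`, `score`
#'   (the `ortholog` element of [score_distributions()]).
#' @param promoters_a,promoters_b the promoter data.frames.
#' @param threshold minimum score, inclusive.
#' @return list `matched` (data.frame `promoter_a`, `promoter_b`,
#'   `score`), `unmatched_a`, `unmatched_b` (promoter id vectors) and
#'   `threshold`.
#' @export
match_promoters <- function(ortholog_pairs, promoters_a, promoters_b,
                            threshold) {
  cand <- ortholog_pairs[ortholog_pairs$score >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$promoter_a, cand$promoter_b), ,
               drop = FALSE]
  used_a <- character(0)
  used_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$promoter_a[i] %in% used_a) &&
        !(cand$promoter_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$promoter_a[i])
      used_b <- c(used_b, cand$promoter_b[i])
    }
  }
  matched <- cand[keep, , drop = FALSE]
  rownames(matched) <- NULL
  list(matched = matched,
       unmatched_a = setdiff(promoters_a$promoter_id, matched$promoter_a),
       unmatched_b = setdiff(promoters_b$promoter_id, matched$promoter_b),
       threshold = threshold)
}

#' Full pairwise promoter conservation analysis
#'
#' Composition of [score_distributions()], [select_threshold()] and
#' [match_promoters()] for one strain pair.  A three-way comparison is
#' realized as the three pairwise analyses.
#'
#' @inheritParams score_distributions
#' @param quantile null-distribution percentile for the threshold.
#' @return list `threshold`, `ortholog_pass_fraction`, `matched`,
#'   `unmatched_a`, `unmatched_b`, `scores` (the two score groups).
#' @export
conserve_promoters <- function(promoters_a, promoters_b, orthologs,
                               identity_min = 60,
                               scoring = alignment_scoring(),
                               quantile = 0.95, max_nonortholog = 5000) {
  sd <- score_distributions(promoters_a, promoters_b, orthologs,
                            identity_min = identity_min, scoring = scoring,
                            max_nonortholog = max_nonortholog)
  sel <- select_threshold(sd$ortholog$score, sd$nonortholog$score,
                          quantile = quantile)
  mt <- match_promoters(sd$ortholog, promoters_a, promoters_b,
                        sel$threshold)
  c(list(threshold = sel$threshold,
         ortholog_pass_fraction = sel$ortholog_pass_fraction),
    mt[c("matched", "unmatched_a", "unmatched_b")],
    list(scores = sd))
}
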