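#' Expression normalization, sliding-window clustering and thresholding
#'
#' 5'-end sequencing read-start tracks are strongly biased toward highly
#' expressed genes: abundant transcripts scatter read starts along their
#' whole gene body (nonspecific initiation and co-purified processed RNAs),
#' so a fixed RPM cutoff both floods high-expression genes with spurious
#' calls and misses genuine TSSs on moderately expressed genes.  The
#' normalization implemented here divides each candidate's RPM by the
#' RNA-seq expression (TPM) of its associated gene and rescales the data
#' set back to a total of one million, after which a single fixed cutoff
#' (10, or 25 for high confidence) applies uniformly across expression
#' levels.
#'
#' @name normalization
NULL

#' Pipeline configuration
#'
#' Houses the tunable constants of the pipeline with their standard
#' defaults: 5-bp clustering windows, a normalized-RPM cutoff of 25 (10
#' for the permissive set), 50-bp promoter windows, a leaderless bound of
#' 6 bp (exclusive), and a 200-bp TSS-to-start distance filter for the
#' conservation analysis.
#'
#' @param window clustering window in bp; two retained TSSs on the same
#'   contig and strand are never closer than this.
#' @param cutoff minimum (normalized) RPM for a reported TSS, inclusive.
#' @param promoter_len promoter window length in bp upstream of the TSS.
#' @param leaderless_max transcripts with a 5' UTR strictly shorter than
#'   this are called leaderless.
#' @param conservation_max_dist InterS TSSs enter the conservation
#'   analysis only if their 5' UTR is strictly shorter than this.
#' @param tpm_floor pseudo-TPM used for genes with zero (or missing)
#'   RNA-seq expression, so that a TSS on an unexpressed gene is kept and
#'   flagged by its large normalized strength rather than dropped.
#' @param seed integer seed recorded in run manifests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window = 5, cutoff = 25, promoter_len = 50,
                            leaderless_max = 6, conservation_max_dist = 200,
                            tpm_floor = 1.0, seed = 1L) {
  stopifnot(window >= 1, cutoff > 0, promoter_len >= 1, tpm_floor > 0)
  structure(list(window = window, cutoff = cutoff,
                 promoter_len = promoter_len,
                 leaderless_max = leaderless_max,
                 conservation_max_dist = conservation_max_dist,
                 tpm_floor = tpm_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or plain `key = value` lines; keys mirror the arguments of
#' [pipeline_config()], and unset keys keep their defaults.
#'
#' @param path configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    stats::setNames(lapply(kv, function(x) as.numeric(trimws(x[2]))),
                    vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Compute TPM from raw per-gene counts
#'
#' `tpm_g = (count_g / length_g) * 1e6 / sum_h(count_h / length_h)`.  TPMs
#' sum to one million whenever any gene has a nonzero count; an all-zero
#' count vector yields all-zero TPMs.
#'
#' @param counts data.frame with columns `gene_id`, `count`, `length`.
#' @return the input with a `tpm` column appended.
#' @export
compute_tpm <- function(counts) {
  stopifnot(all(c("gene_id", "count", "length") %in% names(counts)))
  if (any(counts$length <= 0)) stop("non-positive gene length")
  if (any(counts$count < 0)) stop("negative count")
  rate <- counts$count / counts$length
  total <- sum(rate)
  counts$tpm <- if (total > 0) rate * 1e6 / total else rep(0, nrow(counts))
  counts
}

#' Average TPM across RNA-seq replicates
#'
#' @param ... expression tables (data.frames with `gene_id` and `tpm`); a
#'   single table passes through, supporting single-replicate designs.
#' @return data.frame `gene_id`, `tpm` with the per-gene mean TPM.
#' @export
average_tpm <- function(...) {
  tabs <- list(...)
  ids <- tabs[[1]]$gene_id
  tpm <- rowMeans(vapply(tabs, function(t) t$tpm[match(ids, t$gene_id)],
                         numeric(length(ids))))
  data.frame(gene_id = ids, tpm = tpm, stringsAsFactors = FALSE)
}

#' Normalize candidate TSS strengths by associated-gene expression
#'
#' Each candidate's RPM is divided by the TPM of its associated gene
#' (orphans and genes below `tpm_floor` use `tpm_floor`), and the
#' resulting values are rescaled so that the data set sums to one million
#' (`normalized_rpm`).  Within one gene the divisor is constant, so
#' normalization preserves the rank order of that gene's candidates.
#'
#' @param cands associated candidates (see [associate_genes()]).
#' @param expression data.frame with `gene_id` and `tpm` (mean across
#'   RNA-seq replicates).
#' @param config a [pipeline_config()].
#' @return `cands` with a `normalized_rpm` column appended.
#' @export
normalize_tss <- function(cands, expression, config = pipeline_config()) {
  if (nrow(cands) == 0) {
    cands$normalized_rpm <- numeric(0)
    return(cands)
  }
  tpm <- expression$tpm[match(cands$gene_id, expression$gene_id)]
  tpm[is.na(tpm)] <- 0
  u <- cands$rpm / pmax(tpm, config$tpm_floor)
  cands$normalized_rpm <- u * 1e6 / sum(u)
  cands
}

#' Cluster candidate positions in sliding windows
#'
#' Greedy highest-value peak picking per contig and strand: candidates are
#' visited in decreasing value (ties: smaller coordinate first) and
#' accepted unless an already-accepted candidate lies within strictly less
#' than `window` bp on the same contig and strand.  Retained values are
#' unchanged, and no two retained positions on one contig/strand are
#' closer than `window` bp.
#'
#' @param cands candidate data.frame.
#' @param window suppression radius in bp (`|delta pos| < window`).
#' @param value_col column holding the value to cluster on
#'   (`normalized_rpm` for the normalized data set, `rpm` for raw).
#' @return the retained subset of `cands`.
#' @export
cluster_tss <- function(cands, window = 5, value_col = "rpm") {
  if (nrow(cands) == 0) return(cands)
  keep <- logical(nrow(cands))
  groups <- split(seq_len(nrow(cands)),
                  paste(cands$contig, cands$strand), drop = TRUE)
  w <- as.integer(window)
  for (grp in groups) {
    v <- cands[[value_col]][grp]
    p <- cands$pos[grp]
    ord <- order(-v, p)
    off <- min(p) - 1L
    occ <- logical(max(p) - off)
    m <- length(occ)
    for (i in ord) {
      q <- p[i] - off
      lo <- max(1L, q - w + 1L)
      hi <- min(m, q + w - 1L)
      if (!any(occ[lo:hi])) {
        occ[q] <- TRUE
        keep[grp[i]] <- TRUE
      }
    }
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the RPM cutoff
#'
#' Keeps candidates whose value is at least `cutoff` (boundary inclusive).
#' Applied after clustering; raising the cutoff never adds a TSS, so the
#' permissive (10) set nests the high-confidence (25) set.
#'
#' @param cands clustered candidate data.frame.
#' @param cutoff minimum value, inclusive.
#' @param value_col column to threshold on.
#' @return the retained subset.
#' @export
threshold_tss <- function(cands, cutoff = 25, value_col = "rpm") {
  out <- cands[cands[[value_col]] >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full TSS-calling pipeline
#'
#' Stages, in order: scale each replicate to RPM, intersect replicates
#' (positions absent from either replicate are discarded), associate and
#' classify candidates, optionally normalize by associated-gene expression,
#' cluster in sliding windows, and threshold.  `mode = "raw"` skips the
#' normalization stage and clusters/thresholds plain RPM values, which
#' reproduces the expression-biased behavior that normalization corrects.
#'
#' @param rep1,rep2 raw `read_start_track`s; `rep2 = NULL` runs in
#'   single-replicate mode.
#' @param ann gene annotation data.frame.
#' @param expression expression table with `gene_id` and `tpm`; required
#'   in normalized mode.
#' @param config a [pipeline_config()].
#' @param mode `"normalized"` (default) or `"raw"`.
#' @return TSS data.frame with columns `tss_id`, `contig`, `pos`,
#'   `strand`, `rpm`, `normalized_rpm`, gene association fields and
#'   `category`; per-stage record counts are attached as attribute
#'   `stage_counts`.  In raw mode `normalized_rpm` equals `rpm`.
#' @export
call_tss <- function(rep1, rep2 = NULL, ann, expression = NULL,
                     config = pipeline_config(),
                     mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (mode == "normalized" && is.null(expression))
    stop("normalized mode requires an expression table")
  cands <- intersect_replicates(to_rpm(rep1),
                                if (!is.null(rep2)) to_rpm(rep2))
  counts <- c(candidates = nrow(cands))
  cands <- classify_tss(associate_genes(cands, ann))
  if (mode == "normalized") {
    cands <- normalize_tss(cands, expression, config)
    value_col <- "normalized_rpm"
  } else {
    cands$normalized_rpm <- cands$rpm
    value_col <- "rpm"
  }
  cands <- cluster_tss(cands, window = config$window, value_col = value_col)
  counts <- c(counts, clustered = nrow(cands))
  cands <- threshold_tss(cands, cutoff = config$cutoff, value_col = value_col)
  counts <- c(counts, reported = nrow(cands))
  cands <- sort_tss(cands)
  if (nrow(cands) > 0)
    cands <- cbind(tss_id = sprintf("TSS_%d", seq_len(nrow(cands))), cands)
  attr(cands, "stage_counts") <- counts
  cands
}
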