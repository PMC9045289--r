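#' Seeded synthetic data with planted ground truth
#'
#' The generator emulates the data regime of a bacterial 5'-end
#' sequencing experiment with matched RNA-seq: a compact genome of
#' alternating-strand genes, log-normally distributed expression with a
#' heavy tail above 1,000 TPM, one planted intergenic-sense TSS per gene
#' whose read-start signal scales with expression, purine-biased
#' initiating nucleotides, and expression-proportional background read
#' starts scattered along gene bodies (nonspecific initiation and
#' retained processed transcripts).  Two replicate tracks are drawn
#' independently with Poisson noise.  Every draw is deterministic per
#' seed.
#'
#' @name synthetic_data
NULL

#' Generate a synthetic genome and annotation
#'
#' Genes of fixed length alternate strands along a single linear contig,
#' separated (and flanked) by `intergenic_len` bp.  Positions are integer
#' arithmetic, so the layout is fully deterministic; only the sequence is
#' random.  The base composition is AT-rich (31% GC), typical of
#' clostridial genomes.
#'
#' @param n_genes number of genes (>= 1).
#' @param gene_len gene length in bp.
#' @param intergenic_len spacing between and around genes in bp.
#' @param seed integer seed.
#' @param gc GC content of the random sequence.
#' @param contig_name contig id.
#' @return list `genome` (a [genome()] object), `ann` (annotation
#'   data.frame).
#' @export
generate_genome <- function(n_genes, gene_len = 900, intergenic_len = 200,
                            seed = 1L, gc = 0.31, contig_name = "chr") {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gene_len < 1 || intergenic_len < 1) stop("invalid sizes")
  set.seed(seed)
  total <- n_genes * (gene_len + intergenic_len) + intergenic_len
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), total, replace = TRUE, prob = p),
               collapse = "")
  start <- intergenic_len + (seq_len(n_genes) - 1L) *
    (gene_len + intergenic_len) + 1L
  ann <- gene_annotation(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    contig = contig_name, start = start, end = start + gene_len - 1L,
    strand = rep_len(c("+", "-"), n_genes))
  list(genome = genome(stats::setNames(seq, contig_name), circular = FALSE),
       ann = ann)
}

#' Generate true per-gene expression levels
#'
#' Log-normal TPMs rescaled to sum to one million.  The default spread
#' (`sdlog = 2`) places a tail of genes above 1,000 TPM while keeping a
#' long low-expression shoulder, the regime in which raw read-start
#' thresholds are expression-biased.
#'
#' @param ann annotation data.frame.
#' @param sdlog log-scale standard deviation (0 gives equal TPMs).
#' @param seed integer seed.
#' @return data.frame `gene_id`, `tpm` summing to 1e6.
#' @export
generate_expression <- function(ann, sdlog = 2, seed = 1L) {
  set.seed(seed)
  x <- stats::rlnorm(nrow(ann), meanlog = 0, sdlog = sdlog)
  data.frame(gene_id = ann$gene_id, tpm = x * 1e6 / sum(x),
             stringsAsFactors = FALSE)
}

#' Plant one intergenic-sense TSS per gene
#'
#' Each gene receives a TSS upstream of its translated start at a 5' UTR
#' distance drawn as `6 + Poisson(26)` (mode near the canonical ~32 bp),
#' capped below half the intergenic spacing so the TSS stays closest to
#' its own gene; with probability `leaderless_prob` the distance is
#' instead drawn uniformly from 0-5 bp (a leaderless transcript).  The
#' initiating base (on the TSS strand) is written into the genome
#' sequence: a purine (A/G) with probability `p_purine`, otherwise a
#' pyrimidine.  The planted strength is the expected fraction of library
#' reads initiating at the TSS, `tss_fraction * tpm / 1e6`, i.e.
#' promoter output proportional to transcript abundance.
#'
#' @param sim list `genome`, `ann` from [generate_genome()].
#' @param expression data.frame `gene_id`, `tpm` (see
#'   [generate_expression()]).
#' @param tss_fraction total expected fraction of read starts that come
#'   from planted TSSs (the remainder is background).
#' @param p_purine probability that the initiating base is A or G.
#' @param leaderless_prob probability of a leaderless (UTR < 6 bp) TSS.
#' @param utr_mean mean of the Poisson UTR-length component.
#' @param seed integer seed.
#' @return list `genome` (with initiating bases written), `ann`,
#'   `truth`: data.frame `gene_id`, `contig`, `pos`, `strand`,
#'   `utr`, `leaderless`, `strength`, `init_base`.
#' @export
plant_tss <- function(sim, expression, tss_fraction = 0.3, p_purine = 0.95,
                      leaderless_prob = 0.025, utr_mean = 26, seed = 1L) {
  set.seed(seed)
  ann <- sim$ann
  n <- nrow(ann)
  # Cap UTR lengths at just under half the intergenic spacing so every
  # planted TSS stays closest to (and upstream of) its own gene.
  gene_len <- ann$end - ann$start + 1
  gap <- if (n > 1) min(diff(sort(ann$start)) - gene_len[-n]) else
    min(ann$start) - 1
  utr_cap <- max(6L, min(200L, floor(gap / 2) - 2L, min(ann$start) - 1L))
  leaderless <- stats::runif(n) < leaderless_prob
  # leaderless UTRs are drawn from 1-5 bp: a 0-bp UTR would place the TSS
  # on the translated start itself, i.e. inside the gene (IntraS)
  utr <- ifelse(leaderless, sample(1:5, n, replace = TRUE),
                pmin(6L + stats::rpois(n, utr_mean), utr_cap))
  pos <- ifelse(ann$strand == "+", ann$cds_start - utr, ann$cds_start + utr)
  tpm <- expression$tpm[match(ann$gene_id, expression$gene_id)]
  strength <- tss_fraction * tpm / 1e6
  base <- ifelse(stats::runif(n) < p_purine,
                 sample(c("A", "G"), n, replace = TRUE),
                 sample(c("C", "T"), n, replace = TRUE))
  genome <- sim$genome
  for (i in seq_len(n)) {
    written <- if (ann$strand[i] == "+") base[i] else complement_base(base[i])
    s <- genome$contigs[[ann$contig[i]]]
    substr(s, pos[i], pos[i]) <- written
    genome$contigs[[ann$contig[i]]] <- s
  }
  truth <- data.frame(gene_id = ann$gene_id, contig = ann$contig,
                      pos = as.integer(pos), strand = ann$strand,
                      utr = as.integer(utr), leaderless = leaderless,
                      strength = strength, init_base = base,
                      stringsAsFactors = FALSE)
  list(genome = genome, ann = ann, truth = truth)
}

#' Simulate replicate 5'-end read-start tracks
#'
#' Each replicate draws, independently: at every planted TSS, a Poisson
#' count with mean `strength * depth`; and for every gene, a Poisson
#' total of background read starts with mean
#' `depth * beta * (tpm / 1e6) * (length / 1000)` scattered uniformly
#' over the gene body on the sense strand.  `beta` is thus the expected
#' number of background starts per kilobase of gene body per sequenced
#' read at relative expression 1; `beta = 0` gives noiseless tracks with
#' reads only at planted positions.
#'
#' The default depth puts gene-body background in the read-dense regime
#' (multiple reads per position on expressed genes), where replicate
#' intersection behaves as it does on a full-size genome; at sparse
#' depths, isolated single-read positions that happen to recur in both
#' replicates dominate the background instead.
#'
#' @param planted list from [plant_tss()] (uses `ann` and `truth`).
#' @param expression data.frame `gene_id`, `tpm`.
#' @param depth expected number of read starts per replicate at total
#'   signal fraction 1.
#' @param beta background rate (see above).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list of `n_reps` raw `read_start_track`s.
#' @export
simulate_capp_switch <- function(planted, expression, depth = 1e7,
                                 beta = 2, n_reps = 2, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  ann <- planted$ann
  truth <- planted$truth
  tpm <- expression$tpm[match(ann$gene_id, expression$gene_id)]
  bg_mean <- depth * beta * (tpm / 1e6) * ((ann$end - ann$start + 1) / 1000)
  lapply(seq_len(n_reps), function(r) {
    tss_counts <- stats::rpois(nrow(truth), truth$strength * depth)
    bg_tot <- stats::rpois(nrow(ann), bg_mean)
    # gene bodies never overlap planted (intergenic) TSS positions, so
    # per-gene background counts can be tabulated independently
    bg <- lapply(seq_len(nrow(ann)), function(i) {
      if (bg_tot[i] == 0) return(NULL)
      len <- ann$end[i] - ann$start[i] + 1L
      cnt <- tabulate(sample.int(len, bg_tot[i], replace = TRUE), len)
      nz <- which(cnt > 0L)
      list(pos = ann$start[i] + nz - 1L, count = cnt[nz],
           contig = ann$contig[i], strand = ann$strand[i])
    })
    bg <- bg[!vapply(bg, is.null, logical(1))]
    df <- data.frame(
      contig = c(truth$contig,
                 unlist(lapply(bg, function(b) rep(b$contig, length(b$pos))))),
      strand = c(truth$strand,
                 unlist(lapply(bg, function(b) rep(b$strand, length(b$pos))))),
      pos = c(truth$pos, unlist(lapply(bg, `[[`, "pos"))),
      count = c(tss_counts, unlist(lapply(bg, `[[`, "count"))),
      stringsAsFactors = FALSE)
    df <- df[df$count > 0, , drop = FALSE]
    read_start_track_from_counts(df$contig, df$strand, df$pos, df$count)
  })
}

#' Simulate per-gene RNA-seq counts
#'
#' Counts are Poisson with mean `depth * tpm_g * length_g /
#' sum(tpm * length)` (reads proportional to transcript mass), so
#' [compute_tpm()] on the output recovers the true TPMs up to sampling
#' noise; with `deterministic = TRUE` the means are returned unrounded
#' and the recovery is exact.
#'
#' @param expression data.frame `gene_id`, `tpm` (true TPM).
#' @param ann annotation data.frame.
#' @param depth expected total read count.
#' @param deterministic skip the Poisson draw?
#' @param seed integer seed.
#' @return data.frame `gene_id`, `count`, `length`.
#' @export
simulate_rnaseq_counts <- function(expression, ann, depth = 1e6,
                                   deterministic = FALSE, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  len <- (ann$end - ann$start + 1)[match(expression$gene_id, ann$gene_id)]
  w <- expression$tpm * len
  mean_count <- depth * w / sum(w)
  count <- if (deterministic) mean_count else stats::rpois(length(w), mean_count)
  data.frame(gene_id = expression$gene_id, count = count, length = len,
             stringsAsFactors = FALSE)
}

#' One-stop synthetic experiment
#'
#' Composes [generate_genome()], [generate_expression()], [plant_tss()],
#' [simulate_capp_switch()] and [simulate_rnaseq_counts()] with derived
#' sub-seeds, returning everything needed to run and evaluate the
#' pipeline.
#'
#' @param n_genes,gene_len,intergenic_len genome layout (see
#'   [generate_genome()]).
#' @param sdlog expression spread (see [generate_expression()]).
#' @param depth read starts per replicate at signal fraction 1.
#' @param beta background rate (see [simulate_capp_switch()]).
#' @param tss_fraction,p_purine,leaderless_prob planted-TSS parameters
#'   (see [plant_tss()]).
#' @param seed master integer seed.
#' @return list `genome`, `ann`, `expression` (true TPM), `truth`,
#'   `tracks` (list of 2 replicate tracks), `rnaseq` (counts table with
#'   TPM computed).
#' @export
simulate_tss_experiment <- function(n_genes = 200, gene_len = 900,
                                    intergenic_len = 200, sdlog = 2,
                                    depth = 1e7, beta = 2,
                                    tss_fraction = 0.3, p_purine = 0.95,
                                    leaderless_prob = 0.025, seed = 1L) {
  seed <- as.integer(seed)
  sim <- generate_genome(n_genes, gene_len, intergenic_len, seed = seed)
  expression <- generate_expression(sim$ann, sdlog = sdlog, seed = seed + 1L)
  planted <- plant_tss(sim, expression, tss_fraction = tss_fraction,
                       p_purine = p_purine,
                       leaderless_prob = leaderless_prob, seed = seed + 2L)
  tracks <- simulate_capp_switch(planted, expression, depth = depth,
                                 beta = beta, n_reps = 2, seed = seed + 3L)
  rnaseq <- compute_tpm(simulate_rnaseq_counts(expression, sim$ann,
                                               depth = depth,
                                               seed = seed + 4L))
  list(genome = planted$genome, ann = sim$ann, expression = expression,
       truth = planted$truth, tracks = tracks, rnaseq = rnaseq)
}

#' Write a synthetic experiment to disk in the package's input formats
#'
#' Writes FASTA (genome), GFF3 (annotation), two bedGraph files per
#' replicate track (one per strand), the RNA-seq count TSV and the truth
#' TSV, i.e. exactly what the file-based pipeline entry points consume.
#'
#' @param experiment list from [simulate_tss_experiment()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of paths.
#' @export
write_synthetic_dataset <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "genes.gff3"),
             rnaseq = file.path(dir, "rnaseq_counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genome_fasta(experiment$genome, paths[["genome"]])
  write_gene_annotation(experiment$ann, paths[["annotation"]])
  write.table(experiment$rnaseq[c("gene_id", "count", "length")],
              paths[["rnaseq"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(experiment$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (r in seq_along(experiment$tracks)) {
    fwd <- file.path(dir, sprintf("capp_rep%d_fwd.bedgraph", r))
    rev <- file.path(dir, sprintf("capp_rep%d_rev.bedgraph", r))
    write_start_track(experiment$tracks[[r]], fwd, rev)
    paths[[sprintf("rep%d_fwd", r)]] <- fwd
    paths[[sprintf("rep%d_rev", r)]] <- rev
  }
  invisible(paths)
}
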