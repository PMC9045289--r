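inters_rec <- function(pos, strand, upstream, category = "InterS") {
  data.frame(contig = "c1", pos = pos, strand = strand, rpm = 1,
             normalized_rpm = 1, gene_id = "g", localization = "intergenic",
             orientation = "sense", distance = upstream,
             upstream_of_cds = upstream, category = category,
             stringsAsFactors = FALSE)
}

test_that("5' UTR lengths and leaderless calls follow the strand-aware distance", {
  r <- utr_length(inters_rec(950L, "+", 1000 - 950))
  expect_equal(r$utr_length, 50)
  expect_false(r$leaderless)

  r2 <- utr_length(inters_rec(996L, "+", 1000 - 996))
  expect_equal(r2$utr_length, 4)
  expect_true(r2$leaderless)

  # minus-strand gene 1000-2000, TSS at 2032: UTR measured toward the end
  r3 <- utr_length(inters_rec(2032L, "-", 2032 - 2000))
  expect_equal(r3$utr_length, 32)

  expect_error(utr_length(inters_rec(10L, "+", 5, category = "IntraS")),
               "InterS")
})

test_that("promoter extraction excludes the TSS base and respects strand", {
  g <- genome(c(c1 = "AAACGTTT"))
  plus <- extract_promoters(inters_rec(7L, "+", 1), g, promoter_len = 3)
  expect_equal(plus$seq, "CGT")
  expect_false(plus$truncated)

  minus <- extract_promoters(inters_rec(2L, "-", 1), g, promoter_len = 3)
  expect_equal(minus$seq, "CGT")  # revcomp of positions 3..5 "ACG"

  clipped <- extract_promoters(inters_rec(2L, "+", 1), g, promoter_len = 5)
  expect_equal(clipped$seq, "A")
  expect_true(clipped$truncated)

  wrapped <- extract_promoters(inters_rec(2L, "+", 1),
                               genome(c(c1 = "AAACGTTT"), circular = TRUE),
                               promoter_len = 5)
  expect_equal(wrapped$seq, "GTTTA")  # positions -3..1 wrap to 5..8, 1
  expect_false(wrapped$truncated)
})

test_that("opposite-strand promoters of one site are reverse complements", {
  set.seed(21)
  g <- genome(c(c1 = random_dna(400)))
  for (pos in sample(100:300, 5)) {
    p <- extract_promoters(inters_rec(pos, "+", 1), g, 20)$seq
    # the minus-strand TSS whose upstream window covers the same 20 bases
    m <- extract_promoters(inters_rec(pos - 21L, "-", 1), g, 20)$seq
    expect_equal(m, revcomp(p))
  }
})

test_that("initiating bases are read on the TSS strand", {
  g <- genome(c(c1 = "GGGG"))
  all_g <- data.frame(contig = "c1", pos = 1:4, strand = "+")
  expect_equal(initiating_base_stats(all_g, g)$purine_fraction, 1.0)

  gC <- genome(c(c1 = "ACGT"))
  minus_on_c <- data.frame(contig = "c1", pos = 2L, strand = "-")
  st <- initiating_base_stats(minus_on_c, gC)
  expect_equal(unname(st$counts["G"]), 1L)  # genomic C read as G on minus

  empty <- initiating_base_stats(all_g[0, ], g)
  expect_true(is.na(empty$purine_fraction))
})

test_that("summaries count categories, per-gene InterS TSSs and read mass", {
  rec <- rbind(inters_rec(10L, "+", 5), inters_rec(60L, "+", 55),
               inters_rec(200L, "+", 0, category = "IntraS"))
  rec$gene_id <- c("g1", "g1", "g2")
  rec$normalized_rpm <- c(10, 30, 60)
  ann <- gene_annotation(c("g1", "g2", "g3"), "c1", c(100, 300, 500),
                         c(200, 400, 600), "+")
  s <- summarize_tss(rec, ann)
  expect_equal(s$categories$n[s$categories$category == "InterS"], 2L)
  expect_equal(s$categories$read_mass_fraction[
    s$categories$category == "InterS"], 0.4)
  expect_equal(s$inters_per_gene$n_genes[s$inters_per_gene$n_tss == "2"], 1L)
  expect_equal(s$genes_with_inters$n, 1)
  expect_equal(s$genes_with_inters$fraction, 1 / 3)

  z <- summarize_tss(rec[0, ], ann)
  expect_true(all(z$categories$n == 0L))
  # one record per category
  four <- rbind(inters_rec(10L, "+", 5),
                inters_rec(20L, "-", 5, category = "InterA"),
                inters_rec(150L, "+", 0, category = "IntraS"),
                inters_rec(160L, "-", 0, category = "IntraA"))
  s4 <- summarize_tss(four, ann)
  expect_equal(s4$categories$n[s4$categories$category != "unassigned"],
               rep(1L, 4))
})

test_that("IUPAC scanning honors degeneracy", {
  hit <- iupac_scan("CCTATAATGG", "TATAAT", max_indels = 0,
                    both_strands = FALSE)
  expect_equal(hit$start, 3L)
  expect_equal(hit$match, "TATAAT")

  degen <- iupac_scan("TACAAT", "TANAAT", max_indels = 0,
                      both_strands = FALSE)
  expect_equal(nrow(degen), 1L)

  expect_error(iupac_scan("ACGT", "TAZ"), "invalid IUPAC")
})

test_that("one indel lets the pattern absorb a deletion or insertion", {
  # deletion: TATAAT matches TATAT with one base removed
  del <- iupac_scan("GGTATATGG", "TATAAT", max_indels = 1,
                    both_strands = FALSE)
  expect_equal(nrow(del), 1L)
  expect_equal(del$n_indels, 1L)
  expect_equal(del$match, "TATAT")
  expect_equal(c(del$start, del$end), c(3L, 7L))

  # insertion: an extra subject base inside the motif
  ins <- iupac_scan("GGTATCAATGG", "TATAAT", max_indels = 1,
                    both_strands = FALSE)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$match, "TATCAAT")

  # exact matches are preferred over indel matches at the same locus
  exact <- iupac_scan("GGTATAATGG", "TATAAT", max_indels = 1,
                      both_strands = FALSE)
  expect_equal(exact$n_indels, 0L)
})

test_that("no-indel scanning matches the regex oracle on both strands", {
  set.seed(31)
  patterns <- c("TATAAT", "TTGACA", "TANAAT", "RYSWKM", "TGNCGAA")
  for (i in 1:6) {
    seq <- random_dna(300)
    for (pat in patterns) {
      got <- iupac_scan(seq, pat, max_indels = 0, both_strands = TRUE)
      want <- oracle_iupac_both(seq, pat)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("selected matches never overlap on a strand", {
  set.seed(32)
  for (i in 1:5) {
    hits <- iupac_scan(random_dna(500), "WWWWWW", max_indels = 1)
    for (s in unique(hits$strand)) {
      h <- hits[hits$strand == s, ]
      h <- h[order(h$start), ]
      if (nrow(h) > 1)
        expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    }
  }
})

test_that("promoter sets are scanned motif by motif", {
  proms <- data.frame(promoter_id = c("p1", "p2"),
                      seq = c("CCTATAATGG", "CCCCCCCCCC"),
                      stringsAsFactors = FALSE)
  motifs <- data.frame(name = "sigA_minus10", iupac = "TATAAT",
                       max_indels = 0)
  hits <- scan_promoters(proms, motifs, both_strands = FALSE)
  expect_equal(hits$promoter_id, "p1")
  expect_equal(attr(hits, "motif_summary")$n_promoters, 1L)
})

test_that("the shipped example motif list is valid", {
  motifs <- example_sigma_motifs()
  expect_true(nrow(motifs) >= 5)
  expect_true(all(c("name", "iupac", "max_indels") %in% names(motifs)))
})
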