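test_that("TPM computation matches the defining formula", {
  eq <- compute_tpm(data.frame(gene_id = c("a", "b"), count = c(5, 5),
                               length = c(100, 100)))
  expect_equal(eq$tpm, c(5e5, 5e5))

  tab <- compute_tpm(data.frame(gene_id = c("g1", "g2"),
                                count = c(100, 100),
                                length = c(1000, 2000)))
  expect_equal(tab$tpm, c(666666.6667, 333333.3333), tolerance = 1e-9)
  expect_equal(sum(tab$tpm), 1e6)

  zero <- compute_tpm(data.frame(gene_id = "g", count = 0, length = 10))
  expect_equal(zero$tpm, 0)
})

test_that("average_tpm averages replicates per gene", {
  a <- data.frame(gene_id = c("g1", "g2"), tpm = c(100, 300))
  b <- data.frame(gene_id = c("g2", "g1"), tpm = c(100, 300))
  avg <- average_tpm(a, b)
  expect_equal(avg$tpm[avg$gene_id == "g1"], 200)
  expect_equal(avg$tpm[avg$gene_id == "g2"], 200)
  expect_equal(average_tpm(a), a)
})

test_that("expression normalization rescales to one million and orders by
          rpm/TPM ratio", {
  one <- normalize_tss(data.frame(contig = "c", strand = "+", pos = 1L,
                                  rpm = 42, gene_id = "g"),
                       data.frame(gene_id = "g", tpm = 17))
  expect_equal(one$normalized_rpm, 1e6)

  two <- normalize_tss(
    data.frame(contig = "c", strand = "+", pos = c(1L, 2L), rpm = c(100, 100),
               gene_id = c("hi", "lo")),
    data.frame(gene_id = c("hi", "lo"), tpm = c(1000, 10)))
  expect_equal(two$normalized_rpm, c(9900.990099, 990099.009901),
               tolerance = 1e-9)

  # constant divisor: normalization is rank-preserving within one gene
  same <- normalize_tss(
    data.frame(contig = "c", strand = "+", pos = 1:5,
               rpm = c(5, 40, 12, 7, 33), gene_id = "g"),
    data.frame(gene_id = "g", tpm = 123))
  expect_equal(order(same$normalized_rpm), order(same$rpm))

  # orphans and missing genes fall back to the TPM floor
  orphan <- normalize_tss(
    data.frame(contig = "c", strand = "+", pos = c(1L, 2L), rpm = c(10, 10),
               gene_id = c(NA, "known")),
    data.frame(gene_id = "known", tpm = 100))
  expect_equal(orphan$normalized_rpm[1] / orphan$normalized_rpm[2], 100)
})

test_that("normalized mass is conserved at one million", {
  set.seed(3)
  cands <- data.frame(contig = "c", strand = "+", pos = seq_len(300),
                      rpm = runif(300, 0.01, 1000),
                      gene_id = sample(sprintf("g%d", 1:40), 300, TRUE))
  expr <- data.frame(gene_id = sprintf("g%d", 1:40),
                     tpm = rlnorm(40, 5, 2))
  out <- normalize_tss(cands, expr)
  expect_equal(sum(out$normalized_rpm), 1e6, tolerance = 1e-6)
})

test_that("window clustering keeps the strongest position per conflict", {
  df <- function(pos, val) data.frame(contig = "c", strand = "+", pos = pos,
                                      rpm = val)
  expect_equal(cluster_tss(df(c(100L, 102L, 104L), c(50, 80, 30)),
                           window = 5)$pos, 102L)
  expect_equal(cluster_tss(df(c(100L, 110L), c(10, 10)), window = 5)$pos,
               c(100L, 110L))
  # equal values: smaller coordinate wins
  expect_equal(cluster_tss(df(c(100L, 103L), c(7, 7)), window = 5)$pos, 100L)
  # strands are clustered independently
  both <- rbind(df(100L, 5),
                data.frame(contig = "c", strand = "-", pos = 102L, rpm = 9))
  expect_equal(nrow(cluster_tss(both, window = 5)), 2L)
})

test_that("greedy clustering equals the exhaustive priority oracle", {
  set.seed(11)
  for (i in 1:25) {
    cands <- random_candidates(n_max = 120, span = 300)
    got <- sort(cluster_tss(cands, window = 5)$pos)
    expect_equal(got, oracle_cluster(cands$pos, cands$rpm, window = 5))
  }
})

test_that("no two retained TSSs are closer than the window", {
  set.seed(12)
  for (i in 1:10) {
    w <- sample(2:8, 1)
    out <- cluster_tss(random_candidates(), window = w)
    expect_true(all(diff(sort(out$pos)) >= w))
  }
})

test_that("thresholding is inclusive and nests across cutoffs", {
  df <- data.frame(contig = "c", strand = "+", pos = 1:3,
                   rpm = c(9.9, 10.0, 25.0))
  expect_equal(threshold_tss(df, 10)$rpm, c(10, 25))
  expect_equal(threshold_tss(df, 25)$rpm, 25)
  expect_equal(nrow(threshold_tss(df[0, ], 10)), 0L)

  set.seed(13)
  cands <- random_candidates()
  hi <- threshold_tss(cands, 25)
  lo <- threshold_tss(cands, 10)
  expect_true(all(tss_key(hi) %in% tss_key(lo)))
})

test_that("the pipeline reports a planted TSS only when both replicates see it", {
  ann <- gene_annotation("g1", "c1", 1000, 1900, "+")
  expr <- data.frame(gene_id = "g1", tpm = 100)
  tss <- function(count) read_start_track_from_counts("c1", "+", 950L, count)
  both <- call_tss(tss(50), tss(60), ann, expr)
  expect_equal(nrow(both), 1L)
  expect_equal(both$pos, 950L)
  expect_equal(both$category, "InterS")
  expect_equal(both$normalized_rpm, 1e6)

  blank <- read_start_track_from_counts("c1", "+", 10L, 1)
  expect_equal(nrow(call_tss(tss(50), blank, ann, expr)), 0L)
})

test_that("normalization strips expression-driven gene-body background", {
  # g1 is 100x more expressed than g2 and carries heavy body background;
  # counts are identical in both replicates so the contrast is exact.
  ann <- gene_annotation(c("g1", "g2"), "c1", c(1000, 3000), c(1900, 3900),
                         c("+", "+"))
  expr <- data.frame(gene_id = c("g1", "g2"), tpm = c(5000, 50))
  tr <- function() read_start_track_from_counts(
    "c1", "+", c(950L, 1200L, 1300L, 1400L, 2950L), c(100, 30, 30, 30, 30))
  cfg <- pipeline_config(cutoff = 30000)

  raw <- call_tss(tr(), tr(), ann, config = cfg, mode = "raw")
  expect_true(all(c(950, 1200, 1300, 1400, 2950) %in% raw$pos))

  norm <- call_tss(tr(), tr(), ann, expr, config = cfg, mode = "normalized")
  expect_equal(sort(norm$pos), c(950L, 2950L))  # planted TSSs only
  # hand-computed rescaled values: u = rpm/tpm, scaled to 1e6 total
  u <- c((100 / 220 * 1e6) / 5000, (30 / 220 * 1e6) / 50)
  total_u <- (190 / 220 * 1e6) / 5000 + (30 / 220 * 1e6) / 50
  expect_equal(norm$normalized_rpm[norm$pos == 950L], u[1] / total_u * 1e6,
               tolerance = 1e-9)
  expect_equal(norm$normalized_rpm[norm$pos == 2950L], u[2] / total_u * 1e6,
               tolerance = 1e-9)
})

test_that("configuration files override defaults and reject junk", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("cutoff = 10", "window = 7"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$cutoff, 10)
  expect_equal(cfg$window, 7)
  expect_equal(cfg$promoter_len, 50)

  ypath <- tempfile(fileext = ".yaml")
  writeLines(c("cutoff: 10", "tpm_floor: 2"), ypath)
  ycfg <- read_pipeline_config(ypath)
  expect_equal(ycfg$cutoff, 10)
  expect_equal(ycfg$tpm_floor, 2)

  bad <- tempfile(fileext = ".cfg")
  writeLines("cutof = 10", bad)
  expect_error(read_pipeline_config(bad), "unknown configuration")
  expect_error(pipeline_config(cutoff = -5))
})
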