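test_that("peak merging unions overlaps and passes disjoint peaks through", {
  a <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
                  tissue = "ExE", mark = "H3K4me3")
  b <- data.frame(chrom = "chr1", start = 150L, end = 250L,
                  tissue = "ExE", mark = "H3K4me3")
  m <- merge_peak_sets(a, b)
  expect_equal(m$start, c(100L, 300L))
  expect_equal(m$end, c(250L, 400L))
  # idempotence on identical sets
  m2 <- merge_peak_sets(a, a)
  expect_equal(nrow(m2), nrow(a))
  # abutting (0 bp overlap) peaks stay separate
  ab <- data.frame(chrom = "chr1", start = 200L, end = 300L,
                   tissue = "ExE", mark = "H3K4me3")
  expect_equal(nrow(merge_peak_sets(a[1, ], ab)), 2L)
  b$tissue <- "epiblast"
  expect_error(merge_peak_sets(a, b), "mixed tissue")
})

mk_read2 <- function(id, start, end, strand = "+", sample = "s1", rep = 1L) {
  data.frame(read_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, sample_id = sample, replicate = rep,
             snp_obs = ".", junctions = ".", stringsAsFactors = FALSE)
}

test_that("region counting follows the midpoint rule", {
  regions <- data.frame(id = c("a", "b"), chrom = "chr1",
                        start = c(100L, 200L), end = c(200L, 300L),
                        strand = c("+", "+"))
  # read [180, 260): midpoint 219 -> region b only
  parts <- list(maternal = mk_read2("r1", 180L, 260L),
                paternal = mk_read2("r2", 100L, 140L),  # midpoint 119 -> a
                unassigned = NULL)
  cnt <- count_over_regions(parts, regions, kind = "peak")
  cnt <- cnt[order(cnt$region_id), ]
  expect_equal(cnt$mat, c(0L, 1L))
  expect_equal(cnt$pat, c(1L, 0L))

  # strand-aware LTR counting drops opposite-strand reads
  parts2 <- list(maternal = rbind(mk_read2("r1", 110L, 150L, "+"),
                                  mk_read2("r2", 110L, 150L, "-")),
                 paternal = NULL, unassigned = NULL)
  cnt2 <- count_over_regions(parts2, regions[1, ], kind = "ltr")
  expect_equal(cnt2$mat, 1L)
})

test_that("gene counting is restricted to exons", {
  ref <- small_ref()
  g <- ref$genes[ref$genes$strand == "+", ][1, ]
  ex <- ref$exons[ref$exons$gene_id == g$id, ]
  intron_mid <- ex$end[1] + 200L
  exon_mid <- ex$start[2] + 10L
  parts <- list(
    maternal = rbind(
      mk_read2("r1", intron_mid - 40L, intron_mid + 40L),  # fully intronic
      mk_read2("r2", exon_mid - 40L, exon_mid + 40L)),     # midpoint exonic
    paternal = NULL, unassigned = NULL)
  parts$maternal$chrom <- g$chrom
  cnt <- count_over_regions(parts, ref$genes, kind = "gene",
                            exons = ref$exons)
  expect_equal(cnt$mat[cnt$region_id == g$id], 1L)
  expect_equal(sum(cnt$mat), 1L)
})

test_that("informativeness filter applies 20/5 at-least-one-replicate", {
  cnt <- rbind(make_counts("p1", 10L, 9L, 1L), make_counts("p1", 12L, 8L, 2L),
               make_counts("p2", 10L, 9L, 1L), make_counts("p2", 10L, 9L, 2L))
  expect_equal(filter_informative(cnt, "chip"), "p1")   # [19, 20] retained
  expect_equal(filter_informative(cnt, "chip", threshold = 21L),
               character(0))
  rna <- rbind(make_counts("g1", 5L, 0L, 1L), make_counts("g1", 0L, 0L, 2L),
               make_counts("g2", 2L, 2L, 1L), make_counts("g2", 0L, 4L, 2L))
  expect_equal(filter_informative(rna, "rna"), "g1")
  expect_error(filter_informative(cnt, "dnase"))
  # monotone: lowering the threshold never removes a region
  for (thr in c(25L, 20L, 10L, 5L, 1L)) {
    hi <- filter_informative(cnt, "chip", threshold = thr + 5L)
    lo <- filter_informative(cnt, "chip", threshold = thr)
    expect_true(all(hi %in% lo))
  }
})

test_that("size factors follow the median-of-ratios closed form", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  sf <- size_factor_normalize(m)
  expect_equal(unname(sf$factors), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf2 <- size_factor_normalize(m2)
  expect_equal(unname(sf2$factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(sf2$normalized[, "a"], sf2$normalized[, "b"])
  # X-chromosome regions are scaled but never drive the factors
  m3 <- rbind(m2, c(5, 20))
  sf3 <- size_factor_normalize(m3, chrom = c("chr1", "chr1", "chr1", "chrX"))
  expect_equal(sf3$factors, sf2$factors)
  # all-zero overlap triggers the total-count fallback, with warning
  m4 <- cbind(a = c(0, 4), b = c(4, 0))
  expect_warning(sf4 <- size_factor_normalize(m4), "total-count")
  expect_equal(unname(sf4$factors), c(1, 1))
})

test_that("running windows tile correctly and report RPKM", {
  chroms <- data.frame(chrom = "chr1", length = 10000L)
  reads <- mk_read2("r1", 500L, 580L)
  tr <- running_windows(reads, chroms, width = 1000L, step = 100L,
                        library_size = 1e6)
  expect_equal(nrow(tr), 91L)   # (10000 - 1000)/100 + 1
  expect_equal(max(tr$value), 1.0)  # 1 read, 1 Mb library, 1 kb window
  expect_equal(sum(tr$value > 0), 6L)  # midpoint 539 in 6 windows of step 100
  tr0 <- running_windows(reads[0, ], chroms, library_size = 100)
  expect_true(all(tr0$value == 0))
  expect_error(running_windows(reads, chroms, library_size = 0), "empty")
  expect_error(running_windows(reads, chroms, width = 50, step = 100),
               "width")
  # window counts at step = width conserve midpoint-assignable reads
  ref <- small_ref()
  sim <- simulate_genomic_reads(ref, small_config(), "B6/CAST", 500)
  full <- running_windows(sim$reads, ref$chromosomes, width = 1000L,
                          step = 1000L, library_size = 1e6)
  expect_equal(sum(full$value), nrow(sim$reads))
})

test_that("enrichment normalization anchors P40 at 0 and P99 at 1", {
  # 1..101 puts P40 = 41 and P99 = 100 exactly on data points
  v <- c(0, 0, seq_len(101))
  out <- enrichment_normalize(v)
  expect_equal(out[v == 41], 0)
  expect_equal(out[v == 100], 1)
  nz <- v[v != 0]
  p <- quantile(nz, c(0.4, 0.99), names = FALSE)
  expect_equal(out, (v - p[1]) / (p[2] - p[1]))
  # strictly increasing input -> strictly increasing output; affine
  expect_true(all(diff(out[order(v)]) >= 0))
  expect_equal(cor(out, v), 1)
  expect_error(enrichment_normalize(c(0, 5, 5, 5)), "degenerate")
})
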