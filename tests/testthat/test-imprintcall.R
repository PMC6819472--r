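test_that("reciprocal classification follows the consensus rules", {
  b1 <- rbind(bias_row("p1", "maternal"),          # imprinted maternal
              bias_row("p2", "maternal"),          # strain B6 (switches)
              bias_row("p3", "paternal"),          # strain CAST
              bias_row("p4", "maternal"),          # single cross only
              bias_row("p5", "none", significant = FALSE),
              bias_row("p6", "paternal"))          # imprinted paternal
  b2 <- rbind(bias_row("p1", "maternal"),
              bias_row("p2", "paternal"),
              bias_row("p3", "maternal"),
              bias_row("p4", "none", significant = FALSE),
              bias_row("p5", "none", significant = FALSE),
              bias_row("p6", "paternal"))
  calls <- classify_reciprocal(b1, b2)
  got <- setNames(calls$consensus_class, calls$region_id)
  expect_equal(got[["p1"]], "imprinted_maternal")
  expect_equal(got[["p2"]], "strain_B6")
  expect_equal(got[["p3"]], "strain_CAST")
  expect_equal(got[["p4"]], "single_cross_only")
  expect_equal(got[["p5"]], "biallelic")
  expect_equal(got[["p6"]], "imprinted_paternal")
  # region missing from one cross -> unresolved
  calls2 <- classify_reciprocal(b1, b2[b2$region_id != "p1", ])
  expect_equal(calls2$consensus_class[calls2$region_id == "p1"],
               "unresolved")
  # no region gets both a strain and an imprint label (single label each)
  expect_true(all(table(calls$region_id) == 1))
})

test_that("relabeling the crosses fixes imprints and swaps strains", {
  b1 <- rbind(bias_row("p1", "maternal"), bias_row("p2", "maternal"),
              bias_row("p3", "paternal"))
  b2 <- rbind(bias_row("p1", "maternal"), bias_row("p2", "paternal"),
              bias_row("p3", "paternal"))
  fwd <- classify_reciprocal(b1, b2)
  rev <- classify_reciprocal(b2, b1)
  swap <- c(biallelic = "biallelic", strain_B6 = "strain_CAST",
            strain_CAST = "strain_B6",
            imprinted_maternal = "imprinted_maternal",
            imprinted_paternal = "imprinted_paternal",
            single_cross_only = "single_cross_only")
  expect_equal(rev$consensus_class, unname(swap[fwd$consensus_class]))
})

test_that("matDKO contrast separates canonical from non-canonical", {
  calls <- data.frame(
    region_id = c("p1", "p2", "p3", "p4"),
    consensus_class = c("imprinted_paternal", "imprinted_paternal",
                        "imprinted_paternal", "imprinted_maternal"),
    stringsAsFactors = FALSE)
  dko <- rbind(
    bias_row("p1", "paternal"),                        # retained, no gDMR
    bias_row("p2", "none", significant = FALSE, ratio = 0.5, q = 0.8),
    bias_row("p3", "paternal"),                        # retained, gDMR
    bias_row("p4", "none", significant = FALSE, ratio = 0.2))  # outside band
  gdmr <- data.frame(region_id = "p3", status = "paternal_gDMR",
                     stringsAsFactors = FALSE)
  res <- classify_canonical(calls, dko, gdmr)
  got <- setNames(res$canonical_status, res$region_id)
  expect_equal(got[["p1"]], "non_canonical")
  expect_equal(got[["p2"]], "canonical_maternal")
  expect_equal(got[["p3"]], "canonical_paternal")
  expect_equal(got[["p4"]], "unresolved")  # ratio 0.2 despite q = 0.5
  # missing matDKO data -> unresolved
  res2 <- classify_canonical(calls[1, , drop = FALSE], dko[-1, ], gdmr)
  expect_equal(res2$canonical_status, "unresolved")
  # non-imprinted input is rejected
  bad <- data.frame(region_id = "x", consensus_class = "biallelic")
  expect_error(classify_canonical(bad, dko), "imprinted")
})

test_that("peak-to-gene assignment uses promoter overlap then proximity", {
  genes <- data.frame(
    id = c("gA", "gB", "gC"), name = c("A", "B", "C"), chrom = "chr1",
    start = c(5000L, 20000L, 40000L), end = c(11000L, 26000L, 46000L),
    strand = c("+", "+", "-"), tss = c(5000L, 20000L, 45999L),
    stringsAsFactors = FALSE)
  peaks <- data.frame(
    id = c("pk_prom", "pk_near", "pk_far", "pk_minus"),
    chrom = "chr1",
    start = c(4800L, 14000L, 70000L, 46300L),
    end = c(5200L, 14500L, 70500L, 46600L),
    stringsAsFactors = FALSE)
  asg <- assign_peak_to_gene(peaks, genes)
  prom <- asg[asg$peak_id == "pk_prom", ]
  expect_equal(prom$gene_id, "gA")
  expect_true(prom$promoter_overlap)
  near <- asg[asg$peak_id == "pk_near", ]
  expect_equal(near$gene_id, "gA")          # 3 kb from the gA gene body
  expect_equal(near$distance, 3000L)
  expect_false(near$promoter_overlap)
  far <- asg[asg$peak_id == "pk_far", ]
  expect_true(is.na(far$gene_id))           # 24 kb beyond everything
  # minus-strand promoter window extends right of the TSS
  minus <- asg[asg$peak_id == "pk_minus", ]
  expect_equal(minus$gene_id, "gC")
  expect_true(minus$promoter_overlap)
  # tie at equal distance breaks lexicographically
  genes2 <- genes[1:2, ]
  genes2$start <- c(5000L, 15000L); genes2$end <- c(8000L, 18000L)
  genes2$tss <- genes2$start
  tie_peak <- data.frame(id = "tie", chrom = "chr1",
                         start = 11000L, end = 12000L)
  tie <- assign_peak_to_gene(tie_peak, genes2)
  expect_equal(tie$gene_id, "gA")
})

test_that("peaks spanning two promoters report both genes", {
  genes <- data.frame(
    id = c("gA", "gB"), name = c("A", "B"), chrom = "chr1",
    start = c(5000L, 6000L), end = c(10000L, 12000L),
    strand = c("+", "+"), tss = c(5000L, 6000L), stringsAsFactors = FALSE)
  pk <- data.frame(id = "pk", chrom = "chr1", start = 4900L, end = 6100L)
  asg <- assign_peak_to_gene(pk, genes)
  expect_equal(sort(asg$gene_id), c("gA", "gB"))
  expect_true(all(asg$promoter_overlap))
})

test_that("expression cross-validation requires matching direction", {
  imp <- data.frame(region_id = c("p1", "p2", "p3"),
                    direction = c("paternal", "paternal", "maternal"),
                    gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  rna <- rbind(bias_row("g1", "paternal"),
               bias_row("g2", "maternal"),     # wrong direction
               bias_row("g3", "none", significant = FALSE))
  v <- cross_validate_expression(imp, list(rna = rna),
                                 list(rna = c("g1", "g2", "g3")))
  expect_equal(v$n_informative, 3L)
  expect_equal(v$n_validated, 1L)
  expect_equal(v$fraction, 1 / 3)
  # uninformative genes leave the denominator
  v2 <- cross_validate_expression(imp, list(rna = rna),
                                  list(rna = c("g1")))
  expect_equal(v2$n_informative, 1L)
  expect_equal(v2$fraction, 1)
  expect_error(cross_validate_expression(imp, list()), "auxiliary")
})

test_that("high-pi deep-coverage simdata validates >= 90% of imprints", {
  run <- default_run()
  expect_gte(run$validation$fraction, 0.9)
})
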