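## hand-built micro-fixture: one LTR in a peak, configurable read evidence
ltr_fix <- data.frame(id = "L1", chrom = "chr1", start = 1000L, end = 1400L,
                      strand = "+", stringsAsFactors = FALSE)
peak_fix <- data.frame(id = "P1", chrom = "chr1", start = 900L, end = 1900L,
                       stringsAsFactors = FALSE)

ltr_read <- function(id, start, end, strand = "+", rep = 1L,
                     junctions = ".") {
  data.frame(read_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, sample_id = "rna", replicate = rep,
             snp_obs = ".", junctions = junctions, stringsAsFactors = FALSE)
}

body_reads <- function(n, rep, strand = "+") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    ltr_read(sprintf("b%d_%d", rep, i), 1000L + i * 10L, 1100L + i * 10L,
             strand, rep)
  }))
}
donor_read <- function(rep = 1L) {
  ltr_read(paste0("d", rep), 1150L, 2630L, "+", rep, junctions = "1200-2600")
}

test_that("the promoter criteria are conjunctive", {
  full <- rbind(body_reads(6, 1L), body_reads(6, 2L), donor_read(1L))
  call <- identify_active_ltr_promoters(ltr_fix, peak_fix, full)
  expect_true(call$is_active_promoter)

  # (a) no peak overlap
  far_peak <- peak_fix; far_peak$start <- 5000L; far_peak$end <- 6000L
  expect_false(identify_active_ltr_promoters(ltr_fix, far_peak,
                                             full)$is_active_promoter)
  # (b) only 4 reads in one of the two replicates
  weak <- rbind(body_reads(6, 1L), body_reads(3, 2L), donor_read(2L))
  cb <- identify_active_ltr_promoters(ltr_fix, peak_fix, weak)
  expect_false(cb$is_active_promoter)
  expect_equal(cb$n_replicates_passing, 1L)
  # (c) no donor junction
  nodonor <- rbind(body_reads(6, 1L), body_reads(6, 2L))
  expect_false(identify_active_ltr_promoters(ltr_fix, peak_fix,
                                             nodonor)$is_active_promoter)
  # (d) an upstream junction splicing INTO the LTR
  incoming <- rbind(full,
                    ltr_read("up", 150L, 1230L, "+", 1L,
                             junctions = "200-1200"))
  cd <- identify_active_ltr_promoters(ltr_fix, peak_fix, incoming)
  expect_false(cd$is_active_promoter)
  expect_equal(cd$n_incoming_junctions, 1L)
  # opposite-strand reads never count
  wrong_strand <- rbind(body_reads(6, 1L, "-"), body_reads(6, 2L, "-"),
                        donor_read(1L))
  expect_false(identify_active_ltr_promoters(
    ltr_fix, peak_fix, wrong_strand)$is_active_promoter)
  # unstranded reads are rejected
  bad <- full; bad$strand[1] <- "."
  expect_error(identify_active_ltr_promoters(ltr_fix, peak_fix, bad),
               "stranded")
})

test_that("minus-strand junction orientation is interpreted biologically", {
  ltr_m <- ltr_fix; ltr_m$strand <- "-"
  # donor at the genomic right side of the junction for a minus transcript
  body <- rbind(body_reads(6, 1L, "-"), body_reads(6, 2L, "-"))
  donor_m <- ltr_read("dm", 370L, 1280L, "-", 1L, junctions = "400-1250")
  call <- identify_active_ltr_promoters(ltr_m, peak_fix,
                                        rbind(body, donor_m))
  expect_true(call$is_active_promoter)
  # the same junction is "incoming" for a minus LTR when donor is 3'->5'
  incoming_m <- ltr_read("um", 1170L, 2530L, "-", 1L,
                         junctions = "1200-2500")
  call2 <- identify_active_ltr_promoters(ltr_m, peak_fix,
                                         rbind(body, donor_m, incoming_m))
  expect_false(call2$is_active_promoter)
  expect_equal(call2$n_incoming_junctions, 1L)
})

test_that("transcripts are typed chimera vs ncRNA by annotated acceptors", {
  genes <- data.frame(id = "g1", name = "G1", chrom = "chr1",
                      start = 2000L, end = 8000L, strand = "+",
                      tss = 2000L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", exon_index = 1:3, chrom = "chr1",
                      start = c(2000L, 2600L, 5000L),
                      end = c(2300L, 3000L, 8000L), strand = "+",
                      stringsAsFactors = FALSE)
  full <- rbind(body_reads(6, 1L), body_reads(6, 2L), donor_read(1L))
  call <- identify_active_ltr_promoters(ltr_fix, peak_fix, full)
  ty <- type_transcript(call, ltr_fix, full, genes, exons)
  expect_equal(ty$transcript_type, "chimera")  # acceptor 2600 = exon 2 start
  expect_equal(ty$chimera_gene, "g1")
  expect_equal(ty$chimera_exon, 2L)
  # junction to an unannotated position -> ncRNA
  novel <- rbind(body_reads(6, 1L), body_reads(6, 2L),
                 ltr_read("d1", 1150L, 4030L, "+", 1L,
                          junctions = "1200-4000"))
  call2 <- identify_active_ltr_promoters(ltr_fix, peak_fix, novel)
  expect_equal(type_transcript(call2, ltr_fix, novel, genes,
                               exons)$transcript_type, "ncRNA")
  # acceptor inside an opposite-strand gene's exon -> ncRNA
  genes_m <- genes; genes_m$strand <- "-"; genes_m$tss <- 7999L
  exons_m <- exons; exons_m$strand <- "-"
  expect_equal(type_transcript(call, ltr_fix, full, genes_m,
                               exons_m)$transcript_type, "ncRNA")
})

test_that("on simdata the active set equals the planted set exactly", {
  ds <- small_ds()
  run <- cached("small_run", run_pipeline(ds))
  planted <- ds$truth$ltr_id[ds$truth$is_ltr_promoter]
  expect_setequal(run$ltr$active$ltr_id, planted)
  # decoys all rejected, with the planted failure mode visible
  calls <- run$ltr$calls
  dec <- ds$reference$decoys
  for (i in seq_len(nrow(dec))) {
    row <- calls[calls$ltr_id == dec$ltr_id[i], ]
    expect_false(row$is_active_promoter)
  }
  # chimera targets match the planted partner genes
  tt <- ds$truth[match(run$ltr$active$ltr_id, ds$truth$ltr_id), ]
  expect_equal(run$ltr$active$transcript_type, tt$transcript_type)
  ok <- ifelse(is.na(run$ltr$active$chimera_gene),
               is.na(tt$chimera_gene),
               run$ltr$active$chimera_gene == tt$chimera_gene)
  expect_true(all(ok))
})

test_that("LTR allelic expression flags sparse regions uninformative", {
  ds <- small_ds()
  run <- cached("small_run", run_pipeline(ds))
  expr <- run$ltr$expression[["B6/CAST"]]
  # planted paternal imprints at deep coverage come out paternal
  sig <- expr$bias[expr$bias$significant, ]
  expect_true(all(sig$direction == "paternal"))
  expect_gt(nrow(sig), 0)
  # a region with < 5 assigned reads in every replicate is uninformative
  fake <- list(maternal = NULL, paternal = NULL, unassigned = NULL)
  fake$maternal <- ltr_read("m1", 1010L, 1090L)
  fake$paternal <- ltr_read("p1", 1020L, 1100L)
  calls <- data.frame(ltr_id = "L1", is_active_promoter = TRUE,
                      strand_used = "+", stringsAsFactors = FALSE)
  sparse <- ltr_allelic_expression(calls, ltr_fix, fake, "B6/CAST")
  expect_equal(sparse$uninformative, "L1")
})
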