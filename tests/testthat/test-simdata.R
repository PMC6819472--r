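test_that("config validation rejects bad proportions and parameters", {
  expect_error(sim_config(class_proportions = c(biallelic = 0.5)),
               "sum to 1")
  expect_error(sim_config(allelic_pi = 0.3), "allelic_pi")
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(meth_coverage = 0), "meth_coverage")
})

test_that("planted class counts follow the configured proportions", {
  cfg <- small_config()
  truth <- small_ds()$truth
  expect_equal(nrow(truth), cfg$n_peaks)
  counts <- table(truth$class)
  expect_equal(as.integer(counts["biallelic"]), 84L)   # 0.7 * 120
  expect_equal(sum(truth$class == "imprinted_noncanonical"), 4L)  # 0.03*120

  cfg1 <- sim_config(seed = 3, n_chrom = 2, chrom_length = 2e6,
                     n_peaks = 100,
                     class_proportions = c(biallelic = 1.0),
                     n_background_ltrs = 20L, n_background_cgis = 20L,
                     n_decoys_per_type = 2L)
  ref1 <- simulate_reference(cfg1)
  expect_true(all(ref1$truth$class == "biallelic"))
})

test_that("every non-canonical peak overlaps exactly one ERVK repeat", {
  ref <- small_ref()
  truth <- ref$truth
  nc <- truth[truth$class == "imprinted_noncanonical", ]
  ervk <- ref$repeats[ref$repeats$repeat_family == "ERVK", ]
  for (i in seq_len(nrow(nc))) {
    pk <- ref$peaks[ref$peaks$id == nc$region_id[i], ]
    ov <- overlaps_any0(ervk, pk)
    expect_equal(ervk$id[ov], nc$ltr_id[i])
  }
  # and the LTR sits within 3 kb of the partner gene TSS
  g <- ref$genes[match(nc$gene_id, ref$genes$id), ]
  l <- ervk[match(nc$ltr_id, ervk$id), ]
  d <- pmin(abs(l$start - g$tss), abs(l$end - 1L - g$tss))
  expect_true(all(d <= 3000))
})

test_that("simulation is deterministic given the config", {
  cfg <- small_config()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$chip_counts, b$chip_counts)
  expect_identical(a$rna_reads[["B6/CAST"]]$reads,
                   b$rna_reads[["B6/CAST"]]$reads)
  expect_identical(a$methylation$methyl, b$methylation$methyl)
})

test_that("biallelic counts match the binomial closed form", {
  # depth 200, rho 0: maternal mean over many draws within 3 SD of 100
  cfg <- sim_config(seed = 11, n_peaks = 10000, rho = 0,
                    mean_total_depth = 200,
                    class_proportions = c(biallelic = 1))
  truth <- data.frame(region_id = sprintf("r%05d", 1:10000),
                      class = "biallelic", stringsAsFactors = FALSE)
  cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "B6/CAST")
  cnt1 <- cnt[cnt$replicate == 1, ]
  tot <- cnt1$mat + cnt1$pat
  # E[mat] = tot/2; standardized mean over 10,000 draws ~ N(0, 1/n)
  z <- mean((cnt1$mat - tot / 2) / sqrt(tot * 0.25))
  expect_lt(abs(z), 3 / sqrt(nrow(cnt1)) * sqrt(1) * 3)
  expect_lt(abs(mean(cnt1$mat) - 100), 3 * sqrt(200 * 0.25 / 10000) + 1)
})

test_that("empirical allelic ratio converges to the planted pi", {
  cfg <- sim_config(seed = 12, n_peaks = 4000, rho = 0.02,
                    mean_total_depth = 100,
                    class_proportions = c(imprinted_canonical_maternal = 1))
  truth <- data.frame(region_id = sprintf("r%05d", 1:4000),
                      class = "imprinted_canonical_maternal",
                      stringsAsFactors = FALSE)
  cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "B6/CAST")
  expect_lt(abs(sum(cnt$mat) / sum(cnt$mat + cnt$pat) - 0.9), 0.01)
})

test_that("matDKO reverts canonical maternal imprints but not others", {
  cfg <- sim_config(seed = 13, n_peaks = 3000,
                    class_proportions = c(imprinted_canonical_maternal = 0.5,
                                          imprinted_noncanonical = 0.25,
                                          imprinted_canonical_paternal = 0.25))
  truth <- data.frame(
    region_id = sprintf("r%05d", 1:3000),
    class = rep(c("imprinted_canonical_maternal", "imprinted_noncanonical",
                  "imprinted_canonical_paternal"), length.out = 3000),
    stringsAsFactors = FALSE)
  cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "matDKO/CAST")
  agg <- rowsum(cbind(m = cnt$mat, t = cnt$mat + cnt$pat),
                truth$class[match(cnt$region_id, truth$region_id)])
  ratio <- agg[, "m"] / agg[, "t"]
  expect_lt(abs(ratio["imprinted_canonical_maternal"] - 0.5), 0.01)
  expect_lt(abs(ratio["imprinted_noncanonical"] - 0.1), 0.01)
  expect_lt(abs(ratio["imprinted_canonical_paternal"] - 0.1), 0.01)
})

test_that("allelic_pi = 1 with rho = 0 leaves zero paternal reads", {
  cfg <- sim_config(seed = 14, n_peaks = 500, rho = 0,
                    allelic_pi = 0.999999,
                    class_proportions = c(imprinted_canonical_maternal = 1))
  cfg$allelic_pi <- 1  # boundary: fully mono-allelic
  truth <- data.frame(region_id = sprintf("r%03d", 1:500),
                      class = "imprinted_canonical_maternal",
                      stringsAsFactors = FALSE)
  cnt <- simulate_allelic_chip_counts(NULL, truth, cfg, "B6/CAST")
  expect_true(all(cnt$pat == 0))
})

test_that("snp_rate = 0 leaves every read unassigned downstream", {
  cfg <- sim_config(seed = 15, n_chrom = 1, chrom_length = 2e6,
                    n_peaks = 50, snp_rate = 0, snp_rate_129 = 0,
                    n_background_ltrs = 10L, n_background_cgis = 10L,
                    n_decoys_per_type = 0L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$snps), 0L)
  sim <- simulate_genomic_reads(ref, cfg, "B6/CAST", n_reads = 200)
  parts <- split_reads(sim$reads, ref$snps, "B6/CAST")
  expect_equal(nrow(parts$unassigned), 200L)
})

test_that("planted methylation program hits its target levels", {
  # 10 CpGs at coverage 50, m = 0.8: pooled level within 3 binomial SE
  cfg <- small_config()
  ds <- small_ds()
  meth <- ds$methylation
  nc_ids <- meth$regions$region_id[meth$regions$class == "noncanonical_ltr"]
  m <- meth$methyl
  sel <- m$sample_id == "B6/CAST" & m$stage == "E6.5_ExE" &
    m$allele == "maternal"
  sub <- m[sel, ]
  reg <- meth$regions[meth$regions$class == "noncanonical_ltr", ][1, ]
  in_reg <- sub$chrom == reg$chrom & sub$pos >= reg$start - 500 &
    sub$pos < reg$end + 500
  level <- sum(sub$meth[in_reg]) / sum(sub$meth[in_reg] + sub$unmeth[in_reg])
  n_calls <- sum(sub$meth[in_reg] + sub$unmeth[in_reg])
  expect_lt(abs(level - 0.8), 3 * sqrt(0.8 * 0.2 / n_calls))
  # gametes: both alleles low
  gv <- m[m$sample_id == "B6/CAST" & m$stage == "GV", ]
  in_gv <- gv$chrom == reg$chrom & gv$pos >= reg$start - 500 &
    gv$pos < reg$end + 500
  expect_lt(sum(gv$meth[in_gv]) / sum(gv$meth[in_gv] + gv$unmeth[in_gv]),
            0.25)
})

test_that("matDKO maternal allele at canonical gDMRs is unmethylated", {
  ds <- small_ds()
  meth <- ds$methylation
  gd <- meth$regions[meth$regions$class == "canonical_gdmr" &
                       meth$regions$hyper_allele == "maternal", ][1, ]
  m <- meth$methyl
  sel <- m$sample_id == "matDKO/CAST" & m$stage == "GV" &
    m$allele == "maternal" & m$chrom == gd$chrom &
    m$pos >= gd$start - 500 & m$pos < gd$end + 500
  expect_lt(sum(m$meth[sel]) / sum(m$meth[sel] + m$unmeth[sel]), 0.1)
})
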