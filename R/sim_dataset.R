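#' Simulate a complete reciprocal-hybrid multi-omic dataset
#'
#' Convenience wrapper producing everything the pipeline consumes: the
#' annotation bundle, H3K4me3 allelic counts for both reciprocal crosses
#' plus matDKO/CAST, H3K36me3 allelic counts over genes, RNA-seq reads for
#' both reciprocal crosses, allele-resolved methylation, a sample sheet,
#' and the truth table. Deterministic given the config (including seed).
#'
#' @param config a [sim_config()] object.
#' @param rna logical; also simulate RNA reads (the slowest component).
#' @return a `sim_dataset` list.
#' @export
simulate_dataset <- function(config = sim_config(), rna = TRUE) {
  reference <- simulate_reference(config)
  truth <- reference$truth
  crosses <- c("B6/CAST", "CAST/B6", "matDKO/CAST")
  chip <- do.call(rbind, lapply(crosses, function(cr) {
    simulate_allelic_chip_counts(reference, truth, config, cr)
  }))
  k36 <- do.call(rbind, lapply(c("B6/CAST", "CAST/B6"), function(cr) {
    simulate_allelic_gene_counts(reference, truth, config, cr,
                                 assay = "H3K36me3")
  }))
  rna_reads <- NULL
  if (rna) {
    rna_reads <- lapply(c("B6/CAST", "CAST/B6"), function(cr) {
      simulate_rna_reads(reference, truth, config, cr)
    })
    names(rna_reads) <- c("B6/CAST", "CAST/B6")
  }
  meth <- simulate_methylation(reference, truth, config)
  samples <- sim_sample_sheet(config)
  structure(list(
    config = config,
    reference = reference,
    truth = truth,
    chip_counts = chip,
    k36_counts = k36,
    rna_reads = rna_reads,
    methylation = meth,
    samples = samples
  ), class = "sim_dataset")
}

sim_sample_sheet <- function(config) {
  crosses <- c("B6/CAST", "CAST/B6", "matDKO/CAST")
  rows <- list()
  for (cr in crosses) {
    ms <- cross_maternal_strain(cr)
    ps <- "CAST"
    if (cr == "CAST/B6") { ps <- "B6" }
    for (r in seq_len(config$n_replicates_chip)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = make_sample_id("H3K4me3", "ExE", cr, r),
        maternal_strain = ms, paternal_strain = ps,
        maternal_methylation_intact = cross_maternal_meth_intact(cr),
        tissue = "ExE", assay = "H3K4me3", replicate = r, cross = cr,
        stringsAsFactors = FALSE)
    }
    if (cr != "matDKO/CAST") {
      for (r in seq_len(config$n_replicates_rna)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = make_sample_id("RNA", "ExE", cr, r),
          maternal_strain = ms, paternal_strain = ps,
          maternal_methylation_intact = cross_maternal_meth_intact(cr),
          tissue = "ExE", assay = "RNA", replicate = r, cross = cr,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits exactly the formats the package's readers consume: BED peaks,
#' gene-model TSV, SNP TSVs, repeat TSV, counts TSVs, SAM-lite read TSVs,
#' methylation TSV, sample sheet, and the truth table.
#'
#' @param ds a [simulate_dataset()] bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- ds$reference
  p <- function(f) file.path(dir, f)
  write_bed(ref$peaks, p("peaks.bed"))
  write_gene_table(ref$genes, ref$exons, p("genes.tsv"))
  write_tsv(ref$repeats, p("repeats.tsv"))
  write_tsv(ref$snps, p("snps_b6_cast.tsv"))
  write_tsv(ref$snps_primary, p("snps_b6_cast_excl_shared.tsv"))
  write_tsv(ref$snps_129_cast, p("snps_129_cast.tsv"))
  write_tsv(ds$chip_counts, p("chip_counts.tsv"))
  write_tsv(ds$k36_counts, p("k36_counts.tsv"))
  if (!is.null(ds$rna_reads)) {
    for (cr in names(ds$rna_reads)) {
      write_tsv(ds$rna_reads[[cr]]$reads,
                p(sprintf("rna_reads_%s.tsv", gsub("/", "x", cr))))
    }
  }
  write_tsv(ds$methylation$methyl, p("methylation.tsv"))
  write_tsv(ds$samples, p("samples.tsv"))
  write_tsv(ds$truth, p("truth_table.tsv"))
  invisible(dir)
}
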