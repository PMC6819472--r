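#' Simulation configuration
#'
#' Builds the configuration object for the synthetic reciprocal-hybrid
#' dataset generator. Defaults describe the study conditions every
#' downstream stage is exercised against: 3 autosomes of 10 Mb, 1,000
#' H3K4me3 peaks (70% biallelic, 20% strain-specific, 6% canonical
#' maternal, 1% canonical paternal, 3% non-canonical imprinted), mean peak
#' depth 100 reads per replicate, allelic proportion 0.9 toward the favored
#' allele, beta-binomial overdispersion 0.02, 2 ChIP and 3 RNA replicates,
#' one SNP per 150 bp, and a contiguous 15% 129-derived segment of the
#' matDKO maternal genome.
#'
#' @param seed master integer seed; every output kind draws from its own
#'   stream derived from this value.
#' @param n_chrom number of autosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_peaks number of H3K4me3 peaks.
#' @param class_proportions named numeric summing to 1 over classes
#'   biallelic, strain_B6, strain_CAST, imprinted_canonical_maternal,
#'   imprinted_canonical_paternal, imprinted_noncanonical.
#' @param mean_total_depth Poisson mean of the per-peak per-replicate total
#'   allelically assigned read count.
#' @param allelic_pi allelic proportion toward the favored allele at
#'   non-biallelic regions, in [0.5, 1).
#' @param rho beta-binomial intraclass correlation of the allelic split,
#'   in [0, 1).
#' @param n_replicates_chip,n_replicates_rna biological replicates per
#'   cross and tissue.
#' @param snp_rate per-bp rate of B6/CAST discriminating SNPs.
#' @param snp_rate_129 per-bp rate of 129-only SNPs (B6 = CAST, 129
#'   differs); these drive the second pass of matDKO read assignment.
#' @param shared_cast_frac fraction of B6/CAST SNPs at which the 129 allele
#'   equals the CAST allele (such positions are excluded from the primary
#'   matDKO SNP table).
#' @param fraction_129_segments contiguous fraction of each chromosome that
#'   is 129-derived in the matDKO maternal genome.
#' @param active_fraction_of_noncanonical fraction of non-canonical LTRs
#'   planted as transcriptionally active promoters.
#' @param chimera_fraction fraction of active LTR promoters spliced onto
#'   exon 2 of the partner gene (the rest initiate ncRNAs).
#' @param ltr_length_mean,ltr_length_sd solo-LTR length distribution (bp).
#' @param ltr_same_strand_frac fraction of non-canonical LTRs on the same
#'   strand as the partner gene TSS.
#' @param peak_width peak width in bp.
#' @param gene_length gene length in bp.
#' @param n_background_ltrs ERVK solo LTRs outside peaks (the "mappable"
#'   genome-wide catalog).
#' @param n_background_cgis CpG islands outside peaks.
#' @param n_decoys_per_type decoy LTRs per failure mode (low reads, no
#'   donor junction, incoming upstream junction), planted inside biallelic
#'   peaks.
#' @param rna_gene_depth Poisson mean RNA reads per gene per replicate.
#' @param rna_ltr_depth Poisson mean same-strand RNA reads per active LTR
#'   per replicate.
#' @param meth_coverage Poisson mean bisulfite calls per CpG per allele.
#' @param cg_rate_active,cg_rate_background CpG dinucleotide density of
#'   active-LTR vs background-LTR sequences.
#' @param known_imprint_frac fraction of imprinted-peak genes included in
#'   the known-imprint annotation list.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L,
                       chrom_length = 10e6,
                       n_peaks = 1000L,
                       class_proportions = c(
                         biallelic = 0.70,
                         strain_B6 = 0.10,
                         strain_CAST = 0.10,
                         imprinted_canonical_maternal = 0.06,
                         imprinted_canonical_paternal = 0.01,
                         imprinted_noncanonical = 0.03),
                       mean_total_depth = 100,
                       allelic_pi = 0.9,
                       rho = 0.02,
                       n_replicates_chip = 2L,
                       n_replicates_rna = 3L,
                       snp_rate = 1 / 150,
                       snp_rate_129 = 1 / 450,
                       shared_cast_frac = 0.3,
                       fraction_129_segments = 0.15,
                       active_fraction_of_noncanonical = 0.5,
                       chimera_fraction = 0.6,
                       ltr_length_mean = 417,
                       ltr_length_sd = 60,
                       ltr_same_strand_frac = 0.85,
                       peak_width = 1000L,
                       gene_length = 6000L,
                       n_background_ltrs = 300L,
                       n_background_cgis = 200L,
                       n_decoys_per_type = 5L,
                       rna_gene_depth = 60,
                       rna_ltr_depth = 30,
                       meth_coverage = 30,
                       cg_rate_active = 0.10,
                       cg_rate_background = 0.01,
                       known_imprint_frac = 0.8) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

sim_classes <- c("biallelic", "strain_B6", "strain_CAST",
                 "imprinted_canonical_maternal",
                 "imprinted_canonical_paternal",
                 "imprinted_noncanonical")

#' Validate a simulation configuration
#' @param cfg sim_config list.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (is.null(names(p)) || !all(names(p) %in% sim_classes)) {
    stopf("class_proportions must be named with classes: %s",
          paste(sim_classes, collapse = ", "))
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stopf("class_proportions must sum to 1 (got %.6f)", sum(p))
  }
  if (cfg$allelic_pi < 0.5 || cfg$allelic_pi >= 1) {
    stopf("allelic_pi must be in [0.5, 1)")
  }
  if (cfg$rho < 0 || cfg$rho >= 1) stopf("rho must be in [0, 1)")
  if (cfg$meth_coverage <= 0) stopf("meth_coverage must be positive")
  if (cfg$n_peaks < 1 || cfg$n_chrom < 1) stopf("need >= 1 peak and chromosome")
  invisible(cfg)
}
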