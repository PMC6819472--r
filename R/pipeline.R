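#' Pipeline parameters
#'
#' Thresholds for the end-to-end run, defaulting to the analysis constants:
#' read filters 20 (ChIP) / 5 (RNA) in at least one replicate, alpha 0.05
#' on BH-adjusted p, matDKO lost-bias ratio band [0.35, 0.65], promoter
#' window TSS -1000/+500, nearest-gene cutoff 10 kb, TSS-proximity window
#' 3 kb, methylation flank 500 bp, DMR delta 0.3 / Fisher p 0.05.
#'
#' @param alpha significance level.
#' @param min_reads_chip,min_reads_rna informativeness thresholds.
#' @param ratio_band matDKO allelic-ratio band for "lost bias".
#' @param promoter_up,promoter_down promoter window around the TSS (bp).
#' @param max_gene_distance nearest-gene cutoff (bp).
#' @param tss_window TSS-proximity window (bp).
#' @param meth_flank methylation flank (bp).
#' @param dmr_min_delta,dmr_alpha,dmr_min_calls,dmr_min_cpgs DMR thresholds.
#' @param ltr_min_reads,ltr_min_replicates LTR promoter evidence thresholds.
#' @return a named list of parameters.
#' @export
pipeline_params <- function(alpha = 0.05, min_reads_chip = 20L,
                            min_reads_rna = 5L,
                            ratio_band = c(0.35, 0.65),
                            promoter_up = 1000L, promoter_down = 500L,
                            max_gene_distance = 10000L,
                            tss_window = 3000L, meth_flank = 500L,
                            dmr_min_delta = 0.3, dmr_alpha = 0.05,
                            dmr_min_calls = 10L, dmr_min_cpgs = 5L,
                            ltr_min_reads = 5L, ltr_min_replicates = 2L) {
  p <- as.list(environment())
  stopifnot(all(vapply(p[c("alpha", "min_reads_chip", "min_reads_rna",
                           "max_gene_distance", "tss_window")],
                       function(x) all(x > 0), TRUE)))
  p
}

#' Run the full imprint-discovery pipeline on a simulated dataset
#'
#' Stages, in order: informativeness filtering and overdispersion
#' estimation on the H3K4me3 allelic counts; allelic-bias testing per
#' cross; reciprocal-cross consensus classification; canonical vs
#' non-canonical classification via the matDKO contrast; peak-to-gene
#' assignment and expression cross-validation (H3K36me3 counts and RNA
#' reads passed through allele splitting and exon counting); feature
#' enrichment of non-canonical paternal vs canonical peaks; LTR promoter
#' discovery and transcript typing from the RNA reads; allelic DMR calling
#' and stage dynamics. Deterministic given the dataset.
#'
#' @param ds a [simulate_dataset()] bundle.
#' @param params a [pipeline_params()] list.
#' @return a result bundle (list); see the vignette for a walk-through.
#' @export
run_pipeline <- function(ds, params = pipeline_params()) {
  ref <- ds$reference
  chip <- ds$chip_counts
  crosses <- c("B6/CAST", "CAST/B6")

  # --- allelic bias over peaks -------------------------------------------
  recip <- chip[chip$cross %in% crosses, , drop = FALSE]
  informative <- filter_informative(recip, "chip",
                                    threshold = params$min_reads_chip)
  rho <- mean(vapply(crosses, function(cr) {
    estimate_dispersion(
      recip[recip$cross == cr & recip$region_id %in% informative, ,
            drop = FALSE])$rho
  }, 0))
  bias <- lapply(c(crosses, "matDKO/CAST"), function(cr) {
    d <- chip[chip$cross == cr, , drop = FALSE]
    inf <- if (cr == "matDKO/CAST") {
      filter_informative(d, "chip", threshold = params$min_reads_chip)
    } else informative
    allelic_bias_test(d[d$region_id %in% inf, , drop = FALSE],
                      rho = rho, alpha = params$alpha, cross = cr)
  })
  names(bias) <- c(crosses, "matDKO/CAST")

  # --- classification -----------------------------------------------------
  calls <- classify_reciprocal(bias[["B6/CAST"]], bias[["CAST/B6"]])
  imp <- calls[calls$consensus_class %in% c("imprinted_maternal",
                                            "imprinted_paternal"), ,
               drop = FALSE]
  canonical <- classify_canonical(imp, bias[["matDKO/CAST"]],
                                  gdmr_annotation = ref$gdmr,
                                  regions = ref$peaks,
                                  ratio_band = params$ratio_band)
  gene_map <- assign_peak_to_gene(ref$peaks, ref$genes,
                                  promoter_up = params$promoter_up,
                                  promoter_down = params$promoter_down,
                                  max_distance = params$max_gene_distance)

  # --- expression cross-validation ---------------------------------------
  k36_bias <- list()
  k36_inf <- list()
  for (cr in crosses) {
    d <- ds$k36_counts[ds$k36_counts$cross == cr, , drop = FALSE]
    inf <- filter_informative(d, "chip", threshold = params$min_reads_chip)
    k36_inf[[paste0("H3K36me3_", cr)]] <- inf
    k36_bias[[paste0("H3K36me3_", cr)]] <-
      allelic_bias_test(d[d$region_id %in% inf, , drop = FALSE],
                        rho = rho, alpha = params$alpha, cross = cr)
  }
  rna <- list()
  if (!is.null(ds$rna_reads)) {
    for (cr in names(ds$rna_reads)) {
      parts <- split_reads(ds$rna_reads[[cr]]$reads, ref$snps, cr)
      cnt <- count_over_regions(parts, ref$genes, kind = "gene",
                                exons = ref$exons, cross = cr)
      inf <- filter_informative(cnt, "rna", threshold = params$min_reads_rna)
      rna[[cr]] <- list(
        partitions = parts, counts = cnt, informative = inf,
        bias = allelic_bias_test(cnt[cnt$region_id %in% inf, , drop = FALSE],
                                 rho = rho, alpha = params$alpha, cross = cr))
    }
  }
  aux_bias <- c(k36_bias, lapply(rna, `[[`, "bias"))
  aux_inf <- c(k36_inf, lapply(rna, `[[`, "informative"))
  imp_genes <- data.frame(
    region_id = imp$region_id,
    direction = ifelse(imp$consensus_class == "imprinted_maternal",
                       "maternal", "paternal"),
    gene_id = gene_map$gene_id[match(imp$region_id, gene_map$peak_id)],
    stringsAsFactors = FALSE)
  validation <- if (length(aux_bias) && nrow(imp_genes)) {
    cross_validate_expression(imp_genes, aux_bias, aux_inf)
  }

  # --- feature statistics -------------------------------------------------
  canon_ids <- canonical$region_id[canonical$canonical_status %in%
                                     c("canonical_maternal",
                                       "canonical_paternal")]
  nc_ids <- canonical$region_id[canonical$canonical_status == "non_canonical"]
  nc_pat_ids <- intersect(
    nc_ids, imp$region_id[imp$consensus_class == "imprinted_paternal"])
  features <- NULL
  if (length(nc_pat_ids) >= 2 && length(canon_ids) >= 2) {
    catalogs <- list(
      ERVK_LTR = ref$repeats[ref$repeats$repeat_family == "ERVK", ],
      CGI = ref$cgis,
      LINE = ref$repeats[ref$repeats$repeat_class == "LINE", ])
    features <- feature_overlap_enrichment(
      ref$peaks[ref$peaks$id %in% nc_pat_ids, ],
      ref$peaks[ref$peaks$id %in% canon_ids, ],
      catalogs)
  }

  # --- LTR promoters ------------------------------------------------------
  ltr <- NULL
  if (!is.null(ds$rna_reads)) {
    ltr_catalog <- ref$repeats[ref$repeats$repeat_family == "ERVK", ,
                               drop = FALSE]
    pooled_reads <- do.call(rbind, lapply(ds$rna_reads,
                                          function(x) x$reads))
    promoter_calls <- identify_active_ltr_promoters(
      ltr_catalog, ref$peaks, pooled_reads,
      min_reads = params$ltr_min_reads,
      min_replicates = params$ltr_min_replicates,
      noncanonical_paternal_peaks = nc_pat_ids)
    active <- promoter_calls[promoter_calls$is_active_promoter, ,
                             drop = FALSE]
    types <- lapply(seq_len(nrow(active)), function(i) {
      type_transcript(active[i, ], ltr_catalog, pooled_reads,
                      ref$genes, ref$exons)
    })
    active$transcript_type <- vapply(types, `[[`, "", "transcript_type")
    active$chimera_gene <- vapply(types, function(t) {
      t$chimera_gene %||% NA_character_
    }, "")
    expr <- lapply(names(rna), function(cr) {
      ltr_allelic_expression(active, ltr_catalog, rna[[cr]]$partitions,
                             cross = cr, rho = rho,
                             min_reads = params$min_reads_rna)
    })
    names(expr) <- names(rna)
    ltr <- list(calls = promoter_calls, active = active, expression = expr)
  }

  # --- methylation --------------------------------------------------------
  meth <- NULL
  if (!is.null(ds$methylation) && nrow(ds$methylation$methyl %||%
                                       data.frame()) > 0) {
    regions <- ds$methylation$regions
    regions$id <- regions$region_id
    rmeth <- methylation_at_regions(
      ds$methylation$methyl[ds$methylation$methyl$sample_id == "B6/CAST", ],
      regions, flank = params$meth_flank)
    dmrs <- call_allelic_dmrs(rmeth, min_delta = params$dmr_min_delta,
                              alpha = params$dmr_alpha,
                              min_calls = params$dmr_min_calls,
                              min_cpgs = params$dmr_min_cpgs)
    dyn <- stage_dynamics(rmeth, dmrs)
    meth <- list(region_methylation = rmeth, dmrs = dmrs, dynamics = dyn)
  }

  # --- summary ------------------------------------------------------------
  known_frac <- NA_real_
  if (nrow(imp_genes)) {
    g <- imp_genes$gene_id[!is.na(imp_genes$gene_id)]
    if (length(g)) {
      known_frac <- mean(g %in% ref$known_imprints$gene_id[
        ref$known_imprints$status == "known_imprinted"])
    }
  }
  summary <- list(
    n_informative = length(informative),
    rho = rho,
    class_counts = table(calls$consensus_class),
    canonical_counts = table(canonical$canonical_status),
    known_imprint_fraction = known_frac,
    validation_fraction = if (!is.null(validation)) validation$fraction
                          else NA_real_)

  list(informative = informative, rho = rho, bias = bias, calls = calls,
       canonical = canonical, gene_map = gene_map, rna = rna,
       aux_bias = aux_bias, validation = validation, features = features,
       ltr = ltr, methylation = meth, summary = summary, params = params)
}
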