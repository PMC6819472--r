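## Planted methylation programs (fraction methylated per allele), by region
## class and stage. Stages are ordered gamete -> pre-implantation ->
## post-implantation epiblast / ExE.

sim_stages <- c("GV", "E3.5", "E6.5_epiblast", "E6.5_ExE")

meth_program <- function(class, hyper_allele, stage, maternal_meth_intact) {
  if (class == "noncanonical_ltr") {
    # secondary imprint: unmethylated through pre-implantation, maternal
    # methylation acquired in ExE, bi-allelic methylation in epiblast
    switch(stage,
           GV = c(mat = 0.10, pat = 0.10),
           E3.5 = c(mat = 0.10, pat = 0.10),
           E6.5_epiblast = c(mat = 0.85, pat = 0.85),
           E6.5_ExE = c(mat = 0.80, pat = 0.10))
  } else if (class == "canonical_gdmr") {
    if (hyper_allele == "maternal") {
      m <- if (maternal_meth_intact) 0.85 else 0.02
      c(mat = m, pat = 0.10)
    } else {
      c(mat = 0.10, pat = 0.85)
    }
  } else {
    c(mat = 0.05, pat = 0.05)
  }
}

#' Simulate allele-resolved bisulfite methylation calls
#'
#' Per CpG, allele, stage and cross, the methylated call count is
#' Binomial(coverage, m) with coverage Poisson(`meth_coverage`) and m set
#' by the planted program: non-canonical LTR regions are secondary
#' imprints (both alleles < 0.25 in gametes and pre-implantation, maternal
#' ~0.8 / paternal ~0.1 in ExE, both ~0.85 in epiblast); canonical
#' maternal gDMRs are maternally methylated from the gamete onward in
#' intact crosses and unmethylated on the maternal side in matDKO.
#'
#' @param reference a [simulate_reference()] bundle.
#' @param truth its truth table.
#' @param config the [sim_config()].
#' @param crosses crosses to emit (sample_id = cross string).
#' @param flank bp of flank around each region that carries CpGs.
#' @param cpg_spacing bp between simulated CpGs.
#' @return list with `methyl` (chrom, pos, allele, meth, unmeth, sample_id,
#'   stage) and `regions` (region_id, chrom, start, end, class,
#'   hyper_allele).
#' @export
simulate_methylation <- function(reference, truth, config,
                                 crosses = c("B6/CAST", "matDKO/CAST"),
                                 flank = 500L, cpg_spacing = 25L) {
  if (config$meth_coverage <= 0) stopf("meth_coverage must be positive")
  with_stream(config$seed, "methylation", {
    regions <- meth_region_table(reference, truth)
    if (nrow(regions) == 0) {
      return(list(methyl = data.frame(), regions = regions))
    }
    cpgs <- lapply(seq_len(nrow(regions)), function(i) {
      pos <- seq(max(0L, regions$start[i] - flank),
                 regions$end[i] + flank - 1L, by = cpg_spacing)
      data.frame(region = i, chrom = regions$chrom[i], pos = as.integer(pos))
    })
    cpgs <- do.call(rbind, cpgs)
    out <- list()
    for (cross in crosses) {
      intact <- cross_maternal_meth_intact(cross)
      for (stage in sim_stages) {
        for (al in c("maternal", "paternal")) {
          m <- vapply(cpgs$region, function(i) {
            pr <- meth_program(regions$class[i], regions$hyper_allele[i],
                               stage, intact)
            pr[[if (al == "maternal") "mat" else "pat"]]
          }, 0)
          cov <- rpois(nrow(cpgs), config$meth_coverage)
          meth <- rbinom(nrow(cpgs), cov, m)
          out[[length(out) + 1L]] <- data.frame(
            chrom = cpgs$chrom, pos = cpgs$pos, allele = al,
            meth = meth, unmeth = cov - meth,
            sample_id = cross, stage = stage,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(methyl = do.call(rbind, out), regions = regions)
  })
}

meth_region_table <- function(reference, truth) {
  reps <- reference$repeats
  nc <- truth[truth$class == "imprinted_noncanonical" & !is.na(truth$ltr_id), ]
  nc_ltr <- reps[match(nc$ltr_id, reps$id), , drop = FALSE]
  r1 <- if (nrow(nc)) {
    data.frame(region_id = nc$ltr_id, chrom = nc_ltr$chrom,
               start = nc_ltr$start, end = nc_ltr$end,
               class = "noncanonical_ltr", hyper_allele = "maternal",
               stringsAsFactors = FALSE)
  }
  gd <- reference$gdmr
  r2 <- if (!is.null(gd) && nrow(gd)) {
    data.frame(region_id = gd$region_id, chrom = gd$chrom,
               start = gd$start, end = gd$end,
               class = "canonical_gdmr",
               hyper_allele = ifelse(gd$status == "paternal_gDMR",
                                     "paternal", "maternal"),
               stringsAsFactors = FALSE)
  }
  bg <- reference$cgis[grepl("^cgi_bg", reference$cgis$id), , drop = FALSE]
  bg <- utils::head(bg, 10)
  r3 <- if (nrow(bg)) {
    data.frame(region_id = bg$id, chrom = bg$chrom, start = bg$start,
               end = bg$end, class = "background", hyper_allele = "none",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null), list(r1, r2, r3)))
}
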