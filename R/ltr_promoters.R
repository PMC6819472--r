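## ERVK LTR promoter discovery from spliced RNA evidence. The criteria are
## conjunctive: (a) the LTR lies in an H3K4me3 peak; (b) >= min_reads
## same-strand reads over the LTR in >= min_replicates replicate units
## (each (sample, replicate) is one unit, pooled across tissues); (c) at
## least one junction read whose splice donor lies inside the LTR; (d) no
## junction read splicing INTO the LTR from a 5' donor on the transcript
## strand (true initiation site, not a pass-through exon).

# biological donor/acceptor of genomically stored junctions, by strand
junction_ends <- function(jn, strand) {
  if (strand == "+") {
    list(donor = jn$donor, acceptor = jn$acceptor)
  } else {
    list(donor = jn$acceptor, acceptor = jn$donor)
  }
}

ltr_strand_support <- function(ltr, strand, reads, jn, min_reads,
                               min_replicates) {
  same <- reads$strand == strand
  ov <- same & reads$chrom == ltr$chrom &
    reads$start < ltr$end & reads$end > ltr$start
  unit <- paste(reads$sample_id, reads$replicate)[ov]
  n_pass <- sum(table(unit) >= min_reads)
  jn_same <- jn[same[jn$row] & reads$chrom[jn$row] == ltr$chrom, ,
                drop = FALSE]
  je <- junction_ends(jn_same, strand)
  donor_in <- je$donor >= ltr$start & je$donor < ltr$end
  acceptor_in <- je$acceptor >= ltr$start & je$acceptor < ltr$end
  upstream_donor <- if (strand == "+") {
    je$donor < ltr$start
  } else {
    je$donor >= ltr$end
  }
  list(n_replicates_passing = n_pass,
       n_same_strand_reads = sum(ov),
       n_donor_junctions = sum(donor_in),
       n_incoming_junctions = sum(acceptor_in & upstream_donor))
}

#' Identify transcriptionally active LTR promoters
#'
#' Applies the conjunctive evidence cascade (peak overlap, same-strand read
#' support in multiple replicates, an outgoing splice donor, no incoming
#' upstream junction) to every LTR. Unstranded LTRs are evaluated on both
#' strands and take the better-supported one, flagged `strand_inferred`.
#'
#' @param ltrs LTR repeat data.frame (id, chrom, start, end, strand).
#' @param peaks H3K4me3 peak data.frame (id, chrom, start, end).
#' @param reads stranded RNA read data.frame (possibly pooled across
#'   tissues; each (sample_id, replicate) pair is one replicate unit).
#' @param min_reads same-strand read threshold per replicate unit.
#' @param min_replicates replicate units that must reach `min_reads`.
#' @param noncanonical_paternal_peaks peak ids carrying a non-canonical
#'   paternal imprint, for the imprint_context field.
#' @return LtrPromoterCall data.frame.
#' @export
identify_active_ltr_promoters <- function(ltrs, peaks, reads,
                                          min_reads = 5L,
                                          min_replicates = 2L,
                                          noncanonical_paternal_peaks =
                                            character()) {
  if (any(!reads$strand %in% c("+", "-"))) {
    stopf("RNA reads must be stranded (+ or -)")
  }
  jn <- parse_junctions(reads)
  pk_hit <- GenomicRanges::findOverlaps(as_granges0(ltrs),
                                        as_granges0(peaks),
                                        ignore.strand = TRUE)
  first_pk <- rep(NA_integer_, nrow(ltrs))
  agg <- tapply(S4Vectors::subjectHits(pk_hit),
                S4Vectors::queryHits(pk_hit), min)
  first_pk[as.integer(names(agg))] <- as.integer(agg)
  rows <- lapply(seq_len(nrow(ltrs)), function(i) {
    ltr <- ltrs[i, ]
    pk_i <- first_pk[i]
    in_peak <- !is.na(pk_i)
    strands <- if (ltr$strand %in% c("+", "-")) ltr$strand else c("+", "-")
    sup <- lapply(strands, function(s) {
      ltr_strand_support(ltr, s, reads, jn, min_reads, min_replicates)
    })
    best <- which.max(vapply(sup, `[[`, 0, "n_same_strand_reads"))
    s <- sup[[best]]
    active <- in_peak &&
      s$n_replicates_passing >= min_replicates &&
      s$n_donor_junctions >= 1 &&
      s$n_incoming_junctions == 0
    peak_id <- if (in_peak) peaks$id[pk_i] else NA_character_
    context <- if (!in_peak) {
      "no_peak"
    } else if (peak_id %in% noncanonical_paternal_peaks) {
      "non_canonical_paternal_peak"
    } else "other_peak"
    data.frame(ltr_id = ltr$id, peak_id = peak_id,
               in_h3k4me3_peak = in_peak,
               strand_used = strands[best],
               strand_inferred = length(strands) > 1,
               n_replicates_passing = s$n_replicates_passing,
               n_same_strand_reads = s$n_same_strand_reads,
               n_donor_junctions = s$n_donor_junctions,
               n_incoming_junctions = s$n_incoming_junctions,
               is_active_promoter = active,
               imprint_context = context,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Type the transcript initiated at an active LTR promoter
#'
#' Chimeric mRNA iff at least one junction read links a donor inside the
#' LTR to an annotated exon of a same-strand gene; the target is that gene
#' with the lowest-numbered (transcription order) exon hit. Otherwise the
#' transcript is typed ncRNA.
#'
#' @param call one row of [identify_active_ltr_promoters()] output.
#' @param ltrs LTR repeat data.frame.
#' @param reads stranded RNA read data.frame.
#' @param genes,exons gene models.
#' @return list: transcript_type ("chimera"/"ncRNA"), chimera_gene,
#'   chimera_exon (transcription-order index), or type "none" for an
#'   inactive call.
#' @export
type_transcript <- function(call, ltrs, reads, genes, exons) {
  if (!isTRUE(call$is_active_promoter)) {
    return(list(transcript_type = "none", chimera_gene = NA_character_,
                chimera_exon = NA_integer_))
  }
  ltr <- ltrs[ltrs$id == call$ltr_id, ]
  strand <- call$strand_used
  jn <- parse_junctions(reads)
  same <- reads$strand[jn$row] == strand & reads$chrom[jn$row] == ltr$chrom
  jn <- jn[same, , drop = FALSE]
  je <- junction_ends(jn, strand)
  out <- je$donor >= ltr$start & je$donor < ltr$end
  acceptors <- unique(je$acceptor[out])
  if (!length(acceptors)) {
    return(list(transcript_type = "ncRNA", chimera_gene = NA_character_,
                chimera_exon = NA_integer_))
  }
  exons$tx_index <- exon_tx_index(exons)
  ex <- exons[exons$strand == strand & exons$chrom == ltr$chrom, ,
              drop = FALSE]
  hits <- lapply(acceptors, function(a) {
    which(ex$start <= a & ex$end > a)
  })
  hit_rows <- unique(unlist(hits))
  if (!length(hit_rows)) {
    return(list(transcript_type = "ncRNA", chimera_gene = NA_character_,
                chimera_exon = NA_integer_))
  }
  tx_idx <- ex$tx_index[hit_rows]
  best <- which.min(tx_idx)
  list(transcript_type = "chimera",
       chimera_gene = ex$gene_id[hit_rows[best]],
       chimera_exon = as.integer(tx_idx[best]))
}

#' Allelic expression of active LTR promoters
#'
#' Strand-aware allelic counts over each active LTR from allele-partitioned
#' reads; LTRs with fewer than `min_reads` SNP-spanning (assigned) reads in
#' every replicate are reported uninformative, the rest are tested for
#' allelic bias.
#'
#' @param calls [identify_active_ltr_promoters()] output.
#' @param ltrs LTR repeat data.frame.
#' @param partitions allele partitions from [split_reads()].
#' @param cross cross label.
#' @param rho overdispersion for the bias test.
#' @param min_reads informativeness threshold (RNA default 5).
#' @return list: counts (allelic counts over active LTRs), informative
#'   (ids), bias (BiasResult for informative LTRs).
#' @export
ltr_allelic_expression <- function(calls, ltrs, partitions, cross,
                                   rho = 0, min_reads = 5L) {
  act <- calls[calls$is_active_promoter %in% TRUE, , drop = FALSE]
  regions <- ltrs[match(act$ltr_id, ltrs$id), , drop = FALSE]
  regions$strand <- ifelse(regions$strand %in% c("+", "-"),
                           regions$strand, act$strand_used)
  counts <- count_over_regions(partitions, regions, kind = "ltr",
                               cross = cross)
  informative <- filter_informative(counts, "rna", threshold = min_reads)
  bias <- if (length(informative)) {
    allelic_bias_test(counts[counts$region_id %in% informative, ,
                             drop = FALSE], rho = rho, cross = cross)
  }
  list(counts = counts, informative = informative,
       uninformative = setdiff(act$ltr_id, informative),
       bias = bias)
}
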