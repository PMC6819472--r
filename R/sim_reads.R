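## Read-level simulation. Reads are error-free: the bases observed at SNP
## positions are exactly the haplotype bases of the parental genome the
## read was drawn from (the 129 haplotype inside 129 segments of the
## matDKO maternal genome).

# haplotype base vector over snp_master rows for one parent of a cross
haplotype_bases <- function(snp_master, cross, parent) {
  if (parent == "maternal") {
    switch(cross,
      "B6/CAST" = snp_master$base_b6,
      "CAST/B6" = snp_master$base_cast,
      "matDKO/CAST" = ifelse(snp_master$in_129_segment,
                             snp_master$base_129, snp_master$base_b6),
      stopf("unknown cross '%s'", cross))
  } else {
    switch(cross,
      "B6/CAST" = snp_master$base_cast,
      "CAST/B6" = snp_master$base_b6,
      "matDKO/CAST" = snp_master$base_cast,
      stopf("unknown cross '%s'", cross))
  }
}

# encoded snp_obs strings for reads with a known parental origin
observe_snps <- function(reads, allele, reference, cross) {
  sm <- reference$snp_master
  snp_gr <- GenomicRanges::GRanges(sm$chrom,
                                   IRanges::IRanges(sm$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(as_granges0(reads), snp_gr,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  mat_b <- haplotype_bases(sm, cross, "maternal")
  pat_b <- haplotype_bases(sm, cross, "paternal")
  base <- ifelse(allele[q] == "maternal", mat_b[s], pat_b[s])
  enc <- rep(".", nrow(reads))
  if (length(q)) {
    piece <- paste0(sm$pos[s], ":", base)
    sp <- split(piece, factor(q, levels = seq_len(nrow(reads))))
    nz <- lengths(sp) > 0
    enc[nz] <- vapply(sp[nz], paste, "", collapse = ";")
  }
  enc
}

#' Simulate generic genomic reads with known parental origin
#'
#' Uniformly placed reads, half maternal and half paternal, carrying the
#' haplotype bases of their parent at every overlapped SNP. Used to
#' exercise and oracle-check the allele-assignment stage.
#'
#' @param reference a [simulate_reference()] bundle.
#' @param config the [sim_config()].
#' @param cross cross string.
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @return list with `reads` (read data.frame) and `read_truth`
#'   (read_id, true_allele, from_129_segment).
#' @export
simulate_genomic_reads <- function(reference, config, cross,
                                   n_reads = 2000L, read_length = 80L) {
  with_stream(config$seed, paste("genomicreads", cross), {
    chr <- reference$chromosomes
    ci <- sample.int(nrow(chr), n_reads, replace = TRUE)
    start <- floor(runif(n_reads, 0, chr$length[ci] - read_length))
    allele <- rep(c("maternal", "paternal"), length.out = n_reads)
    reads <- data.frame(
      read_id = sprintf("gr_%06d", seq_len(n_reads)),
      chrom = chr$chrom[ci],
      start = as.integer(start),
      end = as.integer(start + read_length),
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      sample_id = make_sample_id("input", "ExE", cross, 1L),
      replicate = 1L,
      snp_obs = ".",
      junctions = ".",
      stringsAsFactors = FALSE
    )
    reads$snp_obs <- observe_snps(reads, allele, reference, cross)
    seg <- reference$segments_129
    seg_end <- setNames(seg$end, seg$chrom)
    list(reads = reads,
         read_truth = data.frame(
           read_id = reads$read_id,
           true_allele = allele,
           from_129_segment = reads$start < seg_end[reads$chrom],
           stringsAsFactors = FALSE))
  })
}

#' Simulate RNA-seq reads for one cross
#'
#' Generates exonic gene reads whose allelic origin mirrors each gene's
#' planted imprint class, spliced transcripts from every planted active LTR
#' promoter (same-strand reads in the LTR plus donor junctions onto the
#' partner gene's exon 2 for chimeras or a novel downstream exon for
#' ncRNAs), and the three decoy read patterns (too few reads, no donor
#' junction, an incoming upstream junction into the LTR).
#'
#' @inheritParams simulate_genomic_reads
#' @param truth the reference truth table.
#' @param tissue tissue label stamped into sample ids.
#' @return list with `reads` and `read_truth` (read_id, true_allele).
#' @export
simulate_rna_reads <- function(reference, truth, config, cross,
                               tissue = "ExE") {
  if (!cross %in% valid_crosses) stopf("unknown cross '%s'", cross)
  with_stream(config$seed, paste("rna", cross, tissue), {
    parts <- list()
    for (r in seq_len(config$n_replicates_rna)) {
      parts[[length(parts) + 1L]] <- rna_gene_reads(reference, truth, config,
                                                    cross, tissue, r)
      parts[[length(parts) + 1L]] <- rna_ltr_reads(reference, truth, config,
                                                   cross, tissue, r)
      parts[[length(parts) + 1L]] <- rna_decoy_reads(reference, config,
                                                     cross, tissue, r)
    }
    reads <- do.call(rbind, parts)
    reads$read_id <- sprintf("rna_%s_%06d", gsub("/", "x", cross),
                             seq_len(nrow(reads)))
    allele <- reads$allele
    reads$allele <- NULL
    reads$snp_obs <- observe_snps(reads, allele, reference, cross)
    list(reads = reads,
         read_truth = data.frame(read_id = reads$read_id,
                                 true_allele = allele,
                                 stringsAsFactors = FALSE))
  })
}

read_frame <- function(chrom, start, end, strand, sample_id, replicate,
                       allele, junctions = ".") {
  data.frame(read_id = "", chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, sample_id = sample_id,
             replicate = as.integer(replicate), snp_obs = ".",
             junctions = junctions, allele = allele,
             stringsAsFactors = FALSE)
}

rna_gene_reads <- function(reference, truth, config, cross, tissue, r) {
  genes <- reference$genes
  exons <- reference$exons
  rl <- 80L
  n_g <- nrow(genes)
  pi_mat <- class_maternal_pi(truth$class, cross, config$allelic_pi)
  depth <- rpois(n_g, config$rna_gene_depth)
  # replicate-level beta draw gives the overdispersed allelic split
  p_rep <- pi_mat
  if (config$rho > 0) {
    ok <- pi_mat > 0 & pi_mat < 1
    a <- pi_mat[ok] * (1 - config$rho) / config$rho
    b <- (1 - pi_mat[ok]) * (1 - config$rho) / config$rho
    p_rep[ok] <- rbeta(sum(ok), a, b)
  }
  n_mat <- rbinom(n_g, depth, p_rep)
  gene_of_read <- rep(seq_len(n_g), depth)
  is_mat <- unlist(mapply(function(m, d) {
    if (d == 0) return(logical(0))
    sample(rep(c(TRUE, FALSE), c(m, d - m)))
  }, n_mat, depth, SIMPLIFY = FALSE), use.names = FALSE)

  # exon geometry as matrices (3 exons per gene, genomic order)
  es <- matrix(exons$start, ncol = 3, byrow = TRUE)
  ee <- matrix(exons$end, ncol = 3, byrow = TRUE)
  elen <- ee - es
  tot <- rowSums(elen)
  u <- runif(length(gene_of_read)) * tot[gene_of_read]
  g <- gene_of_read
  ex <- 1L + (u > elen[cbind(g, 1)]) +
    (u > elen[cbind(g, 1)] + elen[cbind(g, 2)])
  lo <- es[cbind(g, ex)]
  hi <- pmax(lo + 1L, ee[cbind(g, ex)] - rl)
  start <- as.integer(floor(runif(length(g), lo, hi)))
  end <- pmin(start + rl, ee[cbind(g, ex)])
  read_frame(genes$chrom[g], start, end, genes$strand[g],
             make_sample_id("RNA", tissue, cross, r), r,
             ifelse(is_mat, "maternal", "paternal"))
}

# junction geometry for an LTR transcript; all coordinates genomic
ltr_junction <- function(ltr_strand, ltr_start, ltr_end, acceptor) {
  len <- ltr_end - ltr_start
  donor <- if (ltr_strand == "+") ltr_start + as.integer(round(0.5 * len))
           else ltr_start + as.integer(round(0.5 * len))
  if (ltr_strand == "+") {
    list(start = donor - 50L, end = acceptor + 30L,
         enc = paste0(donor, "-", acceptor))
  } else {
    list(start = acceptor - 30L, end = donor + 50L,
         enc = paste0(acceptor, "-", donor))
  }
}

rna_ltr_reads <- function(reference, truth, config, cross, tissue, r) {
  act <- truth[truth$is_ltr_promoter %in% TRUE, , drop = FALSE]
  if (nrow(act) == 0) return(NULL)
  reps <- reference$repeats
  genes <- reference$genes
  exons <- reference$exons
  out <- vector("list", nrow(act))
  sid <- make_sample_id("RNA", tissue, cross, r)
  for (i in seq_len(nrow(act))) {
    tr <- act[i, ]
    ltr <- reps[reps$id == tr$ltr_id, ]
    pi_mat <- class_maternal_pi(tr$class, cross, config$allelic_pi)
    n_ss <- 5L + rpois(1, config$rna_ltr_depth)
    start <- as.integer(floor(runif(n_ss, ltr$start - 20L, ltr$end - 20L)))
    body <- read_frame(ltr$chrom, start, start + 80L, ltr$strand, sid, r,
                       ifelse(runif(n_ss) < pi_mat, "maternal", "paternal"))
    # splice donors out of the LTR
    if (tr$transcript_type == "chimera") {
      ge <- exons[exons$gene_id == tr$chimera_gene, ]
      ge <- ge[exon_tx_index(ge) == 2L, ]
      acceptor <- if (ltr$strand == "+") ge$start else ge$end - 1L
    } else {
      # novel (unannotated) acceptor in intron 1 of the neighboring gene
      g <- genes[genes$id == tr$gene_id, ]
      acceptor <- if (ltr$strand == "+") g$tss + 1400L else g$tss - 1400L
    }
    n_j <- 2L + rpois(1, 2)
    j <- ltr_junction(ltr$strand, ltr$start, ltr$end, acceptor)
    jn <- read_frame(ltr$chrom, rep(j$start, n_j), rep(j$end, n_j),
                     ltr$strand, sid, r,
                     ifelse(runif(n_j) < pi_mat, "maternal", "paternal"),
                     junctions = j$enc)
    out[[i]] <- rbind(body, jn)
  }
  do.call(rbind, out)
}

rna_decoy_reads <- function(reference, config, cross, tissue, r) {
  dec <- reference$decoys
  if (is.null(dec) || nrow(dec) == 0) return(NULL)
  reps <- reference$repeats
  sid <- make_sample_id("RNA", tissue, cross, r)
  out <- list()
  for (i in seq_len(nrow(dec))) {
    ltr <- reps[reps$id == dec$ltr_id[i], ]
    type <- dec$decoy_type[i]
    len <- ltr$end - ltr$start
    mk_body <- function(n) {
      start <- as.integer(floor(runif(n, ltr$start - 20L, ltr$end - 20L)))
      read_frame(ltr$chrom, start, start + 80L, ltr$strand, sid, r,
                 sample(c("maternal", "paternal"), n, replace = TRUE))
    }
    donor_read <- function() {
      j <- ltr_junction(ltr$strand, ltr$start, ltr$end,
                        if (ltr$strand == "+") ltr$end + 700L
                        else ltr$start - 700L)
      read_frame(ltr$chrom, j$start, j$end, ltr$strand, sid, r,
                 sample(c("maternal", "paternal"), 1), junctions = j$enc)
    }
    blk <- switch(type,
      low_reads = if (r == 1L) rbind(mk_body(3L), donor_read()) else NULL,
      no_donor_junction = mk_body(8L),
      incoming_junction = {
        inside <- ltr$start + as.integer(round(0.3 * len))
        upstream <- if (ltr$strand == "+") {
          list(enc = paste0(ltr$start - 2000L, "-", inside),
               start = ltr$start - 2050L, end = inside + 30L)
        } else {
          list(enc = paste0(inside, "-", ltr$end + 2000L),
               start = inside - 30L, end = ltr$end + 2050L)
        }
        up <- read_frame(ltr$chrom, upstream$start, upstream$end,
                         ltr$strand, sid, r,
                         sample(c("maternal", "paternal"), 1),
                         junctions = upstream$enc)
        if (r == 1L) rbind(mk_body(8L), donor_read(), up)
        else rbind(mk_body(8L), donor_read())
      })
    out[[length(out) + 1L]] <- blk
  }
  if (!length(out)) return(NULL)
  do.call(rbind, Filter(Negate(is.null), out))
}
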