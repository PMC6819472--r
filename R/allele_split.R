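#' Assign reads to parental genomes from SNP observations
#'
#' Implements the three-way sort: a read is called genome1 iff every one of
#' its observed SNP bases matches the genome1 base and it overlaps at least
#' one SNP in the table (symmetrically genome2). A base matching neither
#' genome is a conflict; conflicting or zero informative observations give
#' an unassigned call. Observations at positions absent from the SNP table
#' are ignored.
#'
#' @param reads read data.frame (see [read_reads()]).
#' @param snps SNP table (chrom, pos, base_genome1, base_genome2).
#' @return data.frame: read_id, call (genome1/genome2/unassigned),
#'   n_snps_overlapped, n_matching_g1, n_matching_g2.
#' @export
assign_reads <- function(reads, snps) {
  obs <- parse_snp_obs(reads)
  n <- nrow(reads)
  n_overlap <- integer(n)
  n_g1 <- integer(n)
  n_g2 <- integer(n)
  n_conflict <- integer(n)
  if (nrow(obs) > 0 && nrow(snps) > 0) {
    key_obs <- paste(reads$chrom[obs$row], obs$pos)
    key_snp <- paste(snps$chrom, snps$pos)
    hit <- match(key_obs, key_snp)
    known <- !is.na(hit)
    rows <- obs$row[known]
    b <- obs$base[known]
    g1 <- snps$base_genome1[hit[known]]
    g2 <- snps$base_genome2[hit[known]]
    n_overlap <- tabulate(rows, nbins = n)
    n_g1 <- tabulate(rows[b == g1], nbins = n)
    n_g2 <- tabulate(rows[b == g2], nbins = n)
    n_conflict <- tabulate(rows[b != g1 & b != g2], nbins = n)
  }
  call <- rep("unassigned", n)
  call[n_overlap > 0 & n_g1 == n_overlap] <- "genome1"
  call[n_overlap > 0 & n_g2 == n_overlap] <- "genome2"
  data.frame(read_id = reads$read_id, call = call,
             n_snps_overlapped = n_overlap,
             n_matching_g1 = n_g1, n_matching_g2 = n_g2,
             stringsAsFactors = FALSE)
}

#' Assign a single read (convenience wrapper over [assign_reads()])
#' @param read one-row read data.frame.
#' @param snps SNP table.
#' @return one-row assignment data.frame.
#' @export
assign_read <- function(read, snps) {
  assign_reads(read[1, , drop = FALSE], snps)
}

#' Split reads into maternal / paternal / unassigned partitions
#'
#' Genome calls from [assign_reads()] are relabeled to parental labels via
#' the cross orientation (genome1 = B6, genome2 = CAST; the maternal strain
#' is named first in the cross string).
#'
#' @param reads read data.frame.
#' @param snps SNP table.
#' @param cross cross string, e.g. "B6/CAST".
#' @return list with elements maternal, paternal, unassigned (read
#'   data.frames) and `assignment` (per-read calls with a `parent` column).
#' @export
split_reads <- function(reads, snps, cross) {
  orient <- cross_orientation(cross)
  asg <- assign_reads(reads, snps)
  parent <- rep("unassigned", nrow(asg))
  parent[asg$call == "genome1"] <- orient[["genome1"]]
  parent[asg$call == "genome2"] <- orient[["genome2"]]
  asg$parent <- parent
  list(maternal = reads[parent == "maternal", , drop = FALSE],
       paternal = reads[parent == "paternal", , drop = FALSE],
       unassigned = reads[parent == "unassigned", , drop = FALSE],
       assignment = asg)
}

#' Two-pass maternal assignment for the admixed matDKO maternal genome
#'
#' Pass 1 assigns against the B6/CAST SNP table from which positions where
#' the 129 allele equals the CAST allele have been excluded. Reads left
#' unassigned in pass 1 are re-evaluated against a 129/CAST SNP table;
#' 129-specific calls join the maternal set, and CAST calls from either
#' pass form the paternal set. Reads already assigned in pass 1 are never
#' touched.
#'
#' @param reads read data.frame.
#' @param snps_primary B6/CAST SNP table excluding 129/CAST-shared
#'   positions (genome1 = B6, genome2 = CAST).
#' @param snps_129_cast 129/CAST SNP table (genome1 = 129, genome2 = CAST).
#' @return same shape as [split_reads()], plus a `pass` column in the
#'   assignment (1, 2, or NA for unassigned).
#' @export
two_pass_maternal_assignment <- function(reads, snps_primary, snps_129_cast) {
  if (is.null(snps_129_cast)) stopf("second (129/CAST) SNP table is required")
  pass1 <- assign_reads(reads, snps_primary)
  parent <- rep("unassigned", nrow(reads))
  parent[pass1$call == "genome1"] <- "maternal"
  parent[pass1$call == "genome2"] <- "paternal"
  pass <- ifelse(parent == "unassigned", NA_integer_, 1L)

  todo <- which(parent == "unassigned")
  if (length(todo)) {
    pass2 <- assign_reads(reads[todo, , drop = FALSE], snps_129_cast)
    parent[todo[pass2$call == "genome1"]] <- "maternal"
    parent[todo[pass2$call == "genome2"]] <- "paternal"
    pass[todo[pass2$call != "unassigned"]] <- 2L
  }
  asg <- data.frame(read_id = reads$read_id, parent = parent, pass = pass,
                    stringsAsFactors = FALSE)
  list(maternal = reads[parent == "maternal", , drop = FALSE],
       paternal = reads[parent == "paternal", , drop = FALSE],
       unassigned = reads[parent == "unassigned", , drop = FALSE],
       assignment = asg)
}
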