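#' Consensus classification from the reciprocal crosses
#'
#' Combines per-cross bias results on the same region set. Significant in
#' both crosses with the same parental direction -> imprinted (maternal or
#' paternal); significant in both with the same strain direction (the
#' allelic skew switches parent between reciprocal crosses) ->
#' strain-specific; significant in exactly one -> single_cross_only
#' (excluded from the consensus); neither -> biallelic. Regions missing
#' from either cross come back unresolved.
#'
#' @param bias_cross1 BiasResult data.frame for the cross with maternal
#'   B6 (B6/CAST).
#' @param bias_cross2 BiasResult data.frame for the reciprocal cross
#'   (CAST/B6, maternal CAST).
#' @return data.frame: region_id, consensus_class, direction_cross1,
#'   direction_cross2.
#' @export
classify_reciprocal <- function(bias_cross1, bias_cross2) {
  ids <- sort(union(bias_cross1$region_id, bias_cross2$region_id))
  i1 <- match(ids, bias_cross1$region_id)
  i2 <- match(ids, bias_cross2$region_id)
  d1 <- bias_cross1$direction[i1]
  d2 <- bias_cross2$direction[i2]
  s1 <- bias_cross1$significant[i1] %in% TRUE
  s2 <- bias_cross2$significant[i2] %in% TRUE

  cls <- rep("biallelic", length(ids))
  cls[is.na(i1) | is.na(i2)] <- "unresolved"
  one <- xor(s1, s2) & !is.na(i1) & !is.na(i2)
  cls[one] <- "single_cross_only"
  both <- s1 & s2 & !is.na(i1) & !is.na(i2)
  same_parent <- both & d1 == d2
  cls[same_parent & d1 == "maternal"] <- "imprinted_maternal"
  cls[same_parent & d1 == "paternal"] <- "imprinted_paternal"
  # direction switches with the cross: the favored strain is fixed.
  # cross1 maternal = B6, so maternal-in-1 + paternal-in-2 = B6-specific.
  switched <- both & d1 != d2
  cls[switched & d1 == "maternal"] <- "strain_B6"
  cls[switched & d1 == "paternal"] <- "strain_CAST"
  data.frame(region_id = ids, consensus_class = cls,
             direction_cross1 = d1, direction_cross2 = d2,
             stringsAsFactors = FALSE)
}

#' Canonical vs non-canonical classification via the matDKO contrast
#'
#' Imprinted regions that lose allelic bias when maternally inherited DNA
#' methylation is ablated (not significant in matDKO/CAST AND matDKO
#' allelic ratio inside `ratio_band`) are canonical maternal imprints.
#' Regions that remain imprinted in the same parental direction are
#' canonical paternal imprints if they overlap a known paternal gDMR, and
#' non-canonical imprints otherwise. Anything undecidable (missing or
#' underpowered matDKO data, direction flips, non-significance with a
#' ratio outside the band) is unresolved, never dropped.
#'
#' @param calls output of [classify_reciprocal()]; only imprinted regions
#'   are accepted.
#' @param bias_matdko BiasResult data.frame for matDKO/CAST.
#' @param gdmr_annotation data.frame of known paternal-gDMR regions with a
#'   region_id and/or interval columns; matched by region_id against the
#'   call ids, or by >= 1 bp overlap when `regions` is supplied.
#' @param regions optional interval data.frame (id, chrom, start, end)
#'   locating the called regions, enabling interval overlap with the gDMR
#'   annotation.
#' @param ratio_band matDKO allelic-ratio band treated as "lost bias".
#' @return data.frame: region_id, canonical_status, matdko_ratio, matdko_q.
#' @export
classify_canonical <- function(calls, bias_matdko, gdmr_annotation = NULL,
                               regions = NULL,
                               ratio_band = c(0.35, 0.65)) {
  imp <- calls$consensus_class %in% c("imprinted_maternal",
                                      "imprinted_paternal")
  if (!all(imp)) {
    stopf("classify_canonical expects only imprinted regions (got %s)",
          paste(unique(calls$consensus_class[!imp]), collapse = ", "))
  }
  idx <- match(calls$region_id, bias_matdko$region_id)
  ratio <- bias_matdko$ratio[idx]
  qv <- bias_matdko$q[idx]
  sig <- bias_matdko$significant[idx] %in% TRUE
  dir_dko <- bias_matdko$direction[idx]
  parent_dir <- ifelse(calls$consensus_class == "imprinted_maternal",
                       "maternal", "paternal")

  pat_gdmr <- rep(FALSE, nrow(calls))
  if (!is.null(gdmr_annotation) && nrow(gdmr_annotation)) {
    g <- gdmr_annotation[gdmr_annotation$status %in% "paternal_gDMR", ,
                         drop = FALSE]
    if ("region_id" %in% names(g)) {
      pat_gdmr <- calls$region_id %in% g$region_id
    }
    if (!is.null(regions) && all(c("chrom", "start", "end") %in% names(g))) {
      loc <- regions[match(calls$region_id, regions$id), , drop = FALSE]
      ok <- !is.na(loc$chrom)
      pat_gdmr[ok] <- pat_gdmr[ok] | overlaps_any0(loc[ok, , drop = FALSE], g)
    }
  }

  status <- rep("unresolved", nrow(calls))
  missing <- is.na(idx) | is.na(ratio)
  lost <- !missing & !sig & ratio >= ratio_band[1] & ratio <= ratio_band[2]
  status[lost] <- "canonical_maternal"
  retained <- !missing & sig & dir_dko == parent_dir
  status[retained & pat_gdmr] <- "canonical_paternal"
  status[retained & !pat_gdmr] <- "non_canonical"
  data.frame(region_id = calls$region_id, canonical_status = status,
             matdko_ratio = ratio, matdko_q = qv,
             stringsAsFactors = FALSE)
}

#' Assign a peak to a gene via promoter overlap or proximity
#'
#' A peak overlapping one or more promoters (TSS - `promoter_up` to
#' TSS + `promoter_down`, strand-oriented) reports all overlapped promoter
#' genes; otherwise the nearest gene body within `max_distance` bp; else
#' none. Nearest-gene ties break by smaller distance, then lexicographic
#' gene id.
#'
#' @param peaks peak data.frame (id, chrom, start, end).
#' @param genes gene data.frame (id, chrom, start, end, strand, tss).
#' @param promoter_up,promoter_down promoter window around the TSS in bp.
#' @param max_distance maximum peak-to-gene distance in bp.
#' @return data.frame: peak_id, gene_id (NA when none), promoter_overlap,
#'   distance; one row per (peak, assigned gene).
#' @export
assign_peak_to_gene <- function(peaks, genes, promoter_up = 1000L,
                                promoter_down = 500L, max_distance = 10000L) {
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0L, ifelse(genes$strand == "+", genes$tss - promoter_up,
                            genes$tss - promoter_down + 1L)),
    end = ifelse(genes$strand == "+", genes$tss + promoter_down + 1L,
                 genes$tss + promoter_up + 1L),
    stringsAsFactors = FALSE
  )
  pk_gr <- as_granges0(peaks)
  hit <- GenomicRanges::findOverlaps(pk_gr, as_granges0(prom),
                                     ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  rows <- list()
  if (length(qh)) {
    rows[[1]] <- data.frame(peak_id = peaks$id[qh], gene_id = genes$id[sh],
                            promoter_overlap = TRUE, distance = 0L,
                            stringsAsFactors = FALSE)
  }
  no_prom <- setdiff(seq_len(nrow(peaks)), unique(qh))
  if (length(no_prom)) {
    gene_gr <- as_granges0(genes)
    # explicit scan so equal-distance ties break by lexicographic gene id
    qn <- integer(); gid <- character(); dn <- integer()
    for (k in seq_along(no_prom)) {
      d_all <- suppressWarnings(
        GenomicRanges::distance(pk_gr[no_prom[k]], gene_gr,
                                ignore.strand = TRUE))
      if (all(is.na(d_all))) next
      dmin <- min(d_all, na.rm = TRUE)
      cand <- which(!is.na(d_all) & d_all == dmin)
      qn <- c(qn, k)
      gid <- c(gid, sort(genes$id[cand])[1])
      dn <- c(dn, dmin)
    }
    keep <- dn <= max_distance
    assigned <- data.frame(peak_id = peaks$id[no_prom[qn[keep]]],
                           gene_id = gid[keep],
                           promoter_overlap = FALSE,
                           distance = as.integer(dn[keep]),
                           stringsAsFactors = FALSE)
    unfound <- setdiff(no_prom, no_prom[qn[keep]])
    rows[[length(rows) + 1L]] <- assigned
    if (length(unfound)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$id[unfound], gene_id = NA_character_,
        promoter_overlap = FALSE, distance = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$peak_id, peaks$id), out$gene_id), , drop = FALSE]
}

#' Cross-validate imprinted peaks against expression-type datasets
#'
#' A gene associated with an imprinted peak is validated iff it shows a
#' significant allelic bias in the same parental direction in at least one
#' informative auxiliary dataset (H3K36me3 or RNA-seq bias results). Genes
#' uninformative in all datasets are excluded from the denominator.
#'
#' @param imprinted data.frame with peak region_id, direction ("maternal"
#'   or "paternal") and gene_id.
#' @param aux_bias named list of BiasResult data.frames over genes.
#' @param aux_informative named list (parallel to `aux_bias`) of character
#'   vectors of informative gene ids (from [filter_informative()]).
#' @return list: per_gene data.frame (gene_id, direction, informative,
#'   validated) and `fraction` = validated / informative.
#' @export
cross_validate_expression <- function(imprinted, aux_bias,
                                      aux_informative = NULL) {
  if (length(aux_bias) == 0) stopf("no auxiliary datasets supplied")
  genes <- imprinted[!is.na(imprinted$gene_id), , drop = FALSE]
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  informative <- rep(FALSE, nrow(genes))
  validated <- rep(FALSE, nrow(genes))
  for (k in seq_along(aux_bias)) {
    b <- aux_bias[[k]]
    inf_ids <- if (!is.null(aux_informative)) {
      aux_informative[[k]]
    } else b$region_id
    idx <- match(genes$gene_id, b$region_id)
    is_inf <- genes$gene_id %in% inf_ids & !is.na(idx)
    informative <- informative | is_inf
    ok <- is_inf & b$significant[idx] %in% TRUE &
      b$direction[idx] == genes$direction
    validated <- validated | ok
  }
  per_gene <- data.frame(gene_id = genes$gene_id,
                         direction = genes$direction,
                         informative = informative, validated = validated,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       n_informative = sum(informative),
       n_validated = sum(validated & informative),
       fraction = if (sum(informative) > 0) {
         sum(validated & informative) / sum(informative)
       } else NA_real_)
}
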