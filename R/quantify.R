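#' Merge and de-duplicate peak sets from two crosses
#'
#' Peaks overlapping by at least 1 bp are merged into their union interval
#' with a new stable id; non-overlapping peaks pass through. Both sets must
#' come from the same tissue and mark.
#'
#' @param peaks_cross1,peaks_cross2 peak data.frames (chrom, start, end,
#'   with optional mark/tissue columns).
#' @return consensus peak data.frame, sorted, with ids `cons_0001`, ...
#' @export
merge_peak_sets <- function(peaks_cross1, peaks_cross2) {
  for (col in c("tissue", "mark")) {
    if (col %in% names(peaks_cross1) && col %in% names(peaks_cross2)) {
      vals <- unique(c(peaks_cross1[[col]], peaks_cross2[[col]]))
      if (length(vals) > 1) {
        stopf("cannot merge peak sets with mixed %s values: %s", col,
              paste(vals, collapse = ", "))
      }
    }
  }
  combined <- rbind(peaks_cross1[, c("chrom", "start", "end")],
                    peaks_cross2[, c("chrom", "start", "end")])
  validate_intervals(combined, "peak set")
  gr <- GenomicRanges::reduce(as_granges0(combined), min.gapwidth = 0L,
                              ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr)
  out <- granges0_as_df(gr)
  out$id <- sprintf("cons_%04d", seq_len(nrow(out)))
  if ("mark" %in% names(peaks_cross1)) out$mark <- peaks_cross1$mark[1]
  if ("tissue" %in% names(peaks_cross1)) out$tissue <- peaks_cross1$tissue[1]
  out[, c("id", "chrom", "start", "end", "strand",
          intersect(c("mark", "tissue"), names(out)))]
}

# midpoint of a 0-based half-open read interval
read_midpoint <- function(reads) (reads$start + reads$end - 1L) %/% 2L

count_partition <- function(reads, regions, kind, exons) {
  n_reg <- nrow(regions)
  if (is.null(reads) || nrow(reads) == 0) {
    return(cbind(region = integer(), sample_idx = integer()))
  }
  mid <- read_midpoint(reads)
  mid_gr <- GenomicRanges::GRanges(reads$chrom,
                                   IRanges::IRanges(mid + 1L, width = 1L))
  if (kind == "gene") {
    if (is.null(exons)) stopf("gene counting requires the exon table")
    tgt <- as_granges0(exons)
    tgt_region <- match(exons$gene_id, regions$id)
  } else {
    tgt <- as_granges0(regions)
    tgt_region <- seq_len(n_reg)
  }
  hits <- GenomicRanges::findOverlaps(mid_gr, tgt, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (kind == "ltr") {
    keep <- reads$strand[q] == regions$strand[tgt_region[s]]
    q <- q[keep]; s <- s[keep]
  }
  pair <- unique(cbind(read = q, region = tgt_region[s]))
  pair
}

#' Count allele-partitioned reads over regions
#'
#' A read counts once per overlapped region by the midpoint rule (its
#' midpoint must lie inside the region; for genes, inside an exon of the
#' gene). Counting is strand-aware when `kind = "ltr"` (read strand must
#' equal the region strand).
#'
#' @param partitions list with maternal/paternal/unassigned read
#'   data.frames (as returned by [split_reads()]).
#' @param regions region data.frame with an `id` column (and `strand` for
#'   kind "ltr").
#' @param kind one of "peak", "gene", "window", "ltr".
#' @param exons exon table, required for kind "gene".
#' @param cross optional cross label stamped into the output.
#' @return allelic counts data.frame over all (region, sample, replicate)
#'   combinations present in the reads.
#' @export
count_over_regions <- function(partitions, regions,
                               kind = c("peak", "gene", "window", "ltr"),
                               exons = NULL, cross = NA_character_) {
  kind <- match.arg(kind)
  check_cols(regions, "id", "region table")
  all_reads <- rbind(partitions$maternal, partitions$paternal,
                     partitions$unassigned)
  samp <- unique(all_reads[, c("sample_id", "replicate")])
  if (nrow(samp) == 0) {
    samp <- data.frame(sample_id = character(), replicate = integer())
  }
  grid_key <- function(region_idx, reads, pair) {
    si <- match(paste(reads$sample_id, reads$replicate),
                paste(samp$sample_id, samp$replicate))
    tab <- table(factor(pair[, "region"], levels = seq_len(nrow(regions))),
                 factor(si[pair[, "read"]], levels = seq_len(nrow(samp))))
    as.vector(tab)
  }
  out <- expand.grid(region = seq_len(nrow(regions)),
                     sample = seq_len(nrow(samp)))
  for (part in c("maternal", "paternal", "unassigned")) {
    reads <- partitions[[part]]
    pair <- count_partition(reads, regions, kind, exons)
    col <- c(maternal = "mat", paternal = "pat", unassigned = "unassigned")[part]
    out[[col]] <- if (is.null(reads) || nrow(reads) == 0) {
      0L
    } else grid_key(seq_len(nrow(regions)), reads, pair)
  }
  data.frame(region_id = regions$id[out$region],
             sample_id = samp$sample_id[out$sample],
             replicate = samp$replicate[out$sample],
             mat = as.integer(out$mat), pat = as.integer(out$pat),
             unassigned = as.integer(out$unassigned),
             kind = kind, cross = cross,
             stringsAsFactors = FALSE)
}

#' Informativeness filter on allelic counts
#'
#' A region is retained iff mat + pat reaches the threshold in at least one
#' allelically mapped biological replicate of any supplied sample: 20 for
#' ChIP-type assays, 5 for RNA (configurable). Unassigned reads never count
#' toward the threshold.
#'
#' @param counts allelic counts data.frame.
#' @param assay "chip" or "rna".
#' @param threshold override of the assay default.
#' @return character vector of retained region ids.
#' @export
filter_informative <- function(counts, assay = c("chip", "rna"),
                               threshold = NULL) {
  assay <- match.arg(assay)
  thr <- threshold %||% switch(assay, chip = 20L, rna = 5L)
  ok <- counts$mat + counts$pat >= thr
  sort(unique(counts$region_id[ok]))
}

#' Median-of-ratios size-factor normalization
#'
#' Size factors are the per-sample median ratio to the geometric-mean
#' pseudo-reference, computed on autosomal regions positive in every
#' sample. Sex and mitochondrial chromosome regions are scaled but never
#' used for factor estimation. Falls back to total-count ratios (with a
#' warning) when no region is positive in all samples.
#'
#' @param mat numeric matrix, regions x samples.
#' @param chrom chromosome of each region (default: all autosomal).
#' @return list with `factors` (length = ncol) and `normalized`
#'   (mat scaled by 1/factor per sample).
#' @export
size_factor_normalize <- function(mat, chrom = rep("autosome", nrow(mat))) {
  if (ncol(mat) < 2) stopf("size-factor normalization needs >= 2 samples")
  sex_mt <- c("chrX", "X", "chrY", "Y", "chrM", "M", "chrMT", "MT")
  use <- !(chrom %in% sex_mt)
  sub <- mat[use, , drop = FALSE]
  all_pos <- rowSums(sub > 0) == ncol(sub)
  if (any(all_pos)) {
    logs <- log(sub[all_pos, , drop = FALSE])
    ref <- rowMeans(logs)
    factors <- apply(exp(logs - ref), 2, median)
  } else {
    warnf("no autosomal region positive in all samples; using total-count ratios")
    tot <- colSums(sub)
    factors <- tot / exp(mean(log(tot)))
  }
  list(factors = factors,
       normalized = sweep(mat, 2, factors, "/"))
}

#' Running-window RPKM track
#'
#' Tiles each chromosome with windows of `width` every `step` bp and counts
#' read midpoints per window, scaled to reads per kilobase per million
#' mapped reads.
#'
#' @param reads read data.frame (only chrom/start/end are used).
#' @param chromosomes data.frame with chrom, length.
#' @param width,step window width and step in bp (width >= step > 0).
#' @param library_size total mapped reads for the RPKM denominator
#'   (default: nrow(reads)).
#' @return track data.frame: chrom, start, end, value (RPKM).
#' @export
running_windows <- function(reads, chromosomes, width = 1000L, step = 100L,
                            library_size = nrow(reads)) {
  if (!(width >= step && step > 0)) stopf("need width >= step > 0")
  if (is.null(library_size) || library_size <= 0) {
    stopf("empty library: library_size must be positive")
  }
  wins <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    L <- chromosomes$length[i]
    if (L < width) return(NULL)
    starts <- seq(0L, L - width, by = step)
    data.frame(chrom = chromosomes$chrom[i], start = as.integer(starts),
               end = as.integer(starts + width), stringsAsFactors = FALSE)
  }))
  counts <- integer(nrow(wins))
  if (nrow(reads) > 0) {
    mid <- read_midpoint(reads)
    mid_gr <- GenomicRanges::GRanges(reads$chrom,
                                     IRanges::IRanges(mid + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(mid_gr, as_granges0(wins),
                                        ignore.strand = TRUE)
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(wins))
  }
  wins$value <- counts / (library_size / 1e6) / (width / 1000)
  wins
}

#' Average replicate tracks for display
#' @param tracks list of track data.frames over identical windows.
#' @return one track with the mean value per window.
#' @export
average_tracks <- function(tracks) {
  out <- tracks[[1]]
  vals <- vapply(tracks, function(t) t$value, numeric(nrow(out)))
  out$value <- rowMeans(as.matrix(vals))
  out
}

#' Percentile enrichment normalization for display
#'
#' Anchors the 40th percentile of the non-zero values (unenriched baseline)
#' at 0 and the 99th percentile (highly enriched) at 1 by the affine map
#' x' = (x - P40) / (P99 - P40). No clipping, so relative enrichment and
#' rank order are preserved.
#'
#' @param values numeric vector of track values.
#' @return rescaled numeric vector.
#' @export
enrichment_normalize <- function(values) {
  nz <- values[values != 0 & !is.na(values)]
  if (length(unique(nz)) < 2) {
    stopf("degenerate track: need >= 2 distinct non-zero values")
  }
  p <- quantile(nz, c(0.40, 0.99), names = FALSE, type = 7)
  if (p[2] == p[1]) stopf("degenerate track: P99 equals P40")
  (values - p[1]) / (p[2] - p[1])
}
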