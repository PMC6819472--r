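## Genomic-feature statistics over peak/LTR sets. All chi-square statistics
## are the closed-form Pearson sum((O - E)^2 / E) without continuity
## correction unless a Yates flag is set.

#' Pearson chi-square on a contingency table
#' @param tab integer matrix (observed counts).
#' @param yates apply the Yates continuity correction (2x2 only).
#' @return list: chi2, df, p, expected, min_expected.
#' @export
chisq_stat <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(chi2 = 0, df = 0L, p = 1, expected = tab,
                min_expected = suppressWarnings(min(tab))))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (yates) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected = E, min_expected = min(E))
}

#' Feature-overlap enrichment between two peak sets
#'
#' For each feature catalog, compares the fraction of set A vs set B peaks
#' overlapping the feature (>= 1 bp) by Pearson chi-square (df = 1, no
#' continuity correction), Bonferroni-corrected over the number of
#' features tested. Rows with any expected cell below 1 carry a warning
#' flag.
#'
#' @param set_a,set_b disjoint peak data.frames (chrom, start, end).
#' @param feature_catalogs named list of interval data.frames.
#' @param alpha significance level on the Bonferroni-corrected p.
#' @param yates apply Yates correction.
#' @return EnrichmentRow data.frame: feature, fraction_set_a,
#'   fraction_set_b, chi2, p, p_bonferroni, significant, low_expected.
#' @export
feature_overlap_enrichment <- function(set_a, set_b, feature_catalogs,
                                       alpha = 0.05, yates = FALSE) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) stopf("empty peak set")
  if (length(feature_catalogs) < 2) stopf("need >= 2 feature categories")
  n_feat <- length(feature_catalogs)
  rows <- lapply(names(feature_catalogs), function(f) {
    cat <- feature_catalogs[[f]]
    a_hit <- sum(overlaps_any0(set_a, cat))
    b_hit <- sum(overlaps_any0(set_b, cat))
    tab <- rbind(c(a_hit, nrow(set_a) - a_hit),
                 c(b_hit, nrow(set_b) - b_hit))
    cs <- chisq_stat(tab, yates = yates)
    data.frame(feature = f,
               fraction_set_a = a_hit / nrow(set_a),
               fraction_set_b = b_hit / nrow(set_b),
               chi2 = cs$chi2, p = cs$p,
               p_bonferroni = min(1, cs$p * n_feat),
               low_expected = cs$min_expected < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' CpG dinucleotide density per interval, with a group comparison
#'
#' Density is (# CG dinucleotides) / (length - 1), from supplied sequences
#' or precomputed CG tallies. The two-group comparison delegates to
#' [location_tests()] (Welch two-sample t).
#'
#' @param intervals interval data.frame with an `id` column.
#' @param sequences named character vector of sequences (names = interval
#'   ids), or NULL if `cg_counts` given.
#' @param cg_counts named numeric vector of precomputed CG dinucleotide
#'   tallies.
#' @param groups optional factor/character vector (two levels) per
#'   interval; triggers the Welch comparison.
#' @return list: per_interval data.frame (id, length, cg, density) and
#'   `comparison` (Welch test list or NULL). Intervals shorter than 2 bp
#'   are skipped.
#' @export
cpg_content <- function(intervals, sequences = NULL, cg_counts = NULL,
                        groups = NULL) {
  check_cols(intervals, c("id", "start", "end"), "intervals")
  len <- intervals$end - intervals$start
  keep <- len >= 2
  ids <- intervals$id[keep]
  len <- len[keep]
  cg <- if (!is.null(sequences)) {
    vapply(sequences[ids], count_cg, 0)
  } else if (!is.null(cg_counts)) {
    as.numeric(cg_counts[ids])
  } else {
    stopf("supply sequences or cg_counts")
  }
  per <- data.frame(id = ids, length = len, cg = cg,
                    density = cg / (len - 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  comparison <- NULL
  if (!is.null(groups)) {
    g <- groups[keep]
    lv <- unique(g)
    if (length(lv) != 2) stopf("groups must have exactly 2 levels")
    comparison <- location_tests(per$density[g == lv[1]],
                                 per$density[g == lv[2]],
                                 kind = "welch_two_sample")
    comparison$groups <- lv
  }
  list(per_interval = per, comparison = comparison)
}

count_cg <- function(seq) {
  if (is.na(seq)) return(NA_real_)
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) 0 else length(m)
}

#' TSS proximity and strand concordance of LTRs
#'
#' Classifies each LTR by its distance to the nearest gene TSS (minimum
#' |LTR boundary - TSS|, 0 when the TSS falls inside the LTR) and the
#' strand of that nearest TSS relative to the LTR: same strand within
#' `window`, opposing strand within `window`, or beyond. A background set
#' gives a 2x3 chi-square comparison.
#'
#' @param ltrs stranded interval data.frame (id, chrom, start, end, strand).
#' @param genes gene data.frame with tss and strand.
#' @param background optional background LTR data.frame for the comparison.
#' @param window proximity cutoff in bp.
#' @return list: per_ltr (id, distance, category), proportions, and (with
#'   background) `background_proportions`, chi2, p.
#' @export
tss_proximity <- function(ltrs, genes, background = NULL, window = 3000L) {
  if (nrow(genes) == 0) stopf("no genes supplied")
  categorize <- function(set) {
    d_start <- outer(set$start, genes$tss, function(a, b) abs(a - b))
    d_end <- outer(set$end - 1L, genes$tss, function(a, b) abs(a - b))
    inside <- outer(set$start, genes$tss, `<=`) &
      outer(set$end, genes$tss, `>`)
    same_chr <- outer(set$chrom, genes$chrom, `==`)
    d <- pmin(d_start, d_end)
    d[inside] <- 0L
    d[!same_chr] <- NA_integer_
    nearest <- apply(d, 1, function(r) {
      if (all(is.na(r))) NA_integer_ else which.min(r)
    })
    dist <- d[cbind(seq_len(nrow(set)), nearest)]
    cat <- ifelse(is.na(dist) | dist > window, "beyond",
                  ifelse(genes$strand[nearest] == set$strand,
                         "same_strand", "opposing_strand"))
    data.frame(id = set$id, distance = dist, category = cat,
               stringsAsFactors = FALSE)
  }
  lev <- c("same_strand", "opposing_strand", "beyond")
  fg <- categorize(ltrs)
  out <- list(per_ltr = fg,
              proportions = prop.table(table(factor(fg$category, lev))))
  if (!is.null(background)) {
    bg <- categorize(background)
    tab <- rbind(table(factor(fg$category, lev)),
                 table(factor(bg$category, lev)))
    keep <- colSums(tab) > 0
    cs <- chisq_stat(tab[, keep, drop = FALSE])
    out$background_proportions <- prop.table(table(factor(bg$category, lev)))
    out$chi2 <- cs$chi2
    out$p <- cs$p
  }
  out
}

#' Length and solo-fraction summary of an LTR set
#'
#' @param ltrs repeat data.frame with start, end and is_solo.
#' @return list: n, mean_length, sem_length (NA for a single element),
#'   solo_fraction.
#' @export
solo_ltr_stats <- function(ltrs) {
  if (nrow(ltrs) == 0) stopf("empty LTR set")
  len <- ltrs$end - ltrs$start
  list(n = nrow(ltrs),
       mean_length = mean(len),
       sem_length = if (length(len) > 1) {
         sqrt(var(len) / length(len))
       } else NA_real_,
       solo_fraction = mean(ltrs$is_solo %in% TRUE))
}

#' Association of LTR sets with oocyte chromatin states
#'
#' For each oocyte domain catalog (e.g. H3K4me3, H3K27me3, methylated),
#' compares the overlap fraction of each focal LTR set against a random
#' background subset of the full LTR catalog (sampled without replacement
#' under a fixed seed) by 2x2 chi-square.
#'
#' @param ltr_sets named list of focal LTR interval data.frames.
#' @param domain_catalogs named list of oocyte domain interval data.frames.
#' @param ltr_catalog the full ("mappable") LTR catalog to sample
#'   background from.
#' @param background_n background sample size.
#' @param seed RNG seed for the background draw.
#' @return data.frame: set, mark, fraction_set, fraction_background, chi2,
#'   p; plus the background ids as an attribute.
#' @export
germline_state_association <- function(ltr_sets, domain_catalogs,
                                       ltr_catalog, background_n = 100L,
                                       seed = 1L) {
  if (background_n > nrow(ltr_catalog)) {
    stopf("background_n (%d) exceeds the LTR catalog size (%d)",
          background_n, nrow(ltr_catalog))
  }
  bg <- with_stream(seed, "germline_background", {
    ltr_catalog[sort(sample.int(nrow(ltr_catalog), background_n)), ,
                drop = FALSE]
  })
  rows <- list()
  for (set_name in names(ltr_sets)) {
    set <- ltr_sets[[set_name]]
    for (mark in names(domain_catalogs)) {
      dom <- domain_catalogs[[mark]]
      a <- sum(overlaps_any0(set, dom))
      b <- sum(overlaps_any0(bg, dom))
      tab <- rbind(c(a, nrow(set) - a), c(b, nrow(bg) - b))
      cs <- chisq_stat(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, mark = mark,
        fraction_set = a / nrow(set),
        fraction_background = b / nrow(bg),
        chi2 = cs$chi2, p = cs$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "background_ids") <- bg$id
  out
}
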