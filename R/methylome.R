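#' Allele-resolved methylation pooled over regions
#'
#' Pools methylated / total calls over all CpGs inside each region expanded
#' by `flank` bp, per allele, sample and stage. Regions with zero covered
#' CpGs get a missing level, never 0.
#'
#' @param methyl methylation call data.frame (chrom, pos, allele, meth,
#'   unmeth, sample_id, stage).
#' @param regions region data.frame with an `id` column.
#' @param flank bp added on both sides of each region.
#' @return RegionMethylation data.frame: region_id, sample_id, stage,
#'   allele, n_cpgs_covered, meth_calls, total_calls, level.
#' @export
methylation_at_regions <- function(methyl, regions, flank = 500L) {
  check_cols(regions, c("id", "chrom", "start", "end"), "regions")
  exp_reg <- regions
  exp_reg$start <- pmax(0L, exp_reg$start - as.integer(flank))
  exp_reg$end <- exp_reg$end + as.integer(flank)
  site_gr <- GenomicRanges::GRanges(methyl$chrom,
                                    IRanges::IRanges(methyl$pos + 1L,
                                                     width = 1L))
  hits <- GenomicRanges::findOverlaps(site_gr, as_granges0(exp_reg),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (!length(q)) {
    return(data.frame(region_id = character(), sample_id = character(),
                      stage = character(), allele = character(),
                      n_cpgs_covered = integer(), meth_calls = integer(),
                      total_calls = integer(), level = numeric()))
  }
  key <- data.frame(region_id = regions$id[s],
                    sample_id = methyl$sample_id[q],
                    stage = methyl$stage[q],
                    allele = methyl$allele[q],
                    stringsAsFactors = FALSE)
  grp <- interaction(key$region_id, key$sample_id, key$stage, key$allele,
                     drop = TRUE, sep = "\r")
  tot <- methyl$meth[q] + methyl$unmeth[q]
  agg <- rowsum(cbind(meth = methyl$meth[q], total = tot,
                      covered = as.integer(tot > 0)), grp)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    region_id = vapply(parts, `[`, "", 1),
    sample_id = vapply(parts, `[`, "", 2),
    stage = vapply(parts, `[`, "", 3),
    allele = vapply(parts, `[`, "", 4),
    n_cpgs_covered = as.integer(agg[, "covered"]),
    meth_calls = as.integer(agg[, "meth"]),
    total_calls = as.integer(agg[, "total"]),
    row.names = NULL, stringsAsFactors = FALSE)
  out$level <- ifelse(out$total_calls > 0,
                      out$meth_calls / out$total_calls, NA_real_)
  out[order(out$region_id, out$sample_id, out$stage, out$allele), ]
}

#' Call an allelic DMR from pooled region methylation
#'
#' Requires both alleles covered (>= `min_calls` total calls and
#' `min_cpgs` CpGs each); a DMR needs an absolute level difference of at
#' least `min_delta` and a two-sided Fisher exact p < `alpha` on the
#' pooled (meth, unmeth) x allele table. The hypermethylated allele is the
#' one with the larger level.
#'
#' @param region_meth RegionMethylation rows for ONE region, sample and
#'   stage (a maternal and a paternal row).
#' @param min_delta,alpha,min_calls,min_cpgs thresholds.
#' @return DmrCall list: region_id, sample_id, stage, is_dmr,
#'   hypermethylated_allele, delta, fisher_p, status
#'   ("ok"/"insufficient").
#' @export
call_allelic_dmr <- function(region_meth, min_delta = 0.3, alpha = 0.05,
                             min_calls = 10L, min_cpgs = 5L) {
  m <- region_meth[region_meth$allele == "maternal", , drop = FALSE]
  p <- region_meth[region_meth$allele == "paternal", , drop = FALSE]
  base <- list(region_id = region_meth$region_id[1],
               sample_id = region_meth$sample_id[1],
               stage = region_meth$stage[1])
  if (nrow(m) != 1 || nrow(p) != 1 ||
      m$total_calls < min_calls || p$total_calls < min_calls ||
      m$n_cpgs_covered < min_cpgs || p$n_cpgs_covered < min_cpgs) {
    return(c(base, list(is_dmr = NA, hypermethylated_allele = NA_character_,
                        delta = NA_real_, fisher_p = NA_real_,
                        status = "insufficient")))
  }
  delta <- abs(m$level - p$level)
  tab <- rbind(c(m$meth_calls, m$total_calls - m$meth_calls),
               c(p$meth_calls, p$total_calls - p$meth_calls))
  fp <- fisher.test(tab)$p.value
  is_dmr <- delta >= min_delta && fp < alpha
  c(base, list(
    is_dmr = is_dmr,
    hypermethylated_allele = if (is_dmr) {
      if (m$level > p$level) "maternal" else "paternal"
    } else NA_character_,
    delta = delta, fisher_p = fp, status = "ok"))
}

#' DMR calls across all (region, sample, stage) combinations
#' @param region_meth full RegionMethylation data.frame.
#' @param ... thresholds passed to [call_allelic_dmr()].
#' @return DmrCall data.frame.
#' @export
call_allelic_dmrs <- function(region_meth, ...) {
  grp <- interaction(region_meth$region_id, region_meth$sample_id,
                     region_meth$stage, drop = TRUE)
  rows <- lapply(split(region_meth, grp), call_allelic_dmr, ...)
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Stage-resolved methylation dynamics and secondary-imprint detection
#'
#' A region is a tissue-specific secondary imprint iff it shows no DMR and
#' both alleles below `low_cut` at the gamete and pre-implantation stages,
#' AND a maternal DMR in post-implantation ExE. The epiblast-silencing
#' flag requires both alleles at or above `high_cut` in the
#' post-implantation epiblast. Missing stages suppress the flags they make
#' undecidable (NA). Allelic ChIP trajectories, when supplied, are
#' summarized on raw counts (no size-factor scaling is appropriate for the
#' pre-implantation allelic comparison).
#'
#' @param region_meth RegionMethylation data.frame for one sample series.
#' @param dmrs matching [call_allelic_dmrs()] output.
#' @param stages named list mapping roles gamete, preimplantation,
#'   epiblast, exe to stage labels.
#' @param chip_counts optional allelic ChIP counts data.frame with a
#'   `stage` column (raw counts).
#' @param low_cut,high_cut trajectory thresholds.
#' @return per-region data.frame with levels per key stage, flags
#'   secondary_imprint and epiblast_silenced, and (as attribute
#'   "chip_trajectory") the raw-count allelic means per stage.
#' @export
stage_dynamics <- function(region_meth, dmrs,
                           stages = list(gamete = "GV",
                                         preimplantation = "E3.5",
                                         epiblast = "E6.5_epiblast",
                                         exe = "E6.5_ExE"),
                           chip_counts = NULL,
                           low_cut = 0.25, high_cut = 0.5) {
  get_level <- function(rid, stage, allele) {
    r <- region_meth[region_meth$region_id == rid &
                       region_meth$stage == stage &
                       region_meth$allele == allele, ]
    if (nrow(r) == 0) NA_real_ else r$level[1]
  }
  get_dmr <- function(rid, stage) {
    d <- dmrs[dmrs$region_id == rid & dmrs$stage == stage, ]
    if (nrow(d) == 0 || is.na(d$is_dmr[1])) {
      NULL
    } else d[1, ]
  }
  ids <- unique(region_meth$region_id)
  rows <- lapply(ids, function(rid) {
    lv <- c(gam_m = get_level(rid, stages$gamete, "maternal"),
            gam_p = get_level(rid, stages$gamete, "paternal"),
            pre_m = get_level(rid, stages$preimplantation, "maternal"),
            pre_p = get_level(rid, stages$preimplantation, "paternal"),
            epi_m = get_level(rid, stages$epiblast, "maternal"),
            epi_p = get_level(rid, stages$epiblast, "paternal"),
            exe_m = get_level(rid, stages$exe, "maternal"),
            exe_p = get_level(rid, stages$exe, "paternal"))
    d_gam <- get_dmr(rid, stages$gamete)
    d_pre <- get_dmr(rid, stages$preimplantation)
    d_exe <- get_dmr(rid, stages$exe)
    early_ok <- if (anyNA(lv[c("gam_m", "gam_p", "pre_m", "pre_p")]) ||
                    is.null(d_gam) || is.null(d_pre)) {
      NA
    } else {
      !d_gam$is_dmr && !d_pre$is_dmr &&
        all(lv[c("gam_m", "gam_p", "pre_m", "pre_p")] < low_cut)
    }
    exe_mat_dmr <- if (is.null(d_exe)) {
      NA
    } else {
      d_exe$is_dmr && identical(d_exe$hypermethylated_allele, "maternal")
    }
    secondary <- if (is.na(early_ok) || is.na(exe_mat_dmr)) {
      NA
    } else early_ok && exe_mat_dmr
    epi_sil <- if (anyNA(lv[c("epi_m", "epi_p")])) {
      NA
    } else all(lv[c("epi_m", "epi_p")] >= high_cut)
    data.frame(region_id = rid, t(lv),
               exe_maternal_dmr = exe_mat_dmr,
               secondary_imprint = secondary,
               epiblast_silenced = epi_sil,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(chip_counts)) {
    check_cols(chip_counts, c("stage", "mat", "pat"), "chip counts")
    traj <- aggregate(cbind(mat, pat) ~ stage, data = chip_counts, FUN = mean)
    attr(out, "chip_trajectory") <- traj
  }
  out
}
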