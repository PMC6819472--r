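## Beta-binomial allelic count simulation. Total depth is Poisson; the
## maternal count follows BetaBinomial(total, pi, rho) where pi is the
## class- and cross-dependent maternal proportion and rho the intraclass
## correlation. rho = 0 degenerates to the plain binomial.

rbetabinom <- function(n, size, pi, rho) {
  out <- integer(n)
  if (length(size) == 1) size <- rep(size, n)
  if (length(pi) == 1) pi <- rep(pi, n)
  deg <- rho <= 0 | pi <= 0 | pi >= 1
  if (length(deg) == 1) deg <- rep(deg, n)
  if (any(deg)) out[deg] <- rbinom(sum(deg), size[deg], pi[deg])
  if (any(!deg)) {
    a <- pi[!deg] * (1 - rho) / rho
    b <- (1 - pi[!deg]) * (1 - rho) / rho
    p <- rbeta(sum(!deg), a, b)
    out[!deg] <- rbinom(sum(!deg), size[!deg], p)
  }
  out
}

#' Simulate allelic ChIP read counts over peaks for one cross
#'
#' Per peak and replicate, the total allelically assigned depth is
#' Poisson(`mean_total_depth`) and the maternal share is beta-binomial with
#' the planted class proportion (see [class_maternal_pi()]): 0.5 at
#' biallelic peaks, `allelic_pi` toward the favored allele otherwise.
#' Canonical maternal imprints revert to 0.5 in the matDKO/CAST cross;
#' non-canonical and canonical paternal imprints retain their bias.
#' A small unassigned fraction is added on top of mat + pat.
#'
#' @param reference a [simulate_reference()] bundle.
#' @param truth its truth table (or a modified copy).
#' @param config the [sim_config()].
#' @param cross "B6/CAST", "CAST/B6" or "matDKO/CAST".
#' @param assay,tissue labels stamped into sample ids.
#' @return an allelic counts data.frame (region_id, sample_id, replicate,
#'   mat, pat, unassigned, kind, cross).
#' @export
simulate_allelic_chip_counts <- function(reference, truth, config, cross,
                                         assay = "H3K4me3", tissue = "ExE") {
  if (!cross %in% valid_crosses) stopf("unknown cross '%s'", cross)
  with_stream(config$seed, paste("chip", cross, assay, tissue), {
    n <- nrow(truth)
    reps <- config$n_replicates_chip
    pi_mat <- class_maternal_pi(truth$class, cross, config$allelic_pi)
    out <- lapply(seq_len(reps), function(r) {
      total <- rpois(n, config$mean_total_depth)
      mat <- rbetabinom(n, total, pi_mat, config$rho)
      data.frame(
        region_id = truth$region_id,
        sample_id = make_sample_id(assay, tissue, cross, r),
        replicate = r,
        mat = mat,
        pat = total - mat,
        unassigned = rpois(n, config$mean_total_depth * 0.5),
        kind = "peak",
        cross = cross,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate allelic counts over genes (H3K36me3 or direct RNA counting)
#'
#' Gene-level allelic counts mirror the imprint class of the gene's peak,
#' so imprinted peaks can be cross-validated against expression.
#'
#' @inheritParams simulate_allelic_chip_counts
#' @param assay "H3K36me3" or "RNA".
#' @param mean_depth Poisson mean per gene per replicate.
#' @param n_replicates replicates to draw.
#' @return an allelic counts data.frame with kind = "gene".
#' @export
simulate_allelic_gene_counts <- function(reference, truth, config, cross,
                                         assay = "H3K36me3", tissue = "ExE",
                                         mean_depth = config$mean_total_depth,
                                         n_replicates = config$n_replicates_chip) {
  if (!cross %in% valid_crosses) stopf("unknown cross '%s'", cross)
  with_stream(config$seed, paste("genecounts", cross, assay, tissue), {
    n <- nrow(truth)
    pi_mat <- class_maternal_pi(truth$class, cross, config$allelic_pi)
    out <- lapply(seq_len(n_replicates), function(r) {
      total <- rpois(n, mean_depth)
      mat <- rbetabinom(n, total, pi_mat, config$rho)
      data.frame(
        region_id = truth$gene_id,
        sample_id = make_sample_id(assay, tissue, cross, r),
        replicate = r,
        mat = mat,
        pat = total - mat,
        unassigned = rpois(n, mean_depth * 0.3),
        kind = "gene",
        cross = cross,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
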