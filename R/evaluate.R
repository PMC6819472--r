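#' Score consensus classification against the planted truth
#'
#' Collapses truth and calls to the four-way vocabulary {biallelic,
#' strain_B6, strain_CAST, imprinted} and computes the confusion matrix,
#' per-class sensitivity and precision, and their macro averages.
#' single_cross_only and unresolved predictions count as misses for every
#' truth class.
#'
#' @param calls [classify_reciprocal()] output.
#' @param truth simulator truth table.
#' @return list: confusion (table), per_class data.frame,
#'   macro_sensitivity, macro_precision, direction_accuracy (among
#'   imprinted truth recovered as imprinted).
#' @export
score_classification <- function(calls, truth) {
  collapse_truth <- c(biallelic = "biallelic", strain_B6 = "strain_B6",
                      strain_CAST = "strain_CAST",
                      imprinted_canonical_maternal = "imprinted",
                      imprinted_canonical_paternal = "imprinted",
                      imprinted_noncanonical = "imprinted")
  collapse_call <- c(biallelic = "biallelic", strain_B6 = "strain_B6",
                     strain_CAST = "strain_CAST",
                     imprinted_maternal = "imprinted",
                     imprinted_paternal = "imprinted",
                     single_cross_only = "single_cross_only",
                     unresolved = "unresolved")
  idx <- match(truth$region_id, calls$region_id)
  t4 <- collapse_truth[truth$class]
  c4 <- collapse_call[calls$consensus_class[idx]]
  c4[is.na(c4)] <- "unresolved"
  lev <- c("biallelic", "strain_B6", "strain_CAST", "imprinted")
  confusion <- table(truth = factor(t4, lev),
                     call = factor(c4, c(lev, "single_cross_only",
                                         "unresolved")))
  per_class <- data.frame(
    class = lev,
    sensitivity = vapply(lev, function(cl) {
      n <- sum(t4 == cl)
      if (n == 0) NA_real_ else sum(t4 == cl & c4 == cl) / n
    }, 0),
    precision = vapply(lev, function(cl) {
      n <- sum(c4 == cl)
      if (n == 0) NA_real_ else sum(t4 == cl & c4 == cl) / n
    }, 0),
    row.names = NULL)
  # parental direction among imprinted truth recovered as imprinted
  imp_t <- which(t4 == "imprinted" & c4 == "imprinted")
  dir_truth <- ifelse(truth$favored_allele[imp_t] == "maternal",
                      "imprinted_maternal", "imprinted_paternal")
  dir_call <- calls$consensus_class[idx[imp_t]]
  list(confusion = confusion, per_class = per_class,
       macro_sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
       macro_precision = mean(per_class$precision, na.rm = TRUE),
       direction_accuracy = if (length(imp_t)) {
         mean(dir_truth == dir_call)
       } else NA_real_)
}

#' Score canonical vs non-canonical sub-classification
#'
#' Accuracy of the matDKO-based sub-classification among planted imprints
#' that the consensus step recovered as imprinted.
#'
#' @param canonical [classify_canonical()] output.
#' @param truth simulator truth table.
#' @return list: accuracy, n_scored, table.
#' @export
score_canonical <- function(canonical, truth) {
  expected <- c(imprinted_canonical_maternal = "canonical_maternal",
                imprinted_canonical_paternal = "canonical_paternal",
                imprinted_noncanonical = "non_canonical")
  idx <- match(canonical$region_id, truth$region_id)
  exp_lab <- expected[truth$class[idx]]
  keep <- !is.na(exp_lab)
  got <- canonical$canonical_status[keep]
  list(accuracy = if (any(keep)) mean(got == exp_lab[keep]) else NA_real_,
       n_scored = sum(keep),
       table = table(truth = exp_lab[keep], call = got))
}
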