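## Cross orientation helpers. Genome 1 is always B6 (or the predominantly-B6
## matDKO maternal genome); genome 2 is always CAST. The cross string maps
## genome calls to parental labels.

valid_crosses <- c("B6/CAST", "CAST/B6", "matDKO/CAST")

#' Map genome labels to parental labels for a cross
#'
#' @param cross one of "B6/CAST", "CAST/B6", "matDKO/CAST" (maternal strain
#'   first, by convention).
#' @return named character: which parent genome1 and genome2 belong to.
#' @export
cross_orientation <- function(cross) {
  if (!cross %in% valid_crosses) {
    stopf("unknown cross '%s' (expected one of %s)", cross,
          paste(valid_crosses, collapse = ", "))
  }
  if (cross == "CAST/B6") {
    c(genome1 = "paternal", genome2 = "maternal")
  } else {
    c(genome1 = "maternal", genome2 = "paternal")
  }
}

# maternal strain label of a cross
cross_maternal_strain <- function(cross) {
  switch(cross,
         "B6/CAST" = "B6",
         "CAST/B6" = "CAST",
         "matDKO/CAST" = "B6_129",
         stopf("unknown cross '%s'", cross))
}

# TRUE unless the cross ablates maternally inherited DNA methylation
cross_maternal_meth_intact <- function(cross) cross != "matDKO/CAST"

# sample id shared by simulator and pipeline
make_sample_id <- function(assay, tissue, cross, replicate) {
  paste(assay, tissue, gsub("/", "x", cross, fixed = TRUE),
        paste0("rep", replicate), sep = "_")
}

#' Maternal allelic proportion of a planted class in a given cross
#'
#' Encodes the biology the classifier must recover: strain classes follow
#' the strain through the reciprocal crosses; canonical maternal imprints
#' revert to 0.5 in the matDKO cross (maternal gDMR methylation absent);
#' canonical paternal and non-canonical imprints retain their bias.
#'
#' @param class planted class label.
#' @param cross cross string.
#' @param pi allelic proportion toward the favored allele.
#' @return maternal allelic proportion in [0, 1].
#' @export
class_maternal_pi <- function(class, cross, pi) {
  mat_strain <- cross_maternal_strain(cross)
  vapply(class, function(cl) {
    switch(cl,
      biallelic = 0.5,
      strain_B6 = if (mat_strain %in% c("B6", "B6_129")) pi else 1 - pi,
      strain_CAST = if (mat_strain == "CAST") pi else 1 - pi,
      imprinted_canonical_maternal =
        if (cross_maternal_meth_intact(cross)) pi else 0.5,
      imprinted_canonical_paternal = 1 - pi,
      imprinted_noncanonical = 1 - pi,
      stopf("unknown class '%s'", cl))
  }, 0, USE.NAMES = FALSE)
}
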