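## Allelic-bias statistics. The null hypothesis everywhere is a maternal
## allelic proportion of 0.5. With a single replicate or no overdispersion
## the test is a two-sided exact binomial on the pooled counts (p by
## doubling the smaller tail, capped at 1); with replicates and rho > 0 it
## is a beta-binomial likelihood-ratio test with chi-square(1) reference.

# beta-binomial log-likelihood with mean pi and intraclass correlation rho
bb_loglik <- function(pi, m, n, rho) {
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  sum(lchoose(n, m) + lbeta(m + a, n - m + b) - lbeta(a, b))
}

# two-sided exact binomial p under p = 0.5: double the smaller tail
binom_p_twosided <- function(k, n) {
  if (n == 0) return(NA_real_)
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

bb_lrt_p <- function(m, n, rho) {
  keep <- n > 0
  m <- m[keep]; n <- n[keep]
  if (length(m) == 0) return(NA_real_)
  if (rho <= 0 || length(m) == 1) {
    return(binom_p_twosided(sum(m), sum(n)))
  }
  opt <- optimize(function(p) bb_loglik(p, m, n, rho),
                  interval = c(1e-8, 1 - 1e-8), maximum = TRUE)
  stat <- 2 * (opt$objective - bb_loglik(0.5, m, n, rho))
  pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

#' Method-of-moments estimate of allelic overdispersion
#'
#' Estimates the shared beta-binomial intraclass correlation rho from the
#' excess variance of replicate-level allelic fractions over the binomial
#' expectation, averaged across regions and floored at 0.
#'
#' @param counts allelic counts data.frame (one cross; regions with >= 2
#'   replicates contribute).
#' @param min_regions minimum usable regions required.
#' @return list: rho, n_regions_used, method.
#' @export
estimate_dispersion <- function(counts, min_regions = 20L) {
  sp <- split(counts, counts$region_id)
  est <- vapply(sp, function(d) {
    tot <- d$mat + d$pat
    d <- d[tot > 0, , drop = FALSE]
    tot <- d$mat + d$pat
    if (nrow(d) < 2) return(NA_real_)
    p <- sum(d$mat) / sum(tot)
    if (p < 0.01 || p > 0.99) return(NA_real_)
    v <- var(d$mat / tot)
    b <- mean(1 / tot)
    (v / (p * (1 - p)) - b) / (1 - b)
  }, 0)
  est <- est[!is.na(est)]
  if (length(est) == 0) {
    warnf("no region with >= 2 informative replicates; returning rho = 0")
    return(list(rho = 0, n_regions_used = 0L, method = "mom"))
  }
  if (length(est) < min_regions) {
    warnf("dispersion estimated from only %d regions", length(est))
  }
  list(rho = max(0, mean(est)), n_regions_used = length(est), method = "mom")
}

#' Allelic-bias test per region for one cross
#'
#' H0: maternal proportion = 0.5. Single-replicate (or rho = 0) regions use
#' the two-sided exact binomial on pooled counts; otherwise a beta-binomial
#' likelihood-ratio test across replicates. q-values are Benjamini-Hochberg
#' within the supplied family (one cross x assay x tissue); a region is
#' significant iff q < alpha, with direction from the pooled fraction.
#' Regions with zero reads in every replicate are reported untested
#' (NA p and q, direction "none").
#'
#' @param counts allelic counts data.frame for one cross (pre-filtered by
#'   [filter_informative()] in the standard pipeline).
#' @param rho shared overdispersion (e.g. from [estimate_dispersion()]).
#' @param alpha significance level on the BH-adjusted p.
#' @param cross cross label stamped into the result.
#' @param pseudocount pseudocount for the log2 display ratio only.
#' @return BiasResult data.frame: region_id, cross, mat, pat, ratio,
#'   log2_ratio, p, q, significant, direction, n_replicates, total_reads.
#' @export
allelic_bias_test <- function(counts, rho = 0, alpha = 0.05,
                              cross = counts$cross[1] %||% NA_character_,
                              pseudocount = 1) {
  if (nrow(counts) == 0) {
    return(data.frame(region_id = character(), cross = character(),
                      mat = numeric(), pat = numeric(), ratio = numeric(),
                      log2_ratio = numeric(), p = numeric(), q = numeric(),
                      significant = logical(), direction = character(),
                      n_replicates = integer(), total_reads = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(counts)), counts$region_id)
  mat <- vapply(sp, function(i) sum(counts$mat[i]), 0)
  pat <- vapply(sp, function(i) sum(counts$pat[i]), 0)
  p <- vapply(sp, function(i) {
    bb_lrt_p(counts$mat[i], counts$mat[i] + counts$pat[i], rho)
  }, 0)
  res <- data.frame(
    region_id = names(sp), cross = cross, mat = mat, pat = pat,
    ratio = ifelse(mat + pat > 0, mat / (mat + pat), NA_real_),
    log2_ratio = log2((pat + pseudocount) / (mat + pseudocount)),
    p = p,
    n_replicates = lengths(sp), total_reads = mat + pat,
    row.names = NULL, stringsAsFactors = FALSE)
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  res$significant <- !is.na(res$q) & res$q < alpha
  res$direction <- ifelse(!res$significant, "none",
                          ifelse(res$ratio > 0.5, "maternal", "paternal"))
  res[, c("region_id", "cross", "mat", "pat", "ratio", "log2_ratio",
          "p", "q", "significant", "direction", "n_replicates",
          "total_reads")]
}

#' Allelic ratio mat / (mat + pat) per region
#'
#' Counts are pooled across replicates (optionally after library-size
#' correction); 0.5 means balance, values above 0.5 a maternal skew.
#'
#' @param counts allelic counts data.frame (one cross).
#' @param size_factors optional named vector of per-sample size factors to
#'   divide counts by before pooling.
#' @return data.frame region_id, mat, pat, ratio (NA when mat + pat = 0).
#' @export
allelic_ratio <- function(counts, size_factors = NULL) {
  mat <- counts$mat
  pat <- counts$pat
  if (!is.null(size_factors)) {
    sf <- size_factors[counts$sample_id]
    if (anyNA(sf)) stopf("size factor missing for some samples")
    mat <- mat / sf
    pat <- pat / sf
  }
  agg <- rowsum(cbind(mat = mat, pat = pat), counts$region_id)
  tot <- agg[, "mat"] + agg[, "pat"]
  data.frame(region_id = rownames(agg),
             mat = agg[, "mat"], pat = agg[, "pat"],
             ratio = ifelse(tot > 0, agg[, "mat"] / tot, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch two-sample and one-sample location tests
#'
#' Thin, formula-explicit t tests: Welch's two-sample t with
#' Welch-Satterthwaite degrees of freedom, or a one-sample t of a group
#' against a reference mean mu0.
#'
#' @param sample_a numeric vector (n >= 2).
#' @param sample_b numeric vector (welch_two_sample) or NULL.
#' @param mu0 reference mean (one_sample).
#' @param kind "welch_two_sample" or "one_sample".
#' @return list: t, df, p (two-sided), mean_a, mean_b/mu0.
#' @export
location_tests <- function(sample_a, sample_b = NULL, mu0 = NULL,
                           kind = c("welch_two_sample", "one_sample")) {
  kind <- match.arg(kind)
  if (length(sample_a) < 2) stopf("need n >= 2 in the first group")
  ma <- mean(sample_a); va <- var(sample_a); na <- length(sample_a)
  if (kind == "welch_two_sample") {
    if (is.null(sample_b) || length(sample_b) < 2) {
      stopf("welch_two_sample needs n >= 2 per group")
    }
    mb <- mean(sample_b); vb <- var(sample_b); nb <- length(sample_b)
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      p <- if (ma == mb) 1 else 0
      if (p == 0) warnf("zero variance with unequal means; p = 0")
      return(list(t = if (ma == mb) 0 else Inf * sign(ma - mb),
                  df = na + nb - 2, p = p, mean_a = ma, mean_b = mb))
    }
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df), mean_a = ma, mean_b = mb)
  } else {
    if (is.null(mu0)) stopf("one_sample needs mu0")
    if (va == 0) {
      p <- if (ma == mu0) 1 else 0
      if (p == 0) warnf("zero variance with mean != mu0; p = 0")
      return(list(t = if (ma == mu0) 0 else Inf * sign(ma - mu0),
                  df = na - 1, p = p, mean_a = ma, mu0 = mu0))
    }
    t <- (ma - mu0) / sqrt(va / na)
    list(t = t, df = na - 1, p = 2 * pt(-abs(t), na - 1),
         mean_a = ma, mu0 = mu0)
  }
}
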