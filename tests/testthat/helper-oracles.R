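## Independent oracles, deliberately written as plain enumerations so they
## share no code with the implementation paths they check.

# per-read brute-force allele assignment: loop over every SNP in the table
oracle_assign_read <- function(read, snps) {
  obs <- if (read$snp_obs == "." || !nzchar(read$snp_obs)) {
    list()
  } else {
    strsplit(strsplit(read$snp_obs, ";", fixed = TRUE)[[1]], ":",
             fixed = TRUE)
  }
  n_over <- 0L; n1 <- 0L; n2 <- 0L; conflict <- FALSE
  for (o in obs) {
    pos <- as.integer(o[1]); base <- o[2]
    found <- FALSE
    for (j in seq_len(nrow(snps))) {
      if (snps$chrom[j] == read$chrom && snps$pos[j] == pos) {
        found <- TRUE
        n_over <- n_over + 1L
        if (base == snps$base_genome1[j]) n1 <- n1 + 1L
        else if (base == snps$base_genome2[j]) n2 <- n2 + 1L
        else conflict <- TRUE
        break
      }
    }
  }
  if (n_over > 0 && n1 == n_over) "genome1"
  else if (n_over > 0 && n2 == n_over) "genome2"
  else "unassigned"
}

# vectorized-but-independent oracle (hash on position keys, per read loop)
oracle_assign_reads <- function(reads, snps) {
  vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    key <- paste(snps$chrom, snps$pos)
    obs <- if (r$snp_obs == ".") character() else
      strsplit(r$snp_obs, ";", fixed = TRUE)[[1]]
    n_over <- 0L; n1 <- 0L; n2 <- 0L
    for (o in obs) {
      pb <- strsplit(o, ":", fixed = TRUE)[[1]]
      j <- which(key == paste(r$chrom, pb[1]))
      if (length(j) == 1) {
        n_over <- n_over + 1L
        if (pb[2] == snps$base_genome1[j]) n1 <- n1 + 1L
        if (pb[2] == snps$base_genome2[j]) n2 <- n2 + 1L
      }
    }
    if (n_over > 0 && n1 == n_over) "genome1"
    else if (n_over > 0 && n2 == n_over) "genome2"
    else "unassigned"
  }, "")
}

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# two-sided exact binomial p (doubled smaller tail) by pmf enumeration
oracle_binom_p <- function(k, n) {
  pmf <- vapply(0:n, function(x) choose(n, x) * 0.5^n, 0)
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}
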