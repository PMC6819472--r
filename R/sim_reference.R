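#' Simulate the genome annotation bundle
#'
#' Lays out chromosomes, peaks with planted imprinting classes, partner
#' genes, solo ERVK LTRs (every non-canonical peak overlaps exactly one),
#' CpG islands under canonical peaks, background repeat/CGI catalogs, decoy
#' LTRs inside biallelic peaks, strain-discriminating SNPs (B6/CAST plus
#' the 129 structure of the matDKO maternal genome), gDMR and known-imprint
#' annotations, oocyte chromatin-domain catalogs, and LTR sequences with
#' planted CpG density. Deterministic given the config.
#'
#' @param config a [sim_config()] object.
#' @return a `sim_reference` list; see Details in the package vignette.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  with_stream(config$seed, "reference", build_reference(config))
}

build_reference <- function(cfg) {
  n <- cfg$n_peaks
  per_chrom <- ceiling(n / cfg$n_chrom)
  slot_width <- floor(cfg$chrom_length / per_chrom)
  if (slot_width < 16000) {
    stopf("chromosomes too short for %d peaks (slot width %d < 16000 bp)",
          n, slot_width)
  }
  chromosomes <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                            length = cfg$chrom_length)

  idx <- seq_len(n)
  chrom_i <- ((idx - 1L) %% cfg$n_chrom) + 1L
  slot_i <- ((idx - 1L) %/% cfg$n_chrom)
  slot_base <- slot_i * slot_width
  p0 <- slot_base + 8000L

  # planted classes: deterministic counts from the proportions, shuffled
  cls_counts <- round_proportions(cfg$class_proportions, n)
  classes <- sample(rep(names(cls_counts), cls_counts))

  peaks <- data.frame(
    id = sprintf("peak_%04d", idx),
    chrom = chromosomes$chrom[chrom_i],
    start = p0,
    end = p0 + as.integer(cfg$peak_width),
    strand = ".",
    mark = "H3K4me3",
    tissue = "ExE",
    stringsAsFactors = FALSE
  )

  # one partner gene per peak, TSS at the peak centre
  gene_strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- p0 + as.integer(cfg$peak_width / 2)
  gl <- as.integer(cfg$gene_length)
  if (gl < 5200) stopf("gene_length must be >= 5200")
  genes <- data.frame(
    id = sprintf("gene_%04d", idx),
    name = sprintf("Gene%04d", idx),
    chrom = peaks$chrom,
    start = ifelse(gene_strand == "+", tss, tss - gl + 1L),
    end = ifelse(gene_strand == "+", tss + gl, tss + 1L),
    strand = gene_strand,
    tss = tss,
    stringsAsFactors = FALSE
  )
  exons <- make_exons(genes, gl)

  # non-canonical peaks each carry one solo ERVK LTR near the gene TSS
  nc <- which(classes == "imprinted_noncanonical")
  ltr_nc <- make_ltrs(cfg, tss[nc], gene_strand[nc],
                      peaks$chrom[nc], prefix = "ltr_nc")
  n_active <- round(length(nc) * cfg$active_fraction_of_noncanonical)
  active <- rep(FALSE, length(nc))
  if (n_active > 0) active[sample(seq_along(nc), n_active)] <- TRUE
  # chimeras need the LTR on the partner gene's strand; others become ncRNAs
  same_strand_nc <- ltr_nc$strand == gene_strand[nc]
  chimera <- active & same_strand_nc & (runif(length(nc)) < cfg$chimera_fraction)

  # decoy LTRs inside biallelic peaks: three planted failure modes
  bi <- which(classes == "biallelic")
  n_decoy <- min(cfg$n_decoys_per_type * 3L, length(bi))
  decoy_peak <- if (n_decoy > 0) sort(sample(bi, n_decoy)) else integer()
  ltr_decoy <- make_ltrs(cfg, tss[decoy_peak], gene_strand[decoy_peak],
                         peaks$chrom[decoy_peak], prefix = "ltr_decoy")
  decoy_types <- rep(c("low_reads", "no_donor_junction", "incoming_junction"),
                     length.out = n_decoy)

  # canonical imprinted peaks overlap simulated CGIs (their gDMRs)
  can <- which(classes %in% c("imprinted_canonical_maternal",
                              "imprinted_canonical_paternal"))
  cgis_can <- data.frame(
    id = sprintf("cgi_gdmr_%04d", seq_along(can)),
    chrom = peaks$chrom[can],
    start = peaks$start[can] + 200L,
    end = peaks$start[can] + 800L,
    strand = rep(".", length(can)),
    stringsAsFactors = FALSE
  )

  # background catalogs tile the inter-slot space
  bg <- place_background(cfg, chromosomes, per_chrom, slot_width)

  repeats <- rbind(
    ltr_df(ltr_nc, "ERVK"),
    ltr_df(ltr_decoy, "ERVK"),
    ltr_df(bg$ltrs, "ERVK"),
    ltr_df(bg$lines, "L1", class = "LINE", solo = FALSE)
  )
  cgis <- rbind(cgis_can, bg$cgis)

  snp <- make_snps(cfg, chromosomes)
  segments_129 <- data.frame(
    chrom = chromosomes$chrom,
    start = 0L,
    end = as.integer(round(cfg$fraction_129_segments * chromosomes$length))
  )

  imp <- classes %in% c("imprinted_canonical_maternal",
                        "imprinted_canonical_paternal",
                        "imprinted_noncanonical")
  gdmr <- data.frame(
    region_id = peaks$id[can],
    chrom = peaks$chrom[can], start = peaks$start[can], end = peaks$end[can],
    status = ifelse(classes[can] == "imprinted_canonical_paternal",
                    "paternal_gDMR", "maternal_gDMR"),
    stringsAsFactors = FALSE
  )
  imp_genes <- genes$id[imp]
  n_known <- round(length(imp_genes) * cfg$known_imprint_frac)
  known <- if (length(imp_genes)) sample(imp_genes, n_known) else character()
  known_imprints <- data.frame(
    gene_id = imp_genes,
    status = ifelse(imp_genes %in% known, "known_imprinted", "putative"),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    region_id = peaks$id,
    class = classes,
    favored_allele = c(biallelic = "none", strain_B6 = "B6",
                       strain_CAST = "CAST",
                       imprinted_canonical_maternal = "maternal",
                       imprinted_canonical_paternal = "paternal",
                       imprinted_noncanonical = "paternal")[classes],
    gene_id = genes$id,
    ltr_id = NA_character_,
    is_ltr_promoter = FALSE,
    transcript_type = "none",
    chimera_gene = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  if (length(nc)) {
    truth$ltr_id[nc] <- ltr_nc$id
    truth$is_ltr_promoter[nc] <- active
    truth$transcript_type[nc] <- ifelse(!active, "none",
                                        ifelse(chimera, "chimera", "ncRNA"))
    truth$chimera_gene[nc][chimera] <- genes$id[nc][chimera]
  }
  decoys <- data.frame(
    ltr_id = ltr_decoy$id %||% character(),
    decoy_type = decoy_types,
    peak_id = peaks$id[decoy_peak],
    stringsAsFactors = FALSE
  )

  active_ltr_ids <- if (length(nc)) ltr_nc$id[active] else character()
  ltr_seqs <- make_ltr_seqs(cfg, repeats, active_ltr_ids)
  oocyte_domains <- make_oocyte_domains(cfg, ltr_nc, active_ltr_ids,
                                        bg$ltrs, cgis_can)

  structure(list(
    config = cfg,
    chromosomes = chromosomes,
    peaks = peaks,
    genes = genes,
    exons = exons,
    repeats = repeats,
    cgis = cgis,
    snp_master = snp$master,
    snps = snp$bc,
    snps_primary = snp$primary,
    snps_129_cast = snp$s129,
    segments_129 = segments_129,
    gdmr = gdmr,
    known_imprints = known_imprints,
    oocyte_domains = oocyte_domains,
    ltr_seqs = ltr_seqs,
    truth = truth,
    decoys = decoys
  ), class = "sim_reference")
}

round_proportions <- function(p, n) {
  cnt <- floor(p * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(p * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt[cnt > 0]
}

# three exons per gene; exon_index is genomic order (transcription order
# for + genes, reversed for - genes; see exon_tx_index)
make_exons <- function(genes, gl) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      s <- g$tss + c(0L, 1500L, 5000L)
      e <- g$tss + c(300L, 2000L, gl)
    } else {
      e <- g$tss + 1L - c(0L, 1500L, 5000L)
      s <- g$tss + 1L - c(300L, 2000L, gl)
      s <- rev(s); e <- rev(e)
    }
    data.frame(gene_id = g$id, exon_index = 1:3, chrom = g$chrom,
               start = s, end = e, strand = g$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Transcription-order exon index (1 = 5' exon)
#' @param exons long exon data.frame (genomic order per gene).
#' @return integer vector parallel to `exons` rows.
#' @keywords internal
exon_tx_index <- function(exons) {
  n_per <- table(exons$gene_id)[exons$gene_id]
  ifelse(exons$strand == "+", exons$exon_index,
         as.integer(n_per) - exons$exon_index + 1L)
}

# solo LTRs planted in intron 1 of the partner gene (still overlapping the
# peak and within 3 kb of the TSS), so exonic gene reads never sit on them
make_ltrs <- function(cfg, tss, gene_strand, chrom, prefix) {
  m <- length(tss)
  if (m == 0) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  len <- pmax(150L, pmin(900L,
    as.integer(round(rnorm(m, cfg$ltr_length_mean, cfg$ltr_length_sd)))))
  same <- runif(m) < cfg$ltr_same_strand_frac
  strand <- ifelse(same, gene_strand, chartr("+-", "-+", gene_strand))
  start <- ifelse(gene_strand == "+", tss + 300L, tss - 299L - len)
  data.frame(
    id = sprintf("%s_%04d", prefix, seq_len(m)),
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + len),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

ltr_df <- function(df, family, class = "LTR", solo = TRUE) {
  if (nrow(df) == 0) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), repeat_name = character(),
                      repeat_class = character(), repeat_family = character(),
                      is_solo = logical(), stringsAsFactors = FALSE))
  }
  data.frame(df[, c("id", "chrom", "start", "end", "strand")],
             repeat_name = paste0(family, "_", df$id),
             repeat_class = class, repeat_family = family,
             is_solo = solo, stringsAsFactors = FALSE)
}

place_background <- function(cfg, chromosomes, per_chrom, slot_width) {
  n_lines <- min(150L, cfg$n_peaks * 4L)
  kinds <- c(rep("ltr", cfg$n_background_ltrs),
             rep("cgi", cfg$n_background_cgis),
             rep("line", n_lines))
  m <- length(kinds)
  n_slots <- per_chrom * cfg$n_chrom
  g <- seq_len(m)
  slot <- (g - 1L) %% n_slots
  tier <- (g - 1L) %/% n_slots
  if (m > 0 && 13000L + max(tier) * 1200L + 1200L > slot_width) {
    stopf("background catalogs do not fit the slot layout; reduce counts")
  }
  start <- (slot %/% cfg$n_chrom) * slot_width + 13000L + tier * 1200L
  chrom <- chromosomes$chrom[(slot %% cfg$n_chrom) + 1L]
  len <- ifelse(kinds == "ltr",
                pmax(150L, pmin(900L, as.integer(round(
                  rnorm(m, cfg$ltr_length_mean, cfg$ltr_length_sd))))),
                ifelse(kinds == "cgi", 600L, 1000L))
  strand <- sample(c("+", "-"), m, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + len,
                   strand = strand, stringsAsFactors = FALSE)
  list(
    ltrs = data.frame(id = sprintf("ltr_bg_%04d", seq_len(sum(kinds == "ltr"))),
                      df[kinds == "ltr", ], stringsAsFactors = FALSE),
    cgis = data.frame(id = sprintf("cgi_bg_%04d", seq_len(sum(kinds == "cgi"))),
                      df[kinds == "cgi", c("chrom", "start", "end")],
                      strand = ".", stringsAsFactors = FALSE),
    lines = data.frame(id = sprintf("line_bg_%04d", seq_len(sum(kinds == "line"))),
                       df[kinds == "line", ], stringsAsFactors = FALSE)
  )
}

make_snps <- function(cfg, chromosomes) {
  per_chrom <- lapply(seq_len(nrow(chromosomes)), function(ci) {
    L <- chromosomes$length[ci]
    n_bc <- as.integer(round(L * cfg$snp_rate))
    n_129 <- as.integer(round(L * cfg$snp_rate_129))
    pos <- sort(sample.int(L, n_bc + n_129)) - 1L
    kind <- sample(rep(c("bc", "only129"), c(n_bc, n_129)))
    bases <- c("A", "C", "G", "T")
    nn <- n_bc + n_129
    if (nn == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        base_b6 = character(), base_cast = character(),
                        base_129 = character(), kind = character(),
                        in_129_segment = logical(),
                        stringsAsFactors = FALSE))
    }
    b1 <- sample(bases, nn, replace = TRUE)
    # a base distinct from b1, uniformly over the other three
    other <- function(b) bases[(match(b, bases) + sample.int(3, length(b),
                                                             replace = TRUE) - 1L) %% 4L + 1L]
    b2 <- other(b1)
    b2[kind == "only129"] <- b1[kind == "only129"]   # B6 == CAST there
    b129 <- ifelse(kind == "bc",
                   ifelse(runif(nn) < cfg$shared_cast_frac, b2, b1),
                   other(b1))
    data.frame(chrom = chromosomes$chrom[ci], pos = pos,
               base_b6 = b1, base_cast = b2, base_129 = b129,
               kind = kind,
               in_129_segment = pos <
                 round(cfg$fraction_129_segments * L),
               stringsAsFactors = FALSE)
  })
  master <- do.call(rbind, per_chrom)
  is_bc <- master$kind == "bc"
  bc <- data.frame(chrom = master$chrom[is_bc], pos = master$pos[is_bc],
                   base_genome1 = master$base_b6[is_bc],
                   base_genome2 = master$base_cast[is_bc],
                   stringsAsFactors = FALSE)
  prim_keep <- is_bc & master$base_129 != master$base_cast
  primary <- data.frame(chrom = master$chrom[prim_keep],
                        pos = master$pos[prim_keep],
                        base_genome1 = master$base_b6[prim_keep],
                        base_genome2 = master$base_cast[prim_keep],
                        stringsAsFactors = FALSE)
  s129_keep <- master$base_129 != master$base_cast
  s129 <- data.frame(chrom = master$chrom[s129_keep],
                     pos = master$pos[s129_keep],
                     base_genome1 = master$base_129[s129_keep],
                     base_genome2 = master$base_cast[s129_keep],
                     stringsAsFactors = FALSE)
  list(master = master, bc = bc, primary = primary, s129 = s129)
}

# random sequence with a planted CpG dinucleotide density
plant_cpg_seq <- function(len, cg_rate) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  s <- gsub("CG", "CA", s, fixed = TRUE)
  k <- rbinom(1, len - 1L, cg_rate)
  if (k > 0) {
    slots <- seq(1L, len - 1L, by = 2L)
    at <- sort(sample(slots, min(k, length(slots))))
    for (p in at) substr(s, p, p + 1L) <- "CG"
  }
  s
}

make_ltr_seqs <- function(cfg, repeats, active_ids) {
  ltrs <- repeats[repeats$repeat_class == "LTR", , drop = FALSE]
  if (nrow(ltrs) == 0) return(character())
  rate <- ifelse(ltrs$id %in% active_ids,
                 cfg$cg_rate_active, cfg$cg_rate_background)
  seqs <- vapply(seq_len(nrow(ltrs)), function(i) {
    plant_cpg_seq(ltrs$end[i] - ltrs$start[i], rate[i])
  }, "")
  names(seqs) <- ltrs$id
  seqs
}

make_oocyte_domains <- function(cfg, ltr_nc, active_ids, bg_ltrs, cgis_can) {
  expand <- function(df, by = 1000L) {
    if (nrow(df) == 0) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer()))
    }
    data.frame(chrom = df$chrom, start = pmax(0L, df$start - by),
               end = df$end + by)
  }
  pick_bg <- function(frac) {
    m <- nrow(bg_ltrs)
    if (m == 0) return(bg_ltrs[0, ])
    bg_ltrs[sort(sample.int(m, round(m * frac))), , drop = FALSE]
  }
  list(
    H3K27me3 = expand(rbind(ltr_nc[, c("chrom", "start", "end")],
                            pick_bg(0.10)[, c("chrom", "start", "end")])),
    H3K4me3 = expand(rbind(
      ltr_nc[ltr_nc$id %in% active_ids, c("chrom", "start", "end")],
      pick_bg(0.10)[, c("chrom", "start", "end")])),
    methylated = expand(rbind(cgis_can[, c("chrom", "start", "end")],
                              pick_bg(0.20)[, c("chrom", "start", "end")]))
  )
}
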