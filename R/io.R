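## Readers/writers for the plain-text formats the pipeline touches.
## All interval formats are parsed as 0-based half-open (BED convention);
## chromosome names are taken verbatim (no "chr" normalization).

# ---- generic typed-table reader --------------------------------------------

#' Read a TSV against a declared schema
#'
#' A thin schema layer over [utils::read.delim()]: required columns must be
#' present, optional columns are filled with declared defaults, and column
#' types are enforced with an error naming the first offending row.
#'
#' @param path file path; must exist and carry a header row.
#' @param required named character vector, column name -> type
#'   ("character", "integer", "numeric", "logical").
#' @param optional named list, column name -> list(type=, default=).
#' @return a data.frame with exactly the schema's columns, typed.
#' @export
read_typed_table <- function(path, required, optional = list()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_cols(df, names(required), basename(path))
  for (col in names(optional)) {
    if (!col %in% names(df)) df[[col]] <- optional[[col]]$default
  }
  types <- c(required, vapply(optional, function(o) o$type, ""))
  for (col in names(types)) {
    df[[col]] <- coerce_col(df[[col]], types[[col]], col, basename(path))
  }
  df[, names(types), drop = FALSE]
}

coerce_col <- function(x, type, col, what) {
  out <- switch(type,
    character = as.character(x),
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = parse_logical(x),
    stopf("unknown schema type '%s'", type))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stopf("%s: column '%s' row %d: cannot parse '%s' as %s",
          what, col, bad[1], x[bad[1]], type)
  }
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Write a data.frame as a headered TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- intervals --------------------------------------------------------------

#' Read an interval file (BED or interval-bearing TSV)
#'
#' @param path file path.
#' @param format one of "bed", "repeat" (RepeatMasker-out-like TSV with
#'   header), "gene" (gene-model TSV, see [read_gene_table()]).
#' @return a validated interval data.frame; BED yields columns chrom, start,
#'   end, id, score, strand (strand "." when absent from the file).
#' @export
read_intervals <- function(path, format = c("bed", "repeat", "gene")) {
  format <- match.arg(format)
  switch(format,
    bed = read_bed(path),
    "repeat" = read_repeat_table(path),
    gene = read_gene_table(path))
}

#' Read a BED3/BED6 file (0-based half-open)
#' @param path BED file path.
#' @return data.frame(chrom, start, end, id, score, strand).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      score = numeric(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stopf("%s: malformed BED line %d (fewer than 3 fields)",
          basename(path), which(nf < 3)[1])
  }
  field <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  }
  start <- suppressWarnings(as.integer(field(2, "")))
  end <- suppressWarnings(as.integer(field(3, "")))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stopf("%s: malformed BED line %d (non-numeric coordinates)",
          basename(path), bad[1])
  }
  df <- data.frame(
    chrom = field(1, ""),
    start = start,
    end = end,
    id = field(4, "."),
    score = suppressWarnings(as.numeric(field(5, "0"))),
    strand = field(6, "."),
    stringsAsFactors = FALSE
  )
  df$strand[!df$strand %in% c("+", "-")] <- "."
  df$id[df$id == "."] <- paste0("region_", seq_len(nrow(df)))[df$id == "."]
  validate_intervals(df, basename(path))
  df
}

#' Write intervals as BED6
#' @param df interval data.frame with chrom, start, end and optional id,
#'   score, strand columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    id = df$id %||% paste0("region_", seq_len(nrow(df))),
    score = df$score %||% 0,
    strand = if ("strand" %in% names(df)) df$strand else "."
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-out-like repeat annotation TSV
#' @param path TSV with header columns chrom, start, end, strand,
#'   repeat_name, repeat_class, repeat_family (optional: id, is_solo).
#' @return validated repeat data.frame.
#' @export
read_repeat_table <- function(path) {
  df <- read_typed_table(
    path,
    required = c(chrom = "character", start = "integer", end = "integer",
                 strand = "character", repeat_name = "character",
                 repeat_class = "character", repeat_family = "character"),
    optional = list(id = list(type = "character", default = NA_character_),
                    is_solo = list(type = "logical", default = TRUE))
  )
  if (anyNA(df$id)) df$id <- paste0("rep_", seq_len(nrow(df)))
  if (any(!nzchar(df$repeat_class) | !nzchar(df$repeat_family))) {
    stopf("%s: repeat_class/repeat_family must be non-empty", basename(path))
  }
  validate_intervals(df, basename(path))
  df
}

#' Read a gene-model TSV
#'
#' Minimal gene models: one row per gene with a 0-based TSS and exons
#' encoded as "start-end;start-end" in genomic order.
#'
#' @param path TSV with header columns id, name, chrom, start, end, strand,
#'   tss, exons.
#' @return list with elements `genes` (data.frame) and `exons` (long
#'   data.frame: gene_id, exon_index, chrom, start, end, strand).
#' @export
read_gene_table <- function(path) {
  df <- read_typed_table(
    path,
    required = c(id = "character", name = "character", chrom = "character",
                 start = "integer", end = "integer", strand = "character",
                 tss = "integer", exons = "character")
  )
  validate_intervals(df, basename(path))
  exp_tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  bad <- which(df$tss != exp_tss)
  if (length(bad)) {
    stopf("%s: gene %s: tss %d inconsistent with strand %s and interval",
          basename(path), df$id[bad[1]], df$tss[bad[1]], df$strand[bad[1]])
  }
  exons <- decode_exons(df$exons, df$id, df$chrom, df$strand)
  validate_exons(exons, df)
  list(genes = df[, setdiff(names(df), "exons")], exons = exons)
}

decode_exons <- function(enc, gene_id, chrom, strand) {
  pieces <- strsplit(enc, ";", fixed = TRUE)
  n <- lengths(pieces)
  flat <- unlist(pieces, use.names = FALSE)
  se <- strsplit(flat, "-", fixed = TRUE)
  data.frame(
    gene_id = rep(gene_id, n),
    exon_index = unlist(lapply(n, seq_len)),
    chrom = rep(chrom, n),
    start = as.integer(vapply(se, `[`, "", 1)),
    end = as.integer(vapply(se, `[`, "", 2)),
    strand = rep(strand, n),
    stringsAsFactors = FALSE
  )
}

encode_exons <- function(exons) {
  exons <- exons[order(exons$gene_id, exons$exon_index), ]
  enc <- tapply(paste0(exons$start, "-", exons$end), exons$gene_id,
                paste, collapse = ";")
  enc
}

validate_exons <- function(exons, genes) {
  validate_intervals(exons, "exon table")
  for (gid in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == gid, ]
    g <- genes[genes$id == gid, ]
    if (is.unsorted(e$start) || any(e$start[-1] < e$end[-nrow(e)])) {
      stopf("gene %s: exons must be sorted and non-overlapping", gid)
    }
    if (min(e$start) < g$start || max(e$end) > g$end) {
      stopf("gene %s: exons extend outside the gene interval", gid)
    }
  }
  invisible(exons)
}

#' Write a gene-model TSV (inverse of [read_gene_table()])
#' @param genes gene data.frame (without exons column).
#' @param exons long exon data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, exons, path) {
  enc <- encode_exons(exons)
  genes$exons <- unname(enc[genes$id])
  write_tsv(genes, path)
}

# ---- domain tables ----------------------------------------------------------

#' Read a SNP table (TSV: chrom, pos, base_genome1, base_genome2)
#' @param path TSV path.
#' @return validated SNP data.frame; pos is 0-based.
#' @export
read_snp_table <- function(path) {
  df <- read_typed_table(
    path,
    required = c(chrom = "character", pos = "integer",
                 base_genome1 = "character", base_genome2 = "character")
  )
  ok <- df$base_genome1 %in% c("A", "C", "G", "T") &
    df$base_genome2 %in% c("A", "C", "G", "T") &
    df$base_genome1 != df$base_genome2
  if (!all(ok)) {
    stopf("%s: row %d: SNP bases must be distinct A/C/G/T",
          basename(path), which(!ok)[1])
  }
  df
}

#' Read an allelic count table
#' @param path TSV with columns region_id, sample_id, replicate, mat, pat,
#'   unassigned (optional kind, cross).
#' @return validated counts data.frame.
#' @export
read_allelic_counts <- function(path) {
  df <- read_typed_table(
    path,
    required = c(region_id = "character", sample_id = "character",
                 replicate = "integer", mat = "integer", pat = "integer",
                 unassigned = "integer"),
    optional = list(kind = list(type = "character", default = "peak"),
                    cross = list(type = "character", default = NA_character_))
  )
  validate_allelic_counts(df)
  df
}

#' Validate an allelic count table (non-negative counts, unique keys)
#' @param df counts data.frame.
#' @return `df`, invisibly.
#' @export
validate_allelic_counts <- function(df) {
  check_cols(df, c("region_id", "sample_id", "replicate", "mat", "pat",
                   "unassigned"), "allelic counts")
  bad <- which(df$mat < 0 | df$pat < 0 | df$unassigned < 0)
  if (length(bad)) stopf("allelic counts: negative count at row %d", bad[1])
  key <- paste(df$region_id, df$sample_id, df$replicate)
  if (anyDuplicated(key)) {
    stopf("allelic counts: duplicated (region_id, sample_id, replicate) key: %s",
          key[anyDuplicated(key)])
  }
  invisible(df)
}

#' Read a cross-design sample sheet
#' @param path TSV with columns sample_id, maternal_strain, paternal_strain,
#'   maternal_methylation_intact, tissue, assay, replicate.
#' @return validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_typed_table(
    path,
    required = c(sample_id = "character", maternal_strain = "character",
                 paternal_strain = "character",
                 maternal_methylation_intact = "logical",
                 tissue = "character", assay = "character",
                 replicate = "integer")
  )
  validate_sample_sheet(df)
  df
}

#' Validate a cross-design sample sheet
#' @param df sample sheet data.frame.
#' @return `df`, invisibly.
#' @export
validate_sample_sheet <- function(df) {
  bad <- which(df$maternal_strain == df$paternal_strain)
  if (length(bad)) {
    stopf("sample sheet row %d: maternal and paternal strain identical", bad[1])
  }
  dko <- which(!df$maternal_methylation_intact & df$maternal_strain != "B6_129")
  if (length(dko)) {
    stopf("sample sheet row %d: matDKO samples must have maternal_strain B6_129",
          dko[1])
  }
  invisible(df)
}

#' Read per-CpG allelic methylation calls
#' @param path TSV with columns chrom, pos, allele, meth, unmeth, sample_id,
#'   stage.
#' @return validated methylation data.frame.
#' @export
read_methyl_table <- function(path) {
  df <- read_typed_table(
    path,
    required = c(chrom = "character", pos = "integer", allele = "character",
                 meth = "integer", unmeth = "integer",
                 sample_id = "character", stage = "character")
  )
  if (any(df$meth < 0 | df$unmeth < 0)) stopf("%s: negative methylation count",
                                              basename(path))
  if (!all(df$allele %in% c("maternal", "paternal", "unassigned"))) {
    stopf("%s: allele must be maternal/paternal/unassigned", basename(path))
  }
  df
}

# ---- reads (SAM-lite TSV) ---------------------------------------------------

#' Read simplified aligned reads (SAM-lite TSV)
#'
#' Columns: read_id, chrom, start, end, strand, sample_id, replicate,
#' snp_obs ("pos:base" entries joined by ";", or "."), junctions
#' ("donor-acceptor" entries joined by ";", or "."). Positions are 0-based;
#' junction donor < acceptor genomically.
#'
#' @param path TSV path.
#' @return validated read data.frame (snp_obs/junctions kept encoded).
#' @export
read_reads <- function(path) {
  df <- read_typed_table(
    path,
    required = c(read_id = "character", chrom = "character",
                 start = "integer", end = "integer", strand = "character",
                 sample_id = "character", replicate = "integer",
                 snp_obs = "character", junctions = "character")
  )
  validate_reads(df)
  df
}

#' Validate a read table
#' @param df read data.frame.
#' @return `df`, invisibly.
#' @export
validate_reads <- function(df) {
  validate_intervals(df, "read table")
  if (any(df$replicate < 1)) stopf("read table: replicate must be >= 1")
  obs <- parse_snp_obs(df)
  if (nrow(obs)) {
    bad <- which(obs$pos < df$start[obs$row] | obs$pos >= df$end[obs$row])
    if (length(bad)) {
      stopf("read %s: SNP observation at %d outside [start, end)",
            df$read_id[obs$row[bad[1]]], obs$pos[bad[1]])
    }
  }
  jn <- parse_junctions(df)
  if (nrow(jn) && any(jn$donor >= jn$acceptor)) {
    stopf("read table: junction donor must be < acceptor")
  }
  invisible(df)
}

# long data.frame (row, pos, base) of SNP observations; row indexes df
parse_snp_obs <- function(df) {
  enc <- df$snp_obs
  has <- which(!is.na(enc) & enc != "." & nzchar(enc))
  if (!length(has)) {
    return(data.frame(row = integer(), pos = integer(), base = character()))
  }
  parts <- strsplit(enc[has], ";", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  pb <- strsplit(flat, ":", fixed = TRUE)
  data.frame(
    row = rep(has, n),
    pos = as.integer(vapply(pb, `[`, "", 1)),
    base = vapply(pb, `[`, "", 2),
    stringsAsFactors = FALSE
  )
}

# long data.frame (row, donor, acceptor); row indexes df
parse_junctions <- function(df) {
  enc <- df$junctions
  has <- which(!is.na(enc) & enc != "." & nzchar(enc))
  if (!length(has)) {
    return(data.frame(row = integer(), donor = integer(), acceptor = integer()))
  }
  parts <- strsplit(enc[has], ";", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  da <- strsplit(flat, "-", fixed = TRUE)
  data.frame(
    row = rep(has, n),
    donor = as.integer(vapply(da, `[`, "", 1)),
    acceptor = as.integer(vapply(da, `[`, "", 2))
  )
}

encode_snp_obs <- function(pos_list, base_list) {
  mapply(function(p, b) {
    if (!length(p)) "." else paste(paste0(p, ":", b), collapse = ";")
  }, pos_list, base_list, USE.NAMES = FALSE)
}

encode_junctions <- function(donor_list, acceptor_list) {
  mapply(function(d, a) {
    if (!length(d)) "." else paste(paste0(d, "-", a), collapse = ";")
  }, donor_list, acceptor_list, USE.NAMES = FALSE)
}

# ---- tracks -----------------------------------------------------------------

#' Write a windowed track as bedGraph
#' @param track data.frame with chrom, start, end, value.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  check_cols(track, c("chrom", "start", "end", "value"), "track")
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
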