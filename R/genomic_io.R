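# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate convention (fixed package-wide): external records carry 1-based
# inclusive positions (meQTL tables, SNP/CpG positions); BED and bedGraph are
# read in their native 0-based half-open convention; all internal window
# arithmetic is 0-based half-open. Conversion happens exactly once, here at
# the reader boundary.

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T}` is masked to `N`. The chromosome name is the header token
#' before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_sequence`: named character vector of chromosome
#'   sequences with a `lengths` attribute.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- nm
  new_genome(seqs)
}

new_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(seqs, lengths = setNames(nchar(seqs), names(seqs)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence with", length(x), "chromosome(s):\n")
  print(attr(x, "lengths"))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `genome_sequence`.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) attr(genome, "lengths")

#' Extract a genomic interval (0-based half-open)
#'
#' Out-of-bounds access is an error, never silent truncation.
#'
#' @param genome A `genome_sequence`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open interval bounds.
#' @return Nucleotide string of length `end0 - start0`.
#' @export
genome_slice <- function(genome, chrom, start0, end0) {
  len <- genome_lengths(genome)[chrom]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (start0 < 0 || end0 > len || start0 >= end0)
    stop(sprintf("interval [%d, %d) out of bounds for %s (length %d)",
                 start0, end0, chrom, len))
  substr(genome[[chrom]], start0 + 1L, end0)
}

#' Write a genome to FASTA
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(genome)) {
    writeLines(paste0(">", chrom), con)
    s <- genome[[chrom]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a per-base accessibility track from a 4-column bedGraph
#'
#' Intervals are expanded to per-base signal; bases not covered are 0.
#' Overlapping intervals are resolved last-writer-wins with a warning.
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @param genome A `genome_sequence` giving chromosome lengths.
#' @return An `atac_track`: named list of per-base numeric vectors.
#' @export
read_atac_bedgraph <- function(path, genome) {
  stopifnot(file.exists(path))
  lens <- genome_lengths(genome)
  track <- lapply(lens, numeric)
  info <- file.info(path)
  if (info$size > 0) {
    bg <- read.delim(path, header = FALSE, comment.char = "#",
                     col.names = c("chrom", "start", "end", "value"),
                     colClasses = c("character", "integer", "integer", "numeric"))
    if (any(!is.finite(bg$value)) || any(bg$value < 0))
      stop("bedGraph values must be finite and >= 0: ", path)
    covered <- lapply(lens, logical)
    overlap <- FALSE
    for (i in seq_len(nrow(bg))) {
      chrom <- bg$chrom[i]
      if (!chrom %in% names(lens)) stop("unknown chromosome in bedGraph: ", chrom)
      if (bg$start[i] < 0 || bg$end[i] > lens[[chrom]] || bg$start[i] >= bg$end[i])
        stop(sprintf("bedGraph interval [%d, %d) out of bounds on %s (line %d)",
                     bg$start[i], bg$end[i], chrom, i))
      idx <- (bg$start[i] + 1L):bg$end[i]
      if (any(covered[[chrom]][idx])) overlap <- TRUE
      covered[[chrom]][idx] <- TRUE
      track[[chrom]][idx] <- bg$value[i]
    }
    if (overlap) warning("overlapping bedGraph intervals resolved last-writer-wins")
  }
  structure(track, class = "atac_track")
}

#' Per-base slice of an accessibility track (0-based half-open)
#' @param track An `atac_track`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open bounds.
#' @return Numeric vector of length `end0 - start0`.
#' @export
atac_slice <- function(track, chrom, start0, end0) {
  v <- track[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (start0 < 0 || end0 > length(v) || start0 >= end0)
    stop(sprintf("interval [%d, %d) out of bounds for %s", start0, end0, chrom))
  v[(start0 + 1L):end0]
}

#' Write an accessibility track as bedGraph
#'
#' Zero-signal runs are omitted (bedGraph sparsity convention).
#' @param track An `atac_track`.
#' @param path Output path.
#' @export
write_atac_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

meqtl_required_cols <- c("snp_id", "snp_chrom", "snp_pos", "ref", "alt",
                         "cpg_id", "cpg_chrom", "cpg_pos", "slope", "pvalue")

#' Read a meQTL association table
#'
#' Tab-separated with a header and columns `snp_id, snp_chrom, snp_pos, ref,
#' alt, cpg_id, cpg_chrom, cpg_pos, slope, pvalue`. Positions are 1-based.
#' Rows whose SNP and CpG lie on different chromosomes are dropped (count
#' reported); when a genome is supplied, rows whose reference allele does not
#' match the genome base are dropped (count reported).
#'
#' @param path Path to the table.
#' @param genome Optional `genome_sequence` for reference-allele validation.
#' @return data.frame of meQTL records with a `distance` column (bp).
#' @export
read_meqtl_table <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(meqtl_required_cols, names(df))
  if (length(missing_cols))
    stop("meQTL table is missing columns: ", paste(missing_cols, collapse = ", "))
  df$snp_pos <- as.integer(df$snp_pos)
  df$cpg_pos <- as.integer(df$cpg_pos)
  df$slope <- as.numeric(df$slope)
  df$pvalue <- as.numeric(df$pvalue)
  if (any(!is.finite(df$slope))) stop("non-finite slope in meQTL table")
  bad_alleles <- !(df$ref %in% c("A", "C", "G", "T")) |
    !(df$alt %in% c("A", "C", "G", "T")) | df$ref == df$alt
  if (any(bad_alleles)) stop("invalid ref/alt alleles in meQTL table (",
                             sum(bad_alleles), " rows)")
  mismatch <- df$snp_chrom != df$cpg_chrom
  if (any(mismatch)) {
    msg("dropped ", sum(mismatch), " meQTL rows with SNP/CpG chromosome mismatch")
    df <- df[!mismatch, , drop = FALSE]
  }
  if (!is.null(genome)) {
    obs <- vapply(seq_len(nrow(df)), function(i)
      genome_slice(genome, df$snp_chrom[i], df$snp_pos[i] - 1L, df$snp_pos[i]),
      character(1))
    bad <- obs != df$ref
    if (any(bad)) {
      msg("dropped ", sum(bad), " meQTL rows whose ref allele mismatches the genome")
      df <- df[!bad, , drop = FALSE]
    }
  }
  df$distance <- abs(df$snp_pos - df$cpg_pos)
  rownames(df) <- NULL
  df
}

#' Write a meQTL association table
#' @param records data.frame as returned by [read_meqtl_table()].
#' @param path Output path.
#' @export
write_meqtl_table <- function(records, path) {
  write.table(records[, meqtl_required_cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The eight functional-region types
#'
#' The closed vocabulary of chromatin-state region types used by the
#' interpretability analyses: active promoter, strong enhancer,
#' transcriptional transition, transcriptional elongation, insulator,
#' heterochromatin, repressed region, repetitive element/CNV.
#' @return Character vector of the eight names.
#' @export
functional_region_types <- function() {
  c("Active_Promoter", "Strong_Enhancer", "Txn_Transition", "Txn_Elongation",
    "Insulator", "Heterochrom_lo", "Repressed", "Repetitive_CNV")
}

#' Read functional-region annotations from BED4+
#'
#' @param path BED file with a name column (0-based half-open intervals).
#' @param vocabulary Allowed region-type names; names outside it are an error.
#' @return data.frame with `chrom`, `start0`, `end0`, `region_type`.
#' @export
read_bed_annotations <- function(path, vocabulary = functional_region_types()) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 4L) stop("annotation BED needs at least 4 columns")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start0", "end0", "region_type")
  df$chrom <- as.character(df$chrom)
  df$region_type <- as.character(df$region_type)
  bad <- which(df$start0 >= df$end0)
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1L])
  unknown <- setdiff(unique(df$region_type), vocabulary)
  if (length(unknown))
    stop("unknown region type(s): ", paste(unknown, collapse = ", "))
  df
}

#' Read TSS annotations from BED6
#'
#' The TSS position is the 5' end of the interval: `start0 + 1` (1-based) on
#' the `+` strand and `end0` on the `-` strand.
#'
#' @param path BED6 file: chrom, start, end, gene_id, score, strand.
#' @return data.frame with `chrom`, `tss_pos` (1-based), `gene_id`, `strand`.
#' @export
read_tss_bed <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 6L) stop("TSS BED needs 6 columns (BED6 with strand)")
  df <- df[, 1:6]
  names(df) <- c("chrom", "start0", "end0", "gene_id", "score", "strand")
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  data.frame(chrom = as.character(df$chrom),
             tss_pos = ifelse(df$strand == "+", df$start0 + 1L, df$end0),
             gene_id = as.character(df$gene_id),
             strand = as.character(df$strand),
             stringsAsFactors = FALSE)
}
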