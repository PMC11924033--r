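# CpG-centered window extraction, allele substitution, and the
# positional-wise cutting of windows into terminal / flanking / central
# segments.

#' Deterministic cutting plan for a size class
#'
#' A CpG-centered window is tiled by `2n + 3` half-open cuts: a 250 bp
#' terminal cut, `n` flanking cuts of 500 bp, the 501 bp central cut (CpG at
#' its midpoint), `n` more 500 bp cuts, and a final 250 bp terminal cut.
#' `n = 19` for SMALL (window 20,001 bp) and `n = 199` for LARGE
#' (window 200,001 bp).
#'
#' @param size_class "SMALL" or "LARGE".
#' @return A `segmentation_plan`: list with `size_class`, `n`, `window_len`,
#'   `central_index`, and `cuts` (data.frame of 0-based half-open
#'   `start0`/`end0` relative to window start).
#' @export
plan_cuts <- function(size_class = c("SMALL", "LARGE")) {
  size_class <- match.arg(size_class)
  n <- if (size_class == "SMALL") 19L else 199L
  lens <- c(250L, rep(500L, n), 501L, rep(500L, n), 250L)
  ends <- cumsum(lens)
  structure(list(size_class = size_class, n = n,
                 window_len = sum(lens),
                 central_index = n + 2L,
                 cuts = data.frame(start0 = ends - lens, end0 = ends)),
            class = "segmentation_plan")
}

#' @export
print.segmentation_plan <- function(x, ...) {
  cat(sprintf("segmentation_plan %s: %d cuts tiling a %d bp window (central cut #%d)\n",
              x$size_class, nrow(x$cuts), x$window_len, x$central_index))
  invisible(x)
}

#' Cut index containing a window offset
#' @param plan A `segmentation_plan`.
#' @param offset0 0-based offset within the window.
#' @return 1-based cut index.
#' @export
cut_index_of <- function(plan, offset0) {
  stopifnot(offset0 >= 0, offset0 < plan$window_len)
  findInterval(offset0, plan$cuts$start0)
}

#' Extract a CpG-centered window with pre/post-mutation sequences
#'
#' The window spans `cpg_pos +/- (L-1)/2` so the CpG cytosine sits at 0-based
#' offset `(L-1)/2`. The post-mutation sequence substitutes the SNP's alt
#' allele at its offset. Windows that would extend past a chromosome end are
#' rejected (no padding): `NULL` is returned with a logged reason.
#'
#' @param genome A `genome_sequence`.
#' @param atac An `atac_track` (or `NULL` for a zero track).
#' @param pair One-row data.frame with `snp_chrom`, `snp_pos`, `cpg_pos`,
#'   `ref`, `alt` (1-based positions).
#' @param plan A `segmentation_plan`.
#' @return A `window_pair`: list with `pre_seq`, `post_seq`, `atac`,
#'   `snp_offset` (0-based), `window_start0`, `chrom`; or `NULL` if out of
#'   bounds.
#' @export
extract_window <- function(genome, atac, pair, plan) {
  L <- plan$window_len
  R <- (L - 1L) %/% 2L
  chrom <- pair$snp_chrom
  start0 <- pair$cpg_pos - 1L - R
  end0 <- start0 + L
  chrom_len <- genome_lengths(genome)[chrom]
  if (is.na(chrom_len)) stop("unknown chromosome: ", chrom)
  if (start0 < 0 || end0 > chrom_len) {
    msg("window for CpG at ", chrom, ":", pair$cpg_pos,
        " out of chromosome bounds; pair dropped")
    return(NULL)
  }
  snp_offset <- pair$snp_pos - 1L - start0
  if (snp_offset < 0 || snp_offset >= L)
    stop("SNP outside the window (distance exceeds the plan radius)")
  pre <- genome_slice(genome, chrom, start0, end0)
  if (substr(pre, R + 1L, R + 2L) != "CG")
    warning("window center is not a CG dinucleotide at ", chrom, ":", pair$cpg_pos)
  if (substr(pre, snp_offset + 1L, snp_offset + 1L) != pair$ref)
    warning("genome base at SNP ", chrom, ":", pair$snp_pos,
            " differs from the ref allele")
  post <- pre
  substr(post, snp_offset + 1L, snp_offset + 1L) <- pair$alt
  av <- if (is.null(atac)) numeric(L) else atac_slice(atac, chrom, start0, end0)
  structure(list(pre_seq = pre, post_seq = post, atac = av,
                 snp_offset = snp_offset, window_start0 = start0,
                 chrom = chrom),
            class = "window_pair")
}

#' Cut a window-length sequence or track into plan segments
#'
#' @param x Nucleotide string or numeric vector of length `plan$window_len`.
#' @param plan A `segmentation_plan`.
#' @return List of segments (strings or numeric vectors), one per cut,
#'   ordered 5' to 3'; their concatenation reconstructs the input exactly.
#' @export
cut_segments <- function(x, plan) {
  n_in <- if (is.character(x)) nchar(x) else length(x)
  if (n_in != plan$window_len)
    stop("input length ", n_in, " != expected window length ", plan$window_len)
  if (is.character(x)) {
    mapply(function(s, e) substr(x, s + 1L, e),
           plan$cuts$start0, plan$cuts$end0, SIMPLIFY = FALSE)
  } else {
    mapply(function(s, e) x[(s + 1L):e],
           plan$cuts$start0, plan$cuts$end0, SIMPLIFY = FALSE)
  }
}
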