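# Condition comparison: predict a SNP's effect under case vs control
# accessibility, categorize CpG sites by how the disease condition changes
# the predicted effect, and map affected CpGs to proximal promoters.

#' Predict slopes under case and control accessibility
#'
#' Two forward passes of a trained regression model that differ only in the
#' ATAC column of the feature tensor.
#'
#' @param model Trained REGRESS `methven_model`.
#' @param pair One-row pair data.frame.
#' @param atac_case,atac_control `atac_track` objects covering the window.
#' @param genome A `genome_sequence`.
#' @param plan The pair's `segmentation_plan`.
#' @param embedder An `embedder`.
#' @return List with `slope_case` and `slope_control`.
#' @export
predict_conditions <- function(model, pair, atac_case, atac_control, genome,
                               plan, embedder = onehot_embedder()) {
  stopifnot(model$config$task == "REGRESS")
  predict_one <- function(atac) {
    w <- extract_window(genome, atac, pair, plan)
    if (is.null(w)) stop("window out of chromosome bounds")
    feats <- featurize(w, plan, embedder)
    x <- array(feats, dim = c(1L, nrow(feats), ncol(feats)))
    predict_model(model, x)
  }
  list(slope_case = predict_one(atac_case),
       slope_control = predict_one(atac_control))
}

#' Categorize CpG sites by condition effect
#'
#' Partitions the (case, control) slope plane into four categories with
#' `delta = |slope_case - slope_control|`:
#' UNAFFECTED when `delta <= threshold`; otherwise REDUCED when the case
#' slope is smaller in absolute value than the control slope (the condition
#' weakens the SNP's effect); otherwise UP_ENHANCED when the control slope
#' is non-negative, DOWN_ENHANCED when it is negative. Every point maps to
#' exactly one category.
#'
#' @param slope_case,slope_control Numeric vectors of predicted slopes.
#' @param threshold Delta threshold (0.5 per the method).
#' @return Character vector of categories.
#' @export
categorize_affect <- function(slope_case, slope_control, threshold = 0.5) {
  stopifnot(length(slope_case) == length(slope_control),
            all(is.finite(slope_case)), all(is.finite(slope_control)))
  delta <- abs(slope_case - slope_control)
  ifelse(delta <= threshold, "UNAFFECTED",
         ifelse(abs(slope_case) < abs(slope_control), "REDUCED",
                ifelse(slope_control >= 0, "UP_ENHANCED", "DOWN_ENHANCED")))
}

#' Rank top CpG sites within each affected category
#'
#' Within each category except UNAFFECTED, CpGs are ranked by
#' `delta = |slope_case - slope_control|` descending; ties are broken by CpG
#' id so the ranking is stable under input permutation.
#'
#' @param categorized data.frame with `cpg_id`, `slope_case`,
#'   `slope_control`, `category` columns.
#' @param per_category_k Number of top CpGs to keep per category.
#' @return Named list of data.frames, one per affected category present.
#' @export
rank_top_cpgs <- function(categorized, per_category_k) {
  stopifnot(all(c("cpg_id", "slope_case", "slope_control", "category")
                %in% names(categorized)))
  categorized$delta <- abs(categorized$slope_case - categorized$slope_control)
  affected <- categorized[categorized$category != "UNAFFECTED", , drop = FALSE]
  lapply(split(affected, affected$category), function(df) {
    df <- df[order(-df$delta, df$cpg_id), , drop = FALSE]
    head(df, per_category_k)
  })
}

#' Map CpG sites to their nearest TSS
#'
#' Signed distance is `cpg_pos - tss_pos` on the `+` strand and
#' `tss_pos - cpg_pos` on the `-` strand (positive = downstream of the TSS
#' in the gene's orientation). The nearest gene minimizes `|distance|`
#' (ties broken by lexicographic gene id); a CpG is retained as
#' promoter-proximal iff `|distance| <= window_bp`.
#'
#' @param cpgs data.frame with `cpg_id`, `cpg_chrom` (or `chrom`), `cpg_pos`.
#' @param tss data.frame from [read_tss_bed()].
#' @param window_bp Promoter window around the TSS.
#' @return data.frame with nearest `gene_id`, signed `distance`, `retained`.
#' @export
map_to_promoters <- function(cpgs, tss, window_bp = 2000L) {
  if (nrow(tss) == 0L) stop("empty TSS annotation")
  chrom_col <- if ("cpg_chrom" %in% names(cpgs)) "cpg_chrom" else "chrom"
  out <- cpgs[, c("cpg_id", chrom_col, "cpg_pos")]
  names(out) <- c("cpg_id", "chrom", "cpg_pos")
  out$gene_id <- NA_character_
  out$distance <- NA_integer_
  for (i in seq_len(nrow(out))) {
    cand <- tss[tss$chrom == out$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d_abs <- abs(out$cpg_pos[i] - cand$tss_pos)
    best <- which(d_abs == min(d_abs))
    best <- best[order(cand$gene_id[best])][1L]
    out$gene_id[i] <- cand$gene_id[best]
    out$distance[i] <- if (cand$strand[best] == "+")
      out$cpg_pos[i] - cand$tss_pos[best] else cand$tss_pos[best] - out$cpg_pos[i]
  }
  out$retained <- !is.na(out$distance) & abs(out$distance) <= window_bp
  out
}

#' Call accessibility peaks from a track
#'
#' Fallback peak caller for when no externally called peak set is supplied:
#' maximal runs where the signal is at or above the given quantile of the
#' nonzero track values, with a minimum run length.
#'
#' @param track An `atac_track`.
#' @param quantile_cut Quantile of nonzero values defining the peak
#'   threshold.
#' @param min_len Minimum peak length in bp.
#' @return data.frame with `chrom`, `start0`, `end0` (0-based half-open).
#' @export
call_atac_peaks <- function(track, quantile_cut = 0.95, min_len = 50L) {
  nz <- unlist(lapply(track, function(v) v[v > 0]), use.names = FALSE)
  if (length(nz) == 0L)
    return(data.frame(chrom = character(0), start0 = integer(0), end0 = integer(0)))
  thr <- quantile(nz, quantile_cut, names = FALSE)
  do.call(rbind, lapply(names(track), function(ch) {
    r <- rle(track[[ch]] >= thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len
    data.frame(chrom = rep(ch, sum(keep)), start0 = starts[keep], end0 = ends[keep])
  }))
}

#' Filter SNPs near accessibility peaks
#'
#' A SNP is retained iff it lies within `radius_bp` of any peak interval
#' (peaks are called from the control track when not supplied).
#'
#' @param snps data.frame with `snp_id`, `snp_chrom`, `snp_pos` (1-based).
#' @param atac_control An `atac_track` used for peak calling when `peaks`
#'   is `NULL`.
#' @param radius_bp Retention radius around peaks.
#' @param peaks Optional pre-called peak data.frame (`chrom`, `start0`,
#'   `end0`).
#' @return The retained subset of `snps`.
#' @export
filter_snps_near_peaks <- function(snps, atac_control = NULL, radius_bp = 1000L,
                                   peaks = NULL) {
  if (is.null(peaks)) {
    if (is.null(atac_control)) stop("supply either peaks or a control track")
    peaks <- call_atac_peaks(atac_control)
  }
  if (nrow(peaks) == 0L) return(snps[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(snps)), function(i) {
    pk <- peaks[peaks$chrom == snps$snp_chrom[i], , drop = FALSE]
    if (nrow(pk) == 0L) return(FALSE)
    pos0 <- snps$snp_pos[i] - 1L
    any(pos0 >= pk$start0 - radius_bp & pos0 < pk$end0 + radius_bp)
  }, logical(1))
  snps[keep, , drop = FALSE]
}
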