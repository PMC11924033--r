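# Alignment of recurrent hidden states to genomic coordinates and
# comparison of activation between functional and non-functional regions.

#' Per-cut activation profile of the recurrent encoder
#'
#' For a set of windows, the per-timestep hidden states of the top recurrent
#' layer are summarized as the mean absolute activation over windows and
#' hidden units (absolute value avoids sign cancellation across the two
#' directions), and each cut is mapped to its absolute genomic interval per
#' window.
#'
#' @param model Trained recurrent `methven_model`.
#' @param x Feature array (N x T x F) for the windows.
#' @param windows List of `window_pair` objects (same order as `x`), used
#'   for genomic coordinates.
#' @param plan The `segmentation_plan`.
#' @return An `activation_profile`: list with `a` (length-T vector),
#'   `cut_intervals` (list per window of data.frames with `chrom`, `start0`,
#'   `end0`), and `plan`.
#' @export
activation_profile <- function(model, x, windows, plan) {
  h <- hidden_states(model, x)            # N x T x 2H
  a <- apply(abs(h), 2, mean)
  cut_intervals <- lapply(windows, function(w) {
    data.frame(chrom = w$chrom,
               start0 = w$window_start0 + plan$cuts$start0,
               end0 = w$window_start0 + plan$cuts$end0)
  })
  structure(list(a = a, cut_intervals = cut_intervals, plan = plan),
            class = "activation_profile")
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U with tie correction. The p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values (tie-safe)
#' whenever `choose(nx + ny, nx) <= 20000`, and otherwise by the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return List with `u` (U statistic of `x`), `p_value`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (choose(nx + ny, nx) <= 20000) {
    combos <- combn(nx + ny, nx)
    us <- apply(combos, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
    # two-sided tail, symmetric about nx*ny/2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p <- 1 } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(z, lower.tail = FALSE)
    }
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(u = u, p_value = p, method = method)
}

#' Compare activation between functional and non-functional regions
#'
#' For each region type, cuts overlapping any annotated interval of that
#' type by at least `min_overlap` bp (in any window of the profile) form the
#' in-group; the remaining cuts form the out-group. Per-cut activations of
#' the two groups are compared with the two-sided Mann-Whitney U test; types
#' with an empty group are skipped with a logged reason.
#' Benjamini-Hochberg adjusted p-values are reported alongside raw ones.
#'
#' @param profile An `activation_profile`.
#' @param annotations data.frame from [read_bed_annotations()].
#' @param min_overlap Minimum overlap in bp for a cut to count as inside a
#'   region (default 1).
#' @return data.frame with `region_type`, `n_in`, `n_out`, `u`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_regions <- function(profile, annotations, min_overlap = 1L) {
  types <- sort(unique(annotations$region_type))
  t_cuts <- length(profile$a)
  rows <- lapply(types, function(ty) {
    ann <- annotations[annotations$region_type == ty, , drop = FALSE]
    inside <- rep(FALSE, t_cuts)
    for (ci in profile$cut_intervals) {
      for (k in seq_len(nrow(ann))) {
        if (ann$chrom[k] != ci$chrom[1]) next
        ov <- pmin(ci$end0, ann$end0[k]) - pmax(ci$start0, ann$start0[k])
        inside <- inside | (ov >= min_overlap)
      }
    }
    n_in <- sum(inside); n_out <- t_cuts - n_in
    if (n_in == 0L || n_out == 0L) {
      msg("region type ", ty, " skipped: empty ",
          if (n_in == 0L) "in-group" else "out-group")
      return(NULL)
    }
    mw <- mann_whitney_u(profile$a[inside], profile$a[!inside])
    data.frame(region_type = ty, n_in = n_in, n_out = n_out,
               u = mw$u, p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(region_type = character(0), n_in = integer(0),
                      n_out = integer(0), u = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0)))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
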