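# Construction, class partitioning, chromosome-wise balancing, and splitting
# of SNP-CpG pair datasets.

#' Build labeled SNP-CpG pairs from meQTL records
#'
#' Pairs beyond `max_distance` are dropped. Pairs with distance below 10 kbp
#' form the SMALL class; those with 10 kbp <= distance <= `max_distance` form
#' the LARGE class (the 10 kbp boundary belongs to LARGE). Records with slope
#' exactly 0 have undefined direction and are excluded; the direction label is
#' +1 for positive slope, -1 for negative.
#'
#' Filters log counts and never throw.
#'
#' @param records data.frame from [read_meqtl_table()].
#' @param max_distance Maximum retained SNP-CpG distance in bp.
#' @return data.frame of labeled pairs with `size_class` ("SMALL"/"LARGE")
#'   and `direction_label` (+1/-1) columns.
#' @export
build_pairs <- function(records, max_distance = 100000L) {
  stopifnot(is.data.frame(records), "distance" %in% names(records))
  far <- records$distance > max_distance | records$distance < 1L
  if (any(far)) msg("dropped ", sum(far), " pairs outside [1, ", max_distance, "] bp")
  df <- records[!far, , drop = FALSE]
  zero <- df$slope == 0
  if (any(zero)) msg("excluded ", sum(zero), " pairs with slope == 0 (undefined direction)")
  df <- df[!zero, , drop = FALSE]
  df$size_class <- ifelse(df$distance < 10000L, "SMALL", "LARGE")
  df$direction_label <- ifelse(df$slope > 0, 1L, -1L)
  counts <- table(df$size_class)
  msg("built ", nrow(df), " labeled pairs (",
      paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  rownames(df) <- NULL
  df
}

#' Balance direction classes by chromosome
#'
#' Within each chromosome (and, by default, each size class independently,
#' since each class trains its own model), the majority direction class is
#' down-sampled uniformly at random to the minority count. A chromosome with
#' only one direction present contributes zero pairs. Minority pairs are
#' never removed; survivor order is deterministic given the seed.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param seed Integer seed for the down-sampling.
#' @param by_size_class Balance within each size class separately.
#' @return Balanced data.frame of pairs.
#' @export
balance_by_chromosome <- function(pairs, seed, by_size_class = TRUE) {
  stopifnot(all(c("snp_chrom", "direction_label") %in% names(pairs)))
  group <- if (by_size_class)
    paste(pairs$snp_chrom, pairs$size_class) else pairs$snp_chrom
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), group), function(idx) {
      lab <- pairs$direction_label[idx]
      pos <- idx[lab > 0]; neg <- idx[lab < 0]
      if (length(pos) == 0L || length(neg) == 0L) {
        msg("chromosome group with a single direction class contributes 0 pairs")
        return(integer(0))
      }
      m <- min(length(pos), length(neg))
      c(if (length(pos) > m) sample(pos, m) else pos,
        if (length(neg) > m) sample(neg, m) else neg)
    }), use.names = FALSE)
  })
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split pairs into train/validation/test or k folds
#'
#' Both modes are stratified by `direction_label`. HOLDOUT uses an 8:1:1
#' ratio with exact global sizes `floor(0.8 n)` / `floor(0.1 n)` / remainder.
#' KFOLD produces `k` folds whose sizes differ by at most one. The same seed
#' always yields the same partition.
#'
#' @param pairs data.frame of labeled pairs.
#' @param mode "HOLDOUT" or "KFOLD".
#' @param seed Integer seed.
#' @param k Number of folds for KFOLD.
#' @param fractions Train/validation/test fractions for HOLDOUT.
#' @return For HOLDOUT a list of integer row-index vectors `train`, `val`,
#'   `test`; for KFOLD an integer vector of fold ids (1..k) per row.
#' @export
split_pairs <- function(pairs, mode = c("HOLDOUT", "KFOLD"), seed = 1L,
                        k = 10L, fractions = c(0.8, 0.1, 0.1)) {
  mode <- match.arg(mode)
  n <- nrow(pairs)
  strata <- split(seq_len(n), pairs$direction_label)
  if (mode == "HOLDOUT") {
    stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
    n_train <- floor(fractions[1] * n)
    n_val <- floor(fractions[2] * n)
    with_seed(seed, {
      shuffle <- function(x) x[sample.int(length(x))]
      assign_pool <- lapply(strata, shuffle)
      # per-stratum proportional floor allocation, then top up from the
      # largest strata to hit the exact global sizes
      take <- function(pool, counts) {
        out <- vector("list", length(pool))
        for (i in seq_along(pool)) {
          out[[i]] <- pool[[i]][seq_len(counts[i])]
          pool[[i]] <- pool[[i]][setdiff(seq_along(pool[[i]]), seq_len(counts[i]))]
        }
        list(taken = unlist(out), pool = pool)
      }
      alloc <- function(pool, target) {
        sizes <- lengths(pool)
        counts <- pmin(floor(target * sizes / n), sizes)
        short <- target - sum(counts)
        ord <- order(sizes - counts, decreasing = TRUE)
        j <- 1L
        while (short > 0L) {
          i <- ord[(j - 1L) %% length(pool) + 1L]
          if (counts[i] < length(pool[[i]])) { counts[i] <- counts[i] + 1L; short <- short - 1L }
          j <- j + 1L
        }
        take(pool, counts)
      }
      tr <- alloc(assign_pool, n_train)
      va <- alloc(tr$pool, n_val)
      list(train = sort(tr$taken), val = sort(va$taken),
           test = sort(unlist(va$pool)))
    })
  } else {
    if (n < k) stop("need at least k = ", k, " pairs for KFOLD")
    with_seed(seed, {
      shuffle <- function(x) x[sample.int(length(x))]
      fold <- integer(n)
      cursor <- 0L
      for (idx in lapply(strata, shuffle)) {
        fold[idx] <- (cursor + seq_along(idx) - 1L) %% k + 1L
        cursor <- (cursor + length(idx)) %% k
      }
      fold
    })
  }
}
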