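# Per-cut embedding, average pooling, and concatenation into the model's
# input tensor. Each cut contributes one feature row:
# [pooled pre-allele embedding | pooled post-allele embedding | pooled ATAC].

#' One-hot DNA embedder
#'
#' Maps A, C, G, T to unit basis rows and N to a zero row (embedding width
#' d = 4). This is the ablation embedder for the pre-trained language-model
#' embedding; under mean pooling a cut's one-hot row is its base composition.
#'
#' @return An `embedder`: list with `dim` and `embed(segment)`.
#' @export
onehot_embedder <- function() {
  lut <- matrix(0, nrow = 256, ncol = 4)
  lut[utf8ToInt("A"), 1] <- 1
  lut[utf8ToInt("C"), 2] <- 1
  lut[utf8ToInt("G"), 3] <- 1
  lut[utf8ToInt("T"), 4] <- 1
  ok <- utf8ToInt("ACGTN")
  structure(list(
    dim = 4L,
    name = "onehot",
    embed = function(segment) {
      codes <- utf8ToInt(segment)
      if (!all(codes %in% ok))
        stop("segment contains characters outside {A,C,G,T,N}")
      lut[codes, , drop = FALSE]
    }), class = "embedder")
}

#' Adapt a user-supplied embedding function to the embedder contract
#'
#' Wraps an external per-base embedding hook (for example a pre-trained DNA
#' language model) and validates the shape and finiteness of every returned
#' matrix: one row per input base, `dim` columns.
#'
#' @param hook Function taking a nucleotide string and returning a
#'   (length x dim) numeric matrix.
#' @param dim Declared embedding width of the hook.
#' @param name Label for the embedder.
#' @return An `embedder`.
#' @export
external_lm_embedder <- function(hook, dim, name = "external") {
  stopifnot(is.function(hook), dim >= 1)
  calls <- 0L
  structure(list(
    dim = as.integer(dim),
    name = name,
    embed = function(segment) {
      calls <<- calls + 1L
      m <- hook(segment)
      if (!is.matrix(m) || nrow(m) != nchar(segment) || ncol(m) != dim)
        stop(sprintf("embedding hook returned wrong shape for segment %d: got %s, expected (%d x %d)",
                     calls, paste(dim(m), collapse = " x "), nchar(segment), dim))
      if (!all(is.finite(m)))
        stop("embedding hook returned non-finite values for segment ", calls)
      m
    }), class = "embedder")
}

#' Build the feature tensor for one window
#'
#' For each of the `2n + 3` cuts, the pre- and post-mutation embeddings and
#' the ATAC signal are average-pooled within the cut and concatenated to a
#' row of width `2d + 1`. Ablations zero the corresponding block while
#' keeping the tensor shape fixed: `use_atac = FALSE` zeroes the ATAC
#' column, `use_dna = FALSE` zeroes both embedding blocks.
#'
#' @param window A `window_pair` from [extract_window()].
#' @param plan The matching `segmentation_plan`.
#' @param embedder An `embedder`.
#' @param use_atac,use_dna Ablation flags; both off is an error.
#' @param log1p_atac Apply `log1p` to the ATAC signal before pooling
#'   (default off; raw mean is the canonical pooling).
#' @return Numeric matrix of shape (cuts x `2d + 1`).
#' @export
featurize <- function(window, plan, embedder = onehot_embedder(),
                      use_atac = TRUE, use_dna = TRUE, log1p_atac = FALSE) {
  if (!use_atac && !use_dna)
    stop("at least one of use_atac/use_dna must be on")
  if (nchar(window$pre_seq) != plan$window_len)
    stop("window length does not match the plan")
  d <- embedder$dim
  t_cuts <- nrow(plan$cuts)
  out <- matrix(0, nrow = t_cuts, ncol = 2L * d + 1L)
  if (use_dna) {
    pre_segs <- cut_segments(window$pre_seq, plan)
    post_segs <- cut_segments(window$post_seq, plan)
    for (t in seq_len(t_cuts)) {
      out[t, seq_len(d)] <- colMeans(embedder$embed(pre_segs[[t]]))
      # pre and post differ in one base at most; reuse the pre pooling
      # whenever the cut does not contain the SNP
      if (identical(pre_segs[[t]], post_segs[[t]])) {
        out[t, d + seq_len(d)] <- out[t, seq_len(d)]
      } else {
        out[t, d + seq_len(d)] <- colMeans(embedder$embed(post_segs[[t]]))
      }
    }
  }
  if (use_atac) {
    av <- if (log1p_atac) log1p(window$atac) else window$atac
    atac_segs <- cut_segments(av, plan)
    out[, 2L * d + 1L] <- vapply(atac_segs, mean, numeric(1))
  }
  out
}

#' Featurize a set of pairs into a model-ready array
#'
#' Extracts each pair's window and stacks feature tensors into an array of
#' shape (pairs x cuts x features). Pairs whose window falls outside
#' chromosome bounds are dropped (logged); `kept` indexes the surviving rows
#' of `pairs`.
#'
#' @inheritParams featurize
#' @param pairs data.frame of labeled pairs (one size class).
#' @param genome A `genome_sequence`.
#' @param atac An `atac_track` or `NULL`.
#' @return List with `x` (N x T x F array), `kept` (row indices into
#'   `pairs`), and `snp_cut` (1-based cut index containing each SNP).
#' @export
featurize_pairs <- function(pairs, genome, atac, plan,
                            embedder = onehot_embedder(),
                            use_atac = TRUE, use_dna = TRUE,
                            log1p_atac = FALSE) {
  t_cuts <- nrow(plan$cuts)
  f_dim <- 2L * embedder$dim + 1L
  tensors <- vector("list", nrow(pairs))
  snp_cut <- integer(nrow(pairs))
  kept <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    w <- extract_window(genome, atac, pairs[i, , drop = FALSE], plan)
    if (is.null(w)) next
    tensors[[i]] <- featurize(w, plan, embedder, use_atac, use_dna, log1p_atac)
    snp_cut[i] <- cut_index_of(plan, w$snp_offset)
    kept[i] <- TRUE
  }
  idx <- which(kept)
  x <- array(0, dim = c(length(idx), t_cuts, f_dim))
  for (j in seq_along(idx)) x[j, , ] <- tensors[[idx[j]]]
  list(x = x, kept = idx, snp_cut = snp_cut[idx])
}
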