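# Metrics, cross-validation orchestration, and the decision-tree
# representation probe used for comparing learned embeddings.

#' Classification metrics
#'
#' Hard labels are `score >= threshold`. AUC is the Mann-Whitney rank
#' statistic over scores (ties credited 0.5), equivalent to the area under
#' the ROC curve. With a single observed class the AUC is undefined and
#' returned as `NA` with a warning; the threshold metrics are still
#' computed.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold.
#' @return List with `acc`, `precision`, `recall`, `f1`, `auc`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- mean(pred == labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- if (length(unique(labels)) < 2L) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else {
    rank_auc(scores, labels)
  }
  list(acc = acc, precision = precision, recall = recall, f1 = f1, auc = auc)
}

# AUC as the normalized Mann-Whitney rank-sum statistic; ties get 0.5 credit.
rank_auc <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression metrics
#'
#' RMSE, R-squared (1 - SSres/SStot), and the Pearson correlation
#' coefficient with its two-sided p-value from the t-distribution transform
#' with n - 2 degrees of freedom.
#'
#' @param pred Predicted values.
#' @param target Observed values (non-constant, length >= 3).
#' @return List with `rmse`, `r_squared`, `pcc`, `pcc_pvalue`.
#' @export
regression_metrics <- function(pred, target) {
  stopifnot(length(pred) == length(target), length(pred) >= 3L)
  if (sd(target) == 0) stop("constant target: correlation undefined")
  rmse <- sqrt(mean((pred - target)^2))
  r_squared <- 1 - sum((pred - target)^2) / sum((target - mean(target))^2)
  ct <- cor.test(pred, target, method = "pearson")
  list(rmse = rmse, r_squared = r_squared,
       pcc = unname(ct$estimate), pcc_pvalue = ct$p.value)
}

#' K-fold cross-validation of the model
#'
#' One model is trained per fold on the remaining folds (a slice of the
#' training part is held out as the early-stopping validation set) and
#' evaluated on the left-out fold. Fold seeds are `config$seed + fold`.
#'
#' @param x Feature array (N x T x F).
#' @param y Targets (0/1 for CLASSIFY, slopes for REGRESS).
#' @param config A `model_config`.
#' @param k Number of folds.
#' @param val_fraction Fraction of each training part reserved for early
#'   stopping.
#' @return List with `folds` (per-fold metric rows), `mean`, `sd`, and the
#'   fold assignment.
#' @export
run_cv <- function(x, y, config, k = 10L, val_fraction = 0.1) {
  n <- dim(x)[1]
  if (n < k) stop("fewer samples than folds")
  classify <- config$task == "CLASSIFY"
  strata <- data.frame(direction_label = if (classify) ifelse(y > 0.5, 1L, -1L)
                       else ifelse(y > 0, 1L, -1L))
  fold <- split_pairs(strata, "KFOLD", seed = config$seed, k = k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    n_val <- max(1L, floor(val_fraction * length(train_idx)))
    val_idx <- with_seed(config$seed + f,
                         train_idx[sample.int(length(train_idx), n_val)])
    tr_idx <- setdiff(train_idx, val_idx)
    cfg <- config
    cfg$seed <- config$seed + f
    mdl <- build_model(cfg, dim(x)[2:3])
    mdl <- train_model(mdl, x[tr_idx, , , drop = FALSE], y[tr_idx],
                       x[val_idx, , , drop = FALSE], y[val_idx])
    pred <- predict_model(mdl, x[test_idx, , , drop = FALSE])
    met <- if (classify) classification_metrics(pred, y[test_idx])
           else regression_metrics(pred, y[test_idx])
    rows[[f]] <- as.data.frame(met)
  }
  folds <- do.call(rbind, rows)
  folds$fold <- seq_len(k)
  num <- setdiff(names(folds), "fold")
  list(folds = folds,
       mean = colMeans(folds[num], na.rm = TRUE),
       sd = vapply(folds[num], sd, numeric(1), na.rm = TRUE),
       fold = fold)
}

#' Decision-tree probe of embedding quality
#'
#' The protocol for comparing learned representations across methods: a
#' single decision tree with pinned parameters (Gini impurity, no depth
#' limit beyond the implementation maximum, minimum split 2, deterministic)
#' is trained per fold on the embeddings and evaluated on the left-out fold.
#'
#' @param embeddings Numeric matrix (samples x embedding width), e.g. from
#'   [penultimate()].
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return List with per-fold `folds` data.frame and aggregate `mean`.
#' @export
probe <- function(embeddings, labels, k = 10L, seed = 1L) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) == length(labels),
            all(labels %in% c(0, 1)))
  if (nrow(embeddings) < k) stop("fewer samples than folds")
  strata <- data.frame(direction_label = ifelse(labels > 0.5, 1L, -1L))
  fold <- split_pairs(strata, "KFOLD", seed = seed, k = k)
  df <- as.data.frame(embeddings)
  df$.label <- factor(labels, levels = c(0, 1))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- df[fold != f, , drop = FALSE]
    te <- df[fold == f, , drop = FALSE]
    fit <- rpart::rpart(.label ~ ., data = tr, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          minsplit = 2L, minbucket = 1L, cp = 0,
                          maxdepth = 30L, xval = 0L))
    prob <- predict(fit, te, type = "prob")[, "1"]
    rows[[f]] <- as.data.frame(classification_metrics(prob, labels[fold == f]))
  }
  folds <- do.call(rbind, rows)
  folds$fold <- seq_len(k)
  num <- setdiff(names(folds), "fold")
  list(folds = folds, mean = colMeans(folds[num], na.rm = TRUE), fold = fold)
}
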