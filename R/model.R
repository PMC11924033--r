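# R-level interface to the dual-task recurrent model. The classification and
# regression tasks are independent models with no shared weights.

#' Model configuration
#'
#' Training hyperparameters fixed by the method: Adam with learning rate
#' 0.001, early stopping with patience of 10 epochs, binary cross-entropy
#' loss for CLASSIFY and mean squared error for REGRESS. Architecture sizes
#' are configurable; `use_recurrent = FALSE` replaces the two stacked
#' bidirectional GRU layers with a flatten + dense encoder (ablation).
#'
#' @param task "CLASSIFY" (direction of effect) or "REGRESS" (slope).
#' @param recurrent_hidden GRU units per direction.
#' @param fc_sizes Widths of the two fully connected layers.
#' @param dropout Dropout fraction on the fully connected activations.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param min_epochs Warmup epochs before early stopping may trigger (the
#'   best-epoch weights are still tracked from epoch 1).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed; fully determines initialization and training.
#' @param use_recurrent Use the BiGRU encoder (ablation flag).
#' @param dense_units Encoder width under the dense ablation.
#' @return A `model_config` list.
#' @export
model_config <- function(task = c("CLASSIFY", "REGRESS"),
                         recurrent_hidden = 64L, fc_sizes = c(64L, 16L),
                         dropout = 0.2, learning_rate = 0.001,
                         patience = 10L, min_epochs = 40L,
                         max_epochs = 200L, batch_size = 64L,
                         seed = 1L, use_recurrent = TRUE, dense_units = 128L) {
  task <- match.arg(task)
  stopifnot(length(fc_sizes) == 2L, dropout >= 0, dropout < 1)
  structure(list(task = task, recurrent_hidden = as.integer(recurrent_hidden),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout,
                 learning_rate = learning_rate, patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 use_recurrent = isTRUE(use_recurrent),
                 dense_units = as.integer(dense_units)),
            class = "model_config")
}

cpp_opts <- function(config, input_shape) {
  list(task = config$task, use_recurrent = config$use_recurrent,
       T = as.integer(input_shape[1]), F = as.integer(input_shape[2]),
       hidden = config$recurrent_hidden, fc1 = config$fc_sizes[1],
       fc2 = config$fc_sizes[2], dense_units = config$dense_units,
       learning_rate = config$learning_rate, dropout = config$dropout,
       batch_size = config$batch_size, patience = config$patience,
       min_epochs = config$min_epochs,
       max_epochs = config$max_epochs)
}

#' Build an untrained dual-task model
#'
#' @param config A `model_config`.
#' @param input_shape Integer pair (cuts T, features F).
#' @return A `methven_model`.
#' @export
build_model <- function(config, input_shape) {
  stopifnot(inherits(config, "model_config"), length(input_shape) == 2L,
            all(input_shape >= 1L))
  params <- cpp_init_params(cpp_opts(config, input_shape), config$seed)
  structure(list(config = config, input_shape = as.integer(input_shape),
                 params = params, report = NULL, provenance = "fresh"),
            class = "methven_model")
}

#' @export
print.methven_model <- function(x, ...) {
  cat(sprintf("methven_model [%s] %s encoder, input (%d x %d), %d parameters, %s\n",
              x$config$task,
              if (x$config$use_recurrent) "2x BiGRU" else "dense",
              x$input_shape[1], x$input_shape[2],
              param_count(x), if (is.null(x$report)) "untrained" else "trained"))
  invisible(x)
}

#' Number of model parameters
#' @param model A `methven_model`.
#' @param trainable_only Count only trainable parameters (excludes batch-norm
#'   running statistics).
#' @return Integer count.
#' @export
param_count <- function(model, trainable_only = TRUE) {
  cpp_param_count(model$params, trainable_only)
}

check_x <- function(model, x) {
  if (length(dim(x)) != 3L)
    stop("features must be an (N x T x F) array")
  if (dim(x)[2] != model$input_shape[1] || dim(x)[3] != model$input_shape[2])
    stop(sprintf("feature shape (%d, %d) does not match model input (%d, %d)",
                 dim(x)[2], dim(x)[3], model$input_shape[1], model$input_shape[2]))
  storage.mode(x) <- "double"
  x
}

check_targets <- function(model, y) {
  y <- as.numeric(y)
  if (model$config$task == "CLASSIFY" && !all(y %in% c(0, 1)))
    stop("CLASSIFY targets must be 0/1 (map direction labels with direction_to_target)")
  if (any(!is.finite(y))) stop("non-finite training targets")
  y
}

#' Map direction labels (+1/-1) to classification targets (1/0)
#' @param direction_label Vector of +1/-1 labels.
#' @return Numeric 0/1 vector.
#' @export
direction_to_target <- function(direction_label) {
  stopifnot(all(direction_label %in% c(-1L, 1L)))
  as.numeric(direction_label > 0)
}

#' Train a model with early stopping
#'
#' Minimizes binary cross-entropy (CLASSIFY) or mean squared error (REGRESS)
#' with Adam. Training halts when the validation loss has not improved for
#' `patience` epochs; the best-epoch weights are restored.
#'
#' @param model A `methven_model`.
#' @param x,y Training features (N x T x F) and targets.
#' @param xval,yval Validation features and targets (non-empty).
#' @return The trained model; `$report` holds per-epoch train/validation
#'   losses, `best_epoch`, and `stopped_epoch`.
#' @export
train_model <- function(model, x, y, xval, yval) {
  x <- check_x(model, x); xval <- check_x(model, xval)
  y <- check_targets(model, y); yval <- check_targets(model, yval)
  stopifnot(dim(x)[1] == length(y), dim(xval)[1] == length(yval))
  if (length(yval) == 0L) stop("empty validation set: early stopping undefined")
  fit <- cpp_train(model$params, x, y, xval, yval,
                   cpp_opts(model$config, model$input_shape), model$config$seed)
  model$params <- fit$params
  model$report <- list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                       best_epoch = fit$best_epoch,
                       stopped_epoch = fit$stopped_epoch)
  model
}

#' Fine-tune a trained model on a new dataset
#'
#' Runs the identical training loop initialized from the model's current
#' weights (architecture must match, which is guaranteed by reusing the
#' model object); provenance is recorded.
#'
#' @inheritParams train_model
#' @param max_epochs Optional epoch budget override for the fine-tuning run.
#' @return The fine-tuned model.
#' @export
finetune_model <- function(model, x, y, xval, yval, max_epochs = NULL) {
  if (!is.null(max_epochs)) model$config$max_epochs <- as.integer(max_epochs)
  if (identical(max_epochs, 0L)) {
    model$provenance <- c(model$provenance, "finetuned:0-epochs")
    return(model)
  }
  out <- train_model(model, x, y, xval, yval)
  out$provenance <- c(model$provenance, "finetuned")
  out
}

#' Predict with a model
#'
#' Deterministic at inference (no dropout sampling; batch normalization uses
#' running statistics). CLASSIFY returns probabilities in (0, 1); REGRESS
#' returns slopes.
#'
#' @param model A `methven_model`.
#' @param x Feature array (N x T x F).
#' @return Numeric vector of length N.
#' @export
predict_model <- function(model, x) {
  x <- check_x(model, x)
  out <- cpp_forward(model$params, x,
                     cpp_opts(model$config, model$input_shape), 0L)$output
  as.numeric(out)
}

#' Penultimate-layer embeddings
#'
#' Activations of the layer preceding the output head, used to compare
#' representation quality across methods via a simple probe classifier.
#'
#' @param model A `methven_model`.
#' @param x Feature array (N x T x F).
#' @return Matrix (N x last fully connected width).
#' @export
penultimate <- function(model, x) {
  x <- check_x(model, x)
  cpp_forward(model$params, x, cpp_opts(model$config, model$input_shape), 1L)$penultimate
}

#' Per-timestep hidden states of the top recurrent layer
#'
#' Both directions concatenated. Undefined (error) under the dense-encoder
#' ablation.
#'
#' @param model A `methven_model`.
#' @param x Feature array (N x T x F).
#' @return Array (N x T x 2 * recurrent_hidden).
#' @export
hidden_states <- function(model, x) {
  if (!model$config$use_recurrent)
    stop("hidden states are undefined for the dense-encoder ablation")
  x <- check_x(model, x)
  cpp_forward(model$params, x, cpp_opts(model$config, model$input_shape), 2L)$hidden
}
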