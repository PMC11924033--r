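# Fast structural tests of the network; learnability at scale is covered by
# the acceptance suite.

tiny_cfg <- function(task = "CLASSIFY", ...) {
  defaults <- list(task = task, recurrent_hidden = 4L, fc_sizes = c(6L, 3L),
                   max_epochs = 8L, min_epochs = 0L, batch_size = 8L,
                   seed = 11L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

rand_x <- function(n, t = 9L, f = 5L, seed = 1) {
  set.seed(seed)
  array(rnorm(n * t * f), dim = c(n, t, f))
}

test_that("building is seeded and classification outputs live in (0, 1)", {
  x <- rand_x(6)
  m1 <- build_model(tiny_cfg(), c(9L, 5L))
  m2 <- build_model(tiny_cfg(), c(9L, 5L))
  p1 <- predict_model(m1, x)
  p2 <- predict_model(m2, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  zeros <- array(0, dim = c(3, 9, 5))
  expect_true(all(is.finite(predict_model(m1, zeros))))
  m3 <- build_model(tiny_cfg(seed = 99L), c(9L, 5L))
  expect_false(identical(predict_model(m3, x), p1))
})

test_that("parameter counts match the hand-derived architecture formulas", {
  t_len <- 9L; f_dim <- 5L; h <- 4L; f1 <- 6L; f2 <- 3L
  m <- build_model(tiny_cfg(), c(t_len, f_dim))
  gru <- function(fin) 3 * h * (fin + h + 1)                 # W, U, b per dir
  bn <- function(w) 2 * w                                    # gamma, beta
  want <- bn(t_len * f_dim) +                                # input norm
    2 * gru(f_dim) + 2 * gru(2 * h) +                        # stacked BiGRU
    bn(4 * h) + (4 * h + 1) * f1 + bn(f1) + (f1 + 1) * f2 +  # fc stack
    (f2 + 1) * 1                                             # head
  expect_equal(param_count(m), want)
  dense <- build_model(tiny_cfg(use_recurrent = FALSE, dense_units = 7L),
                       c(t_len, f_dim))
  want_dense <- bn(t_len * f_dim) + (t_len * f_dim + 1) * 7 +
    bn(7) + (7 + 1) * f1 + bn(f1) + (f1 + 1) * f2 + (f2 + 1) * 1
  expect_equal(param_count(dense), want_dense)
  expect_false(param_count(m) == param_count(dense))
})

test_that("prediction is batch-consistent and order-equivariant", {
  x <- rand_x(10)
  m <- build_model(tiny_cfg(), c(9L, 5L))
  batched <- predict_model(m, x)
  single <- vapply(1:10, function(i)
    predict_model(m, x[i, , , drop = FALSE]), numeric(1))
  expect_equal(batched, single, tolerance = 1e-5)
  perm <- sample.int(10)
  expect_equal(predict_model(m, x[perm, , , drop = FALSE]), batched[perm],
               tolerance = 1e-10)
  expect_error(predict_model(m, rand_x(3, t = 8L)), "does not match")
})

test_that("regression to constant targets converges to the constant", {
  x <- rand_x(30, seed = 2)
  # a higher learning rate reaches the constant's offset within the budget
  cfg <- tiny_cfg("REGRESS", max_epochs = 80L, dropout = 0,
                  learning_rate = 0.01, batch_size = 4L)
  m <- build_model(cfg, c(9L, 5L))
  y <- rep(2.5, 30)
  m <- train_model(m, x[1:24, , ], y[1:24], x[25:30, , ], y[25:30])
  pred <- predict_model(m, x[25:30, , ])
  expect_lt(mean((pred - 2.5)^2), 0.05)
})

test_that("early stopping fires patience epochs after the best epoch", {
  x <- rand_x(40, seed = 3)
  y <- rbinom(40, 1, 0.5)
  cfg <- model_config("CLASSIFY", recurrent_hidden = 4L, fc_sizes = c(6L, 3L),
                      max_epochs = 200L, min_epochs = 0L, patience = 4L,
                      batch_size = 8L, seed = 12L)
  # pure-noise labels: validation loss cannot keep improving for long
  m <- train_model(build_model(cfg, c(9L, 5L)),
                   x[1:30, , ], y[1:30], x[31:40, , ], y[31:40])
  expect_lt(m$report$stopped_epoch, 200L)
  expect_equal(m$report$stopped_epoch, m$report$best_epoch + 4L)
  vl <- unlist(m$report$val_loss)
  expect_equal(which.min(vl), m$report$best_epoch)
  expect_error(train_model(build_model(cfg, c(9L, 5L)), x, y,
                           x[0, , , drop = FALSE], numeric(0)), "validation")
})

test_that("training is exactly reproducible for a fixed seed", {
  x <- rand_x(20, seed = 4)
  y <- rbinom(20, 1, 0.5)
  run <- function() {
    m <- train_model(build_model(tiny_cfg(), c(9L, 5L)),
                     x[1:16, , ], y[1:16], x[17:20, , ], y[17:20])
    list(loss = m$report$train_loss, pred = predict_model(m, x))
  }
  expect_identical(run(), run())
})

test_that("penultimate embeddings have the last fc width and drive the head", {
  x <- rand_x(8)
  m <- build_model(tiny_cfg(), c(9L, 5L))
  pen <- penultimate(m, x)
  expect_equal(dim(pen), c(8L, 3L))
  expect_identical(pen, penultimate(m, x))
  # a least-squares refit from the penultimate layer reproduces the logits
  logits <- qlogis(predict_model(m, x))
  fit <- lm.fit(cbind(1, pen), logits)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("hidden states expose per-timestep structure", {
  x <- rand_x(5)
  m <- build_model(tiny_cfg(), c(9L, 5L))
  h <- hidden_states(m, x)
  expect_equal(dim(h), c(5L, 9L, 8L))
  expect_identical(h, hidden_states(m, x))
  # perturbing one input row changes that timestep's hidden state
  x2 <- x
  x2[3, 6, ] <- x2[3, 6, ] + 5
  h2 <- hidden_states(m, x2)
  expect_gt(max(abs(h2[3, 6, ] - h[3, 6, ])), 0)
  expect_equal(h2[1, , ], h[1, , ])        # other samples untouched
  dense <- build_model(tiny_cfg(use_recurrent = FALSE), c(9L, 5L))
  expect_error(hidden_states(dense, x), "dense")
})

test_that("fine-tuning restarts from the trained weights with provenance", {
  x <- rand_x(24, seed = 5)
  y <- as.numeric(x[, 3, 2] > 0)
  cfg <- tiny_cfg(max_epochs = 10L)
  m <- train_model(build_model(cfg, c(9L, 5L)),
                   x[1:16, , ], y[1:16], x[17:24, , ], y[17:24])
  frozen <- finetune_model(m, x[1:16, , ], y[1:16], x[17:24, , ], y[17:24],
                           max_epochs = 0L)
  expect_identical(frozen$params, m$params)
  expect_true("finetuned:0-epochs" %in% frozen$provenance)
  ft <- finetune_model(m, x[1:16, , ], y[1:16], x[17:24, , ], y[17:24],
                       max_epochs = 5L)
  expect_true("finetuned" %in% ft$provenance)
  expect_false(identical(ft$params, m$params))
})

test_that("target validation rejects malformed inputs", {
  x <- rand_x(4)
  m <- build_model(tiny_cfg(), c(9L, 5L))
  expect_error(train_model(m, x, c(0, 1, 2, 1), x, c(0, 1, 0, 1)), "0/1")
  expect_equal(direction_to_target(c(1L, -1L, 1L)), c(1, 0, 1))
  expect_error(direction_to_target(c(1L, 0L)))
})
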