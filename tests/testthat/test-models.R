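test_that("zero-parameter LSTM cell has its closed form", {
  p <- lstm_cell_params(2, 3, zero = TRUE)
  C_prev <- c(1, -2, 0.5)
  out <- lstm_cell_step(p, h_prev = rep(0, 3), C_prev = C_prev,
                        x_t = c(4, -7))
  expect_equal(out$f, rep(0.5, 3))
  expect_equal(out$i, rep(0.5, 3))
  expect_equal(out$o, rep(0.5, 3))
  expect_equal(out$C, 0.5 * C_prev)
  expect_equal(out$h, 0.5 * tanh(0.5 * C_prev))
})

test_that("scalar LSTM cell matches hand arithmetic", {
  # single unit, single input, hand-set weights
  p <- list(W_f = matrix(c(0.5, 1), 2, 1), W_i = matrix(c(-0.3, 0.2), 2, 1),
            W_a = matrix(c(0.1, 0.4), 2, 1), W_o = matrix(c(0.7, -0.2), 2, 1),
            b_f = 0.1, b_i = -0.1, b_a = 0.2, b_o = 0)
  h_prev <- 0.3; C_prev <- -0.2; x <- 0.8
  f <- 1 / (1 + exp(-(0.5 * 0.3 + 1 * 0.8 + 0.1)))
  i <- 1 / (1 + exp(-(-0.3 * 0.3 + 0.2 * 0.8 - 0.1)))
  a <- tanh(0.1 * 0.3 + 0.4 * 0.8 + 0.2)
  o <- 1 / (1 + exp(-(0.7 * 0.3 - 0.2 * 0.8)))
  C <- f * C_prev + i * a
  h <- o * tanh(C)
  out <- lstm_cell_step(p, h_prev, C_prev, x)
  expect_equal(out$h, h, tolerance = 1e-12)
  expect_equal(out$C, C, tolerance = 1e-12)
})

test_that("gate activations are strictly inside (0, 1)", {
  withr::with_seed(3, {
    p <- lstm_cell_params(4, 6)
    out <- lstm_cell_step(p, h_prev = matrix(rnorm(12), 2),
                          C_prev = matrix(rnorm(12), 2),
                          x_t = matrix(rnorm(8), 2))
  })
  for (g in list(out$f, out$i, out$o))
    expect_true(all(g > 0 & g < 1))
  expect_error(lstm_cell_step(p, rep(0, 3), rep(0, 3), rep(0, 4)),
               "shape mismatch")
})

test_that("attention weights form a probability vector over positions", {
  withr::with_seed(4, {
    H <- lapply(1:5, function(t) matrix(rnorm(8 * 3), 8, 3))
    prm <- list(w = rnorm(3), b = 0.2)
  })
  att <- attention_pool(H, prm)
  expect_equal(rowSums(att$weights), rep(1, 8), tolerance = 1e-12)
  expect_true(all(att$weights > 0))

  # equal scores -> uniform weights
  H0 <- lapply(1:4, function(t) matrix(1, 3, 2))
  a0 <- attention_pool(H0, list(w = c(0.3, -0.2), b = 0))
  expect_equal(unname(a0$weights), matrix(0.25, 3, 4), tolerance = 1e-12)

  expect_error(attention_pool(list(), prm), "empty")
})

test_that("a dominant score drives the context to that position", {
  H <- list(matrix(c(1, 0), 1), matrix(c(0, 1), 1))
  # score gap ~20 via direct softmax on synthetic scores
  att <- attention_pool(H, list(w = c(0, 0), b = 0))
  s <- c(20, 0)
  a <- exp(s - max(s)) / sum(exp(s - max(s)))
  V <- a[1] * H[[1]] + a[2] * H[[2]]
  expect_equal(max(abs(V - H[[1]])), 0, tolerance = 1e-8)
})

test_that("model forward pass is a batch of probability vectors", {
  cfg <- train_config(seed = 2)
  m <- build_lstm_attention(5, cfg)
  x <- withr::with_seed(1, array(stats::runif(12 * 3 * 5), c(12, 3, 5)))
  pr <- predict(m, x)
  expect_equal(dim(pr), c(12, 3))
  expect_equal(rowSums(pr), rep(1, 12), tolerance = 1e-9)
})

test_that("parameter count matches the closed-form layer arithmetic", {
  count_lstm <- function(ind, h) 4 * ((ind + h) * h + h)
  expected <- count_lstm(7, 10) + count_lstm(10, 10) + (10 + 1) +
    count_lstm(20, 20) + (20 * 6 + 6) + (6 * 3 + 3)
  expect_equal(n_parameters(build_lstm_attention(7)), expected)
  # plain LSTM drops attention and halves layer-3 input
  expected_plain <- count_lstm(7, 10) + count_lstm(10, 10) +
    count_lstm(10, 20) + (20 * 6 + 6) + (6 * 3 + 3)
  expect_equal(n_parameters(build_lstm(7)), expected_plain)
})

test_that("analytic gradients match finite differences", {
  for (use_att in c(TRUE, FALSE)) {
    cfg <- train_config(lstm_units = c(3, 3, 4), dense_units = 3, seed = 9,
                        l2_scope = "all", l2 = 0.01)
    m <- if (use_att) build_lstm_attention(2, cfg) else build_lstm(2, cfg)
    withr::with_seed(10, {
      x <- array(stats::rnorm(5 * 3 * 2), c(5, 3, 2))
      y <- sample(1:3, 5, replace = TRUE)
      idx <- sample(n_parameters(m), 10)
    })
    lg <- nn_loss_grads(m, x, y)
    flat <- turnload:::flatten_params(m$params)
    g <- turnload:::flatten_params(lg$grads)
    for (j in idx) {
      e <- 1e-5
      up <- flat; up[j] <- up[j] + e
      dn <- flat; dn[j] <- dn[j] - e
      m2 <- m
      m2$params <- turnload:::relist_like(up, m$params)
      l_up <- nn_loss_grads(m2, x, y)$loss
      m2$params <- turnload:::relist_like(dn, m$params)
      l_dn <- nn_loss_grads(m2, x, y)$loss
      num <- (l_up - l_dn) / (2 * e)
      expect_equal(g[j], num, tolerance = 1e-4)
    }
  }
})

test_that("up-sampling balances classes by copying within class", {
  samples <- tibble::tibble(
    sample_id = 1:17,
    class_id = rep(1:3, c(10, 5, 2)),
    steps = lapply(1:17, function(i) matrix(i, 2, 2))
  )
  bal <- upsample_balance(samples, seed = 1)
  expect_equal(unname(c(table(bal$class_id))), c(10, 10, 10))
  # every output sample is a copy of an input of the same class
  for (i in seq_len(nrow(bal))) {
    src <- samples[samples$sample_id == bal$sample_id[i], ]
    expect_equal(bal$class_id[i], src$class_id)
    expect_identical(bal$steps[[i]], src$steps[[1]])
  }
  # already balanced -> unchanged multiset
  even <- samples[c(1:5, 11:15, rep(16:17, c(3, 2))), ]
  bal2 <- upsample_balance(even, seed = 2)
  expect_equal(sort(bal2$sample_id), sort(even$sample_id))
  expect_error(upsample_balance(samples[0, ]), "empty class")
})

test_that("up-sampling preserves per-class means in expectation", {
  samples <- tibble::tibble(
    sample_id = 1:30,
    class_id = rep(1:3, c(18, 8, 4)),
    steps = lapply(withr::with_seed(2, stats::rnorm(30)),
                   function(v) matrix(v, 1, 1))
  )
  true_means <- tapply(vapply(samples$steps, c, numeric(1)),
                       samples$class_id, mean)
  est <- rowMeans(vapply(1:200, function(s) {
    b <- upsample_balance(samples, seed = s)
    tapply(vapply(b$steps, c, numeric(1)), b$class_id, mean)
  }, numeric(3)))
  expect_equal(unname(est), as.numeric(true_means), tolerance = 0.05)
})

test_that("min-max scaling is fitted on train and applied to test", {
  tr <- tibble::tibble(class_id = c(1, 2, 3),
                       steps = list(matrix(c(2, 0), 1), matrix(c(4, 0), 1),
                                    matrix(c(6, 0), 1)))
  te <- tibble::tibble(class_id = 1,
                       steps = list(matrix(c(8, 5), 1)))
  sc <- normalize01(tr, te)
  expect_equal(vapply(sc$train$steps, function(m) m[1, 1], numeric(1)),
               c(0, 0.5, 1))
  # constant feature maps to 0
  expect_true(all(vapply(sc$train$steps, function(m) m[1, 2], numeric(1)) == 0))
  # out-of-range test value exceeds 1, allowed
  expect_equal(sc$apply_to$steps[[1]][1, 1], 1.5)
  expect_error(normalize01(tr[0, ]), "empty")
})

test_that("stratified split is disjoint, exhaustive and seeded", {
  samples <- tibble::tibble(
    sample_id = 1:100,
    class_id = rep(1:3, c(50, 30, 20)),
    steps = lapply(1:100, function(i) matrix(i, 1, 1))
  )
  sp <- split_samples(samples, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), 1:100)
  # stratification preserves class proportions
  expect_equal(unname(c(table(sp$train$class_id))), c(35, 21, 14))
  sp2 <- split_samples(samples, 0.7, seed = 5)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)
  expect_error(split_samples(samples[1:5, ]), "at least 10")
})

test_that("training fits linearly separable classes and respects the epoch cap", {
  withr::with_seed(6, {
    n <- 60
    cls <- rep(1:3, each = n / 3)
    x <- array(0, c(n, 3, 2))
    for (i in seq_len(n)) {
      centre <- switch(cls[i], c(0, 0), c(1, 0), c(0, 1))
      x[i, , ] <- rep(centre, each = 3) + stats::rnorm(6, 0, 0.05)
    }
  })
  samples <- tibble::tibble(
    sample_id = seq_len(60), class_id = cls,
    steps = lapply(seq_len(60), function(i) x[i, , ]))
  cfg <- train_config(seed = 8, val_frac = 0, patience = 50)
  m <- train_model(build_lstm_attention(2, cfg), samples, cfg)
  expect_lte(nrow(m$history), 50)
  pr <- predict(m, samples)
  acc <- mean(max.col(pr) == cls)
  expect_gt(acc, 0.95)
  # loss trends downward over training
  h <- m$history$train_loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
})

test_that("baseline models emit 3-class probabilities and memorise as expected", {
  withr::with_seed(12, {
    samples <- tibble::tibble(
      sample_id = 1:45,
      class_id = rep(1:3, each = 15),
      steps = lapply(rep(1:3, each = 15), function(cl)
        matrix(stats::rnorm(6, cl), 3, 2))
    )
  })
  knn1 <- fit_knn(samples, k = 1)
  pr1 <- predict(knn1, samples)
  expect_equal(max.col(pr1), samples$class_id)  # k=1 memorises
  expect_equal(rowSums(pr1), rep(1, 45))

  # agreement with an established KNN on unambiguous queries (k = 1)
  skip_if_not_installed("class")
  withr::with_seed(13, {
    q <- tibble::tibble(
      sample_id = 1:9, class_id = rep(1:3, 3),
      steps = lapply(rep(1:3, 3), function(cl)
        matrix(stats::rnorm(6, cl, 0.2), 3, 2)))
  })
  ref <- class::knn(turnload:::flatten_steps(samples),
                    turnload:::flatten_steps(q),
                    factor(samples$class_id), k = 1)
  expect_equal(max.col(predict(knn1, q)), as.integer(as.character(ref)))

  rf <- fit_rf(samples, seed = 3, ntree = 50)
  pra <- predict(rf, samples)
  prb <- predict(fit_rf(samples, seed = 3, ntree = 50), samples)
  expect_identical(pra, prb)  # deterministic per seed
  expect_equal(rowSums(pra), rep(1, 45), tolerance = 1e-9)
})

test_that("sequences are contiguous within-turn runs with the turn's label", {
  # two turns with 4 and 5 windows -> 2 + 3 sequences, correct shapes
  lab <- tibble::tibble(
    subject = 1, segment_id = rep(1:2, c(4, 5)),
    class_id = rep(c(1L, 3L), c(4, 5)),
    start_s = c(seq(0, by = 18, length.out = 4),
                seq(200, by = 18, length.out = 5)),
    rmssd = 1:9, sdnn = 9:1)
  sq <- make_sequences(lab, c("rmssd", "sdnn"), seq_len = 3)
  expect_equal(nrow(sq), 5)
  expect_equal(sq$class_id, c(1L, 1L, 3L, 3L, 3L))
  expect_true(all(vapply(sq$steps, nrow, integer(1)) == 3))
  expect_true(all(vapply(sq$steps, ncol, integer(1)) == 2))
  # groups shorter than seq_len contribute nothing
  expect_equal(nrow(make_sequences(lab[1:2, ], c("rmssd"), 3)), 0)
  # single-segment check: 6 consecutive windows -> 4 sequences
  one <- tibble::tibble(subject = 1, segment_id = 1, class_id = 2,
                        start_s = seq(0, by = 18, length.out = 6),
                        rmssd = 1:6, sdnn = 1:6)
  sq1 <- make_sequences(one, c("rmssd", "sdnn"), seq_len = 3)
  expect_equal(nrow(sq1), 4)
  expect_equal(sq1$steps[[1]][, "rmssd"], c(1, 2, 3))
  expect_true(all(sq1$class_id == 2))
})
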