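# Flatten/unflatten parameter trees for the Adam update.
flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_like <- function(flat, template) {
  out <- template
  pos <- 1L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    if (n == 0L) return(x)
    v <- flat[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  walk(out)
}

#' Train a sequence model with Adam and early stopping
#'
#' Minimises cross-entropy (plus the configured L2 penalty) with Adam at the
#' configured learning rate and batch size, for at most `max_epochs` epochs.
#' A stratified validation fraction of the training data is held out; when
#' its loss has not improved for `patience` epochs training stops and the
#' best-validation-loss parameters are restored. With `val_frac = 0` the
#' model trains for the full epoch budget on all data.
#'
#' @param model Untrained model from [build_lstm_attention()] /
#'   [build_lstm()].
#' @param samples Balanced, scaled sequence tibble (`steps`, `class_id`).
#' @param config Optional [train_config()] override; defaults to the model's.
#' @return The model with trained parameters and a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, samples, config = NULL) {
  cfg <- config %||% model$config
  x_all <- as_sequence_array(samples)
  y_all <- as.integer(samples$class_id)

  with_local_seed(cfg$seed, {
    # stratified validation holdout
    if (cfg$val_frac > 0) {
      val_idx <- unlist(lapply(unique(y_all), function(cl) {
        ix <- which(y_all == cl)
        n_val <- max(1L, round(cfg$val_frac * length(ix)))
        if (length(ix) <= n_val) return(integer(0))
        sample(ix, n_val)
      }))
    } else val_idx <- integer(0)
    tr_idx <- setdiff(seq_along(y_all), val_idx)
    x_tr <- x_all[tr_idx, , , drop = FALSE]; y_tr <- y_all[tr_idx]
    has_val <- length(val_idx) > 0
    if (has_val) {
      x_val <- x_all[val_idx, , , drop = FALSE]; y_val <- y_all[val_idx]
    }

    flat <- flatten_params(model$params)
    m_t <- numeric(length(flat)); v_t <- numeric(length(flat))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_val <- Inf; best_flat <- flat; wait <- 0L
    hist <- list()
    n_tr <- length(y_tr)

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        lg <- nn_loss_grads(model, x_tr[b, , , drop = FALSE], y_tr[b])
        if (!is.finite(lg$loss)) abort("training diverged: non-finite loss")
        g <- flatten_params(lg$grads)
        step <- step + 1L
        m_t <- b1 * m_t + (1 - b1) * g
        v_t <- b2 * v_t + (1 - b2) * g^2
        mh <- m_t / (1 - b1^step)
        vh <- v_t / (1 - b2^step)
        flat <- flat - cfg$learning_rate * mh / (sqrt(vh) + eps)
        model$params <- relist_like(flat, model$params)
        ep_loss <- ep_loss + lg$loss * length(b)
      }
      ep_loss <- ep_loss / n_tr
      if (has_val) {
        pv <- nn_forward(model, x_val)$prob
        val_loss <- -mean(log(pv[cbind(seq_along(y_val), y_val)] + 1e-12))
        hist[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss,
                                val_loss = val_loss)
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best_flat <- flat; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      } else {
        hist[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss,
                                val_loss = NA_real_)
        best_flat <- flat
      }
    }
    model$params <- relist_like(best_flat, model$params)
  })
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Fit the non-recurrent baselines and the plain LSTM
#'
#' KNN and random forest operate on the flattened sequence features
#' (`seq_len * n_features` columns); the plain LSTM shares the recurrent
#' architecture minus attention. All three return 3-class probability
#' matrices through `predict()`.
#'
#' @param train Balanced, scaled sequence tibble.
#' @param config A [train_config()].
#' @param k Neighbours for KNN (default 5).
#' @param ntree Trees for the random forest (default 300).
#' @return Named list `knn`, `rf`, `lstm` of fitted models.
#' @export
train_baselines <- function(train, config = train_config(), k = 5,
                            ntree = 300) {
  input_dim <- ncol(train$steps[[1]])
  lstm <- train_model(build_lstm(input_dim, config), train)
  list(
    knn = fit_knn(train, k = k),
    rf = fit_rf(train, seed = config$seed, ntree = ntree),
    lstm = lstm
  )
}

#' k-nearest-neighbour classifier on flattened sequences
#'
#' Stores the flattened training matrix; prediction returns the fraction of
#' the `k` nearest training samples (Euclidean distance) in each class, a
#' proper 3-class probability vector suitable for ROC analysis.
#'
#' @param train Sequence tibble.
#' @param k Number of neighbours.
#' @return Object of class `turnload_knn`.
#' @export
fit_knn <- function(train, k = 5) {
  structure(list(x = flatten_steps(train),
                 y = as.integer(train$class_id), k = k),
            class = c("turnload_knn", "turnload_model"))
}

#' @export
predict.turnload_knn <- function(object, samples, ...) {
  xq <- if (is.matrix(samples)) samples else flatten_steps(samples)
  n <- nrow(xq)
  pr <- matrix(0, n, 3, dimnames = list(NULL, c("climbing", "leveling",
                                                "descending")))
  tr <- object$x
  tr_sq <- rowSums(tr^2)
  for (i in seq_len(n)) {
    d2 <- tr_sq - 2 * as.numeric(tr %*% xq[i, ]) + sum(xq[i, ]^2)
    nb <- order(d2)[seq_len(object$k)]
    tab <- tabulate(object$y[nb], nbins = 3)
    pr[i, ] <- tab / object$k
  }
  pr
}

#' Random-forest classifier on flattened sequences
#'
#' @param train Sequence tibble.
#' @param seed Integer seed (forests are stochastic).
#' @param ntree Number of trees.
#' @return Object of class `turnload_rf` wrapping the fitted forest.
#' @export
fit_rf <- function(train, seed = 1, ntree = 300) {
  x <- flatten_steps(train)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(train$class_id, levels = 1:3)
  with_local_seed(seed, {
    fit <- randomForest::randomForest(x, y, ntree = ntree)
  })
  structure(list(fit = fit, p = ncol(x)),
            class = c("turnload_rf", "turnload_model"))
}

#' @export
predict.turnload_rf <- function(object, samples, ...) {
  xq <- if (is.matrix(samples)) samples else flatten_steps(samples)
  colnames(xq) <- paste0("f", seq_len(ncol(xq)))
  pr <- unname(stats::predict(object$fit, xq, type = "prob"))
  colnames(pr) <- c("climbing", "leveling", "descending")
  pr
}
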