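#' Training configuration for the sequence classifiers
#'
#' Defaults follow the reference regimen: three LSTM layers of 10, 10 and 20
#' units, a 6-unit ReLU dense layer, a 3-unit softmax head, Adam at learning
#' rate 0.005 with batch size 150, at most 50 epochs with early stopping, L2
#' penalty 0.01 on LSTM and dense weights, and a 70/30 train/test split.
#' The validation fraction (15% of training data) and patience (5 epochs) are
#' this package's early-stopping choices.
#'
#' @param lstm_units Integer vector of LSTM layer widths.
#' @param dense_units,output_units Dense layer widths.
#' @param batch_size,learning_rate,max_epochs,l2 Optimiser settings.
#' @param train_frac Training fraction of the train/test split.
#' @param val_frac Fraction of training data held out for early stopping.
#' @param patience Early-stopping patience, epochs.
#' @param seq_len Windows per sequence sample.
#' @param l2_scope Which weight matrices the L2 penalty covers: `"dense"`
#'   (default, the fully connected layers) or `"all"` (LSTM gate kernels
#'   too). At this model size a 0.01 penalty over every LSTM kernel exceeds
#'   the data loss at initialisation and collapses training toward the
#'   uniform predictor, so the dense-only scope is the default.
#' @param seed Integer seed for initialisation and shuffling.
#' @return A list of class `turnload_config`.
#' @export
train_config <- function(lstm_units = c(10, 10, 20), dense_units = 6,
                         output_units = 3, batch_size = 150,
                         learning_rate = 0.005, max_epochs = 50, l2 = 0.01,
                         train_frac = 0.7, val_frac = 0.15, patience = 5,
                         seq_len = 3, l2_scope = c("dense", "all"),
                         seed = 1) {
  l2_scope <- match.arg(l2_scope)
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must lie in (0, 1)")
  if (val_frac < 0 || val_frac >= 1) abort("val_frac must lie in [0, 1)")
  if (any(c(lstm_units, dense_units, output_units, batch_size,
            max_epochs, patience, seq_len) < 1))
    abort("layer sizes, batch size, epochs, patience and seq_len must be positive")
  structure(list(
    lstm_units = lstm_units, dense_units = dense_units,
    output_units = output_units, batch_size = batch_size,
    learning_rate = learning_rate, max_epochs = max_epochs, l2 = l2,
    train_frac = train_frac, val_frac = val_frac, patience = patience,
    seq_len = seq_len, l2_scope = l2_scope, seed = as.integer(seed)
  ), class = "turnload_config")
}

new_nn_model <- function(input_dim, config, use_attention) {
  u <- config$lstm_units
  with_local_seed(config$seed, {
    params <- list(
      lstm1 = lstm_cell_params(input_dim, u[1]),
      lstm2 = lstm_cell_params(u[1], u[2]),
      att = if (use_attention) list(w = as.numeric(glorot(u[2], 1)), b = 0),
      lstm3 = lstm_cell_params(if (use_attention) 2 * u[2] else u[2], u[3]),
      dense1 = list(W = glorot(u[3], config$dense_units),
                    b = rep(0, config$dense_units)),
      dense2 = list(W = glorot(config$dense_units, config$output_units),
                    b = rep(0, config$output_units))
    )
  })
  structure(list(params = params, config = config, input_dim = input_dim,
                 use_attention = use_attention, trained = FALSE,
                 history = NULL),
            class = c(if (use_attention) "turnload_lstm_attention",
                      "turnload_nn", "turnload_model"))
}

#' Build the LSTM-with-self-attention classifier
#'
#' Architecture: two sequence-returning LSTM layers; a self-attention layer
#' pooling the second layer's hidden sequence into a context vector; a
#' concatenate step appending the context vector to each hidden state; a
#' final LSTM layer emitting only its last hidden state; a ReLU dense layer;
#' and a softmax output over the three load classes. L2 weight decay applies
#' to LSTM and dense weight matrices.
#'
#' @param input_dim Features per sequence step.
#' @param config A [train_config()].
#' @return An untrained model object (class `turnload_nn`).
#' @examples
#' m <- build_lstm_attention(7)
#' n_parameters(m)
#' @export
build_lstm_attention <- function(input_dim, config = train_config()) {
  new_nn_model(input_dim, config, use_attention = TRUE)
}

#' Build the plain-LSTM baseline
#'
#' Identical to [build_lstm_attention()] with the attention and concatenate
#' stages removed: the third LSTM layer consumes the second layer's hidden
#' sequence directly.
#'
#' @inheritParams build_lstm_attention
#' @return An untrained model object.
#' @export
build_lstm <- function(input_dim, config = train_config()) {
  new_nn_model(input_dim, config, use_attention = FALSE)
}

#' Number of trainable parameters of a sequence model
#' @param model A model from [build_lstm_attention()] or [build_lstm()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE, use.names = FALSE),
             length, integer(1)))
}

# Forward pass over a batch. x: array [B, T, F]. Returns probabilities and,
# when keep = TRUE, all caches needed for backprop.
nn_forward <- function(model, x, keep = FALSE) {
  p <- model$params
  B <- dim(x)[1]; T_ <- dim(x)[2]
  X <- lapply(seq_len(T_), function(t) matrix(x[, t, ], nrow = B))
  f1 <- lstm_layer_forward(p$lstm1, X)
  f2 <- lstm_layer_forward(p$lstm2, f1$H)
  if (model$use_attention) {
    att <- attention_pool(f2$H, p$att)
    X3 <- lapply(f2$H, function(h) cbind(h, att$context))
  } else {
    att <- NULL
    X3 <- f2$H
  }
  f3 <- lstm_layer_forward(p$lstm3, X3)
  hT <- f3$H[[T_]]
  z1 <- sweep(hT %*% p$dense1$W, 2, p$dense1$b, "+")
  r1 <- pmax(z1, 0)
  logits <- sweep(r1 %*% p$dense2$W, 2, p$dense2$b, "+")
  prob <- softmax_rows(logits)
  if (!keep) return(list(prob = prob))
  list(prob = prob, X = X, f1 = f1, f2 = f2, att = att, X3 = X3, f3 = f3,
       hT = hT, z1 = z1, r1 = r1)
}

# Cross-entropy + L2 loss and full parameter gradients for a batch.
# y: integer labels 1..K.
nn_loss_grads <- function(model, x, y) {
  p <- model$params
  fw <- nn_forward(model, x, keep = TRUE)
  B <- dim(x)[1]; T_ <- dim(x)[2]; K <- ncol(fw$prob)
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
  eps <- 1e-12
  ce <- -mean(log(fw$prob[cbind(seq_len(B), y)] + eps))
  l2 <- model$config$l2
  reg_all <- identical(model$config$l2_scope %||% "dense", "all")
  l2_lstm <- if (reg_all) l2 else 0
  reg_mats <- c(
    list(p$dense1$W, p$dense2$W),
    if (reg_all) list(p$lstm1$W_f, p$lstm1$W_i, p$lstm1$W_a, p$lstm1$W_o,
                      p$lstm2$W_f, p$lstm2$W_i, p$lstm2$W_a, p$lstm2$W_o,
                      p$lstm3$W_f, p$lstm3$W_i, p$lstm3$W_a, p$lstm3$W_o)
  )
  loss <- ce + l2 * sum(vapply(reg_mats, function(m) sum(m^2), numeric(1)))

  dlogits <- (fw$prob - Y) / B
  g_dense2 <- list(W = crossprod(fw$r1, dlogits) + 2 * l2 * p$dense2$W,
                   b = colSums(dlogits))
  dr1 <- dlogits %*% t(p$dense2$W)
  dz1 <- dr1 * (fw$z1 > 0)
  g_dense1 <- list(W = crossprod(fw$hT, dz1) + 2 * l2 * p$dense1$W,
                   b = colSums(dz1))
  dhT <- dz1 %*% t(p$dense1$W)

  dH3 <- lapply(seq_len(T_), function(t) matrix(0, B, ncol(fw$f3$H[[1]])))
  dH3[[T_]] <- dhT
  b3 <- lstm_layer_backward(p$lstm3, fw$X3, fw$f3, dH3)

  if (model$use_attention) {
    u2 <- ncol(fw$f2$H[[1]])
    dH2 <- lapply(b3$dX, function(d) d[, seq_len(u2), drop = FALSE])
    dV <- Reduce(`+`, lapply(b3$dX, function(d)
      d[, u2 + seq_len(u2), drop = FALSE]))
    ab <- attention_backward(fw$f2$H, p$att, fw$att, dV)
    dH2 <- Map(`+`, dH2, ab$dH)
    g_att <- list(w = ab$w, b = ab$b)
  } else {
    dH2 <- b3$dX
    g_att <- NULL
  }
  b2 <- lstm_layer_backward(p$lstm2, fw$f1$H, fw$f2, dH2)
  b1 <- lstm_layer_backward(p$lstm1, fw$X, fw$f1, b2$dX)

  add_l2 <- function(g, lp) {
    for (nm in c("W_f", "W_i", "W_a", "W_o"))
      g[[nm]] <- g[[nm]] + 2 * l2_lstm * lp[[nm]]
    g
  }
  grads <- list(
    lstm1 = add_l2(b1$grads, p$lstm1),
    lstm2 = add_l2(b2$grads, p$lstm2),
    att = g_att,
    lstm3 = add_l2(b3$grads, p$lstm3),
    dense1 = g_dense1, dense2 = g_dense2
  )
  list(loss = loss, ce = ce, grads = grads, prob = fw$prob)
}

#' Class probabilities from a trained sequence model
#'
#' @param object A `turnload_nn` model.
#' @param samples Either a sequence-sample tibble (with a `steps`
#'   list-column, see [make_sequences()]) or a numeric array
#'   `[n, seq_len, features]`.
#' @param ... Unused.
#' @return Matrix `n x 3` of class probabilities (columns: climbing,
#'   leveling, descending).
#' @export
predict.turnload_nn <- function(object, samples, ...) {
  x <- as_sequence_array(samples)
  pr <- nn_forward(object, x)$prob
  colnames(pr) <- c("climbing", "leveling", "descending")
  pr
}

as_sequence_array <- function(samples) {
  if (is.array(samples) && length(dim(samples)) == 3) return(samples)
  if (!is.data.frame(samples) || is.null(samples$steps))
    abort("`samples` must be a sequence tibble with a `steps` column or a 3-d array")
  n <- nrow(samples)
  L <- nrow(samples$steps[[1]]); F_ <- ncol(samples$steps[[1]])
  x <- array(0, c(n, L, F_))
  for (i in seq_len(n)) x[i, , ] <- samples$steps[[i]]
  x
}
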