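sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Construct LSTM cell parameters
#'
#' Weight matrices `W_f`, `W_i`, `W_a`, `W_o` (forget gate, input gate,
#' candidate values, output gate), each of shape
#' `(hidden_dim + input_dim) x hidden_dim` acting on the concatenation
#' `[h_(t-1), x_t]`, with bias vectors `b_f`, `b_i`, `b_a`, `b_o`. Weights
#' are Glorot-uniform; the forget-gate bias starts at 1 so early training
#' retains cell state.
#'
#' @param input_dim,hidden_dim Layer dimensions.
#' @param zero If `TRUE`, all parameters are zero (useful for closed-form
#'   checks).
#' @return Named list of the eight parameter arrays.
#' @export
lstm_cell_params <- function(input_dim, hidden_dim, zero = FALSE) {
  z <- input_dim + hidden_dim
  mk <- function() if (zero) matrix(0, z, hidden_dim) else glorot(z, hidden_dim)
  list(
    W_f = mk(), W_i = mk(), W_a = mk(), W_o = mk(),
    b_f = if (zero) rep(0, hidden_dim) else rep(1, hidden_dim),
    b_i = rep(0, hidden_dim), b_a = rep(0, hidden_dim),
    b_o = rep(0, hidden_dim)
  )
}

#' One LSTM cell step
#'
#' The standard gated recurrence on the concatenated input
#' `z_t = [h_(t-1), x_t]`:
#' forget gate `f_t = sigmoid(W_f z_t + b_f)`, input gate
#' `i_t = sigmoid(W_i z_t + b_i)`, candidate `a_t = tanh(W_a z_t + b_a)`,
#' cell state `C_t = f_t * C_(t-1) + i_t * a_t`, output gate
#' `o_t = sigmoid(W_o z_t + b_o)`, hidden state `h_t = o_t * tanh(C_t)`
#' (all products elementwise).
#'
#' @param params Parameter list from [lstm_cell_params()].
#' @param h_prev,C_prev Previous hidden / cell state: vectors of length
#'   `hidden_dim` or matrices `batch x hidden_dim`.
#' @param x_t Input: vector of length `input_dim` or matrix
#'   `batch x input_dim`.
#' @return List with `h` and `C` (same shape as the states) plus the gate
#'   activations `f`, `i`, `a`, `o`.
#' @examples
#' p <- lstm_cell_params(2, 3, zero = TRUE)
#' lstm_cell_step(p, h_prev = rep(0, 3), C_prev = rep(1, 3), x_t = c(1, -1))$h
#' @export
lstm_cell_step <- function(params, h_prev, C_prev, x_t) {
  vec_in <- is.null(dim(h_prev))
  if (vec_in) {
    h_prev <- matrix(h_prev, 1); C_prev <- matrix(C_prev, 1)
    x_t <- matrix(x_t, 1)
  }
  hd <- ncol(h_prev)
  if (ncol(h_prev) + ncol(x_t) != nrow(params$W_f))
    abort("shape mismatch between states, input and parameters")
  z <- cbind(h_prev, x_t)
  f <- sigmoid(sweep(z %*% params$W_f, 2, params$b_f, "+"))
  i <- sigmoid(sweep(z %*% params$W_i, 2, params$b_i, "+"))
  a <- tanh(sweep(z %*% params$W_a, 2, params$b_a, "+"))
  o <- sigmoid(sweep(z %*% params$W_o, 2, params$b_o, "+"))
  C <- f * C_prev + i * a
  h <- o * tanh(C)
  if (vec_in) {
    h <- drop(h); C <- drop(C); f <- drop(f); i <- drop(i)
    a <- drop(a); o <- drop(o)
  }
  list(h = h, C = C, f = f, i = i, a = a, o = o)
}

# Forward pass of one LSTM layer over a sequence.
# X: list of T matrices [B x input_dim]. Returns hidden sequence and caches.
lstm_layer_forward <- function(lp, X) {
  B <- nrow(X[[1]]); hd <- length(lp$b_f); T_ <- length(X)
  h <- matrix(0, B, hd); C <- matrix(0, B, hd)
  H <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- cbind(h, X[[t]])
    f <- sigmoid(sweep(z %*% lp$W_f, 2, lp$b_f, "+"))
    i <- sigmoid(sweep(z %*% lp$W_i, 2, lp$b_i, "+"))
    a <- tanh(sweep(z %*% lp$W_a, 2, lp$b_a, "+"))
    o <- sigmoid(sweep(z %*% lp$W_o, 2, lp$b_o, "+"))
    C_new <- f * C + i * a
    tC <- tanh(C_new)
    h_new <- o * tC
    cache[[t]] <- list(z = z, f = f, i = i, a = a, o = o,
                       C_prev = C, tC = tC)
    h <- h_new; C <- C_new
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

# Backward pass matching lstm_layer_forward. dH: list of T gradients on the
# hidden outputs (zeros where a step's output is unused).
lstm_layer_backward <- function(lp, X, fwd, dH) {
  T_ <- length(X)
  B <- nrow(X[[1]]); hd <- length(lp$b_f); ind <- ncol(X[[1]])
  g <- list(
    W_f = 0 * lp$W_f, W_i = 0 * lp$W_i, W_a = 0 * lp$W_a, W_o = 0 * lp$W_o,
    b_f = 0 * lp$b_f, b_i = 0 * lp$b_i, b_a = 0 * lp$b_a, b_o = 0 * lp$b_o
  )
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, hd); dC_next <- matrix(0, B, hd)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dH[[t]] + dh_next
    dC <- dC_next + dh * cc$o * (1 - cc$tC^2)
    do_ <- dh * cc$tC
    df <- dC * cc$C_prev
    di <- dC * cc$a
    da <- dC * cc$i
    dC_next <- dC * cc$f
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dza <- da * (1 - cc$a^2)
    dzo <- do_ * cc$o * (1 - cc$o)
    g$W_f <- g$W_f + crossprod(cc$z, dzf)
    g$W_i <- g$W_i + crossprod(cc$z, dzi)
    g$W_a <- g$W_a + crossprod(cc$z, dza)
    g$W_o <- g$W_o + crossprod(cc$z, dzo)
    g$b_f <- g$b_f + colSums(dzf)
    g$b_i <- g$b_i + colSums(dzi)
    g$b_a <- g$b_a + colSums(dza)
    g$b_o <- g$b_o + colSums(dzo)
    dz <- dzf %*% t(lp$W_f) + dzi %*% t(lp$W_i) +
      dza %*% t(lp$W_a) + dzo %*% t(lp$W_o)
    dh_next <- dz[, seq_len(hd), drop = FALSE]
    dX[[t]] <- dz[, hd + seq_len(ind), drop = FALSE]
  }
  list(grads = g, dX = dX)
}

#' Self-attention pooling over a hidden sequence
#'
#' Scores each sequence position of the hidden sequence `H` with
#' `s_i = tanh(w' h_i + b)`, normalises the scores with softmax into weights
#' `a` (a probability vector over positions), and returns the context vector
#' `V = sum_i a_i h_i`.
#'
#' @param H Hidden sequence: a list of `T` matrices `batch x hidden`, or a
#'   single `T x hidden` matrix for one sample.
#' @param params List with `w` (length `hidden`) and scalar `b`.
#' @return List with `weights` (`batch x T`, rows sum to 1) and `context`
#'   (`batch x hidden`).
#' @examples
#' H <- matrix(rnorm(12), 4, 3)
#' att <- attention_pool(H, list(w = rep(0, 3), b = 0))
#' att$weights  # uniform 1/4
#' @export
attention_pool <- function(H, params) {
  single <- is.matrix(H)
  if (single) H <- lapply(seq_len(nrow(H)), function(t) H[t, , drop = FALSE])
  if (length(H) == 0) abort("empty hidden sequence")
  T_ <- length(H); B <- nrow(H[[1]])
  S <- vapply(H, function(h) as.numeric(tanh(h %*% params$w + params$b)),
              numeric(B))
  S <- matrix(S, B, T_)
  A <- softmax_rows(S)
  V <- matrix(0, B, ncol(H[[1]]))
  for (t in seq_len(T_)) V <- V + A[, t] * H[[t]]
  list(weights = A, context = V, scores = S)
}

# Backward pass for attention_pool. dV: [B x hidden]. Returns dH (list) and
# parameter gradients.
attention_backward <- function(H, params, att, dV) {
  T_ <- length(H); B <- nrow(H[[1]]); hd <- ncol(H[[1]])
  A <- att$weights; S <- att$scores
  dA <- vapply(seq_len(T_), function(t) rowSums(dV * H[[t]]), numeric(B))
  dA <- matrix(dA, B, T_)
  dS <- A * (dA - rowSums(A * dA))       # softmax Jacobian, rowwise
  dU <- (1 - S^2) * dS                   # tanh score
  dH <- vector("list", T_)
  dw <- rep(0, hd); db <- 0
  for (t in seq_len(T_)) {
    dH[[t]] <- A[, t] * dV + outer(dU[, t], as.numeric(params$w))
    dw <- dw + as.numeric(crossprod(H[[t]], dU[, t]))
    db <- db + sum(dU[, t])
  }
  list(dH = dH, w = dw, b = db)
}
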