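# LSTM machinery.
#
# A small, self-contained recurrent-network engine on BLAS-backed matrix
# ops: stacked unidirectional or bidirectional LSTM layers with a linear
# head, exact backpropagation through time (returning input gradients, which
# the saliency analysis consumes), inverted dropout between layers, and an
# RMSprop-adapted stochastic gradient descent step. Each LSTM layer carries
# two bias vectors (input-hidden and hidden-hidden), so a layer with input
# width i and h units has 4h(i + h) + 8h trainable scalars.
#
# Sequences are lists of B x width matrices (one per time step); gradients
# are verified against central finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

new_lstm_layer <- function(input_size, hidden_size) {
  k <- 1 / sqrt(hidden_size)
  r <- function(n1, n2) matrix(stats::runif(n1 * n2, -k, k), n1, n2)
  list(Wx = r(input_size, 4 * hidden_size),
       Wh = r(hidden_size, 4 * hidden_size),
       b_ih = stats::runif(4 * hidden_size, -k, k),
       b_hh = stats::runif(4 * hidden_size, -k, k))
}

#' Build a recurrent network
#'
#' `n_layers` stacked LSTM layers (unidirectional or bidirectional) followed
#' by a linear output layer. Weights are initialised uniformly in
#' `[-1/sqrt(h), 1/sqrt(h)]` under the given seed.
#'
#' @param input_size input feature width (e.g. number of selected channels)
#' @param hidden_size LSTM units per layer (per direction if bidirectional)
#' @param n_layers number of stacked LSTM layers
#' @param output_size linear head width
#' @param bidirectional process each sequence in both directions
#' @param seed integer seed for initialisation
#' @return object of class `rnn_model`
#' @export
rnn_model <- function(input_size, hidden_size, n_layers = 2, output_size = 2,
                      bidirectional = FALSE, seed = 1) {
  with_seed(seed, {
    dirs_in <- function(l) if (l == 1) input_size else {
      hidden_size * (1 + bidirectional)
    }
    layers <- lapply(seq_len(n_layers), function(l) {
      if (bidirectional) {
        list(f = new_lstm_layer(dirs_in(l), hidden_size),
             b = new_lstm_layer(dirs_in(l), hidden_size))
      } else {
        list(f = new_lstm_layer(dirs_in(l), hidden_size))
      }
    })
    head_in <- hidden_size * (1 + bidirectional)
    k <- 1 / sqrt(head_in)
    structure(list(layers = layers,
                   head = list(W = matrix(stats::runif(head_in * output_size,
                                                       -k, k),
                                          head_in, output_size),
                               b = stats::runif(output_size, -k, k)),
                   input_size = input_size, hidden_size = hidden_size,
                   n_layers = n_layers, output_size = output_size,
                   bidirectional = bidirectional),
              class = "rnn_model")
  })
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf(
    "<rnn_model> %d x %sLSTM(%d) + linear(%d) on %d inputs: %s parameters\n",
    x$n_layers, if (x$bidirectional) "Bi" else "", x$hidden_size,
    x$output_size, x$input_size,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars, by enumerating every weight matrix and
#' bias vector of the model.
#'
#' @param model an `rnn_model`
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else n <<- n + length(p)
    invisible(NULL)
  }
  walk(model$layers)
  walk(model$head)
  n
}

# ---- single layer forward/backward ---------------------------------------

# X: list of T matrices [B x I]; returns hidden states and a cache for BPTT.
lstm_layer_forward <- function(X, layer, h0 = NULL, c0 = NULL,
                               reverse = FALSE) {
  T_ <- length(X)
  B <- nrow(X[[1]])
  H <- ncol(layer$Wh)
  Hs <- H / 4
  if (reverse) X <- rev(X)
  XX <- do.call(rbind, X)
  XW <- XX %*% layer$Wx
  bias <- matrix(layer$b_ih + layer$b_hh, B, H, byrow = TRUE)
  h <- if (is.null(h0)) matrix(0, B, Hs) else h0
  c <- if (is.null(c0)) matrix(0, B, Hs) else c0
  out <- vector("list", T_)
  gi <- gf <- gg <- go <- cc <- cp <- hp <- vector("list", T_)
  ix <- seq_len(Hs)
  for (t in seq_len(T_)) {
    A <- (XW[(t - 1) * B + seq_len(B), , drop = FALSE] + h %*% layer$Wh) + bias
    i_ <- sigmoid(A[, ix, drop = FALSE])
    f_ <- sigmoid(A[, ix + Hs, drop = FALSE])
    g_ <- tanh(A[, ix + 2 * Hs, drop = FALSE])
    o_ <- sigmoid(A[, ix + 3 * Hs, drop = FALSE])
    cp[[t]] <- c
    hp[[t]] <- h
    c <- f_ * c + i_ * g_
    h <- o_ * tanh(c)
    gi[[t]] <- i_; gf[[t]] <- f_; gg[[t]] <- g_; go[[t]] <- o_
    cc[[t]] <- c
    out[[t]] <- h
  }
  cache <- list(XX = XX, gi = gi, gf = gf, gg = gg, go = go,
                cc = cc, cp = cp, hp = hp, B = B, T_ = T_, Hs = Hs,
                reverse = reverse)
  list(H = if (reverse) rev(out) else out, h_final = h, c_final = c,
       cache = cache)
}

# dH: list of T matrices [B x Hs] (gradient w.r.t. layer outputs).
# Returns parameter gradients and input gradients (time order of the input).
lstm_layer_backward <- function(dH, cache, layer,
                                dh_final = NULL, dc_final = NULL) {
  T_ <- cache$T_; B <- cache$B; Hs <- cache$Hs
  if (cache$reverse) dH <- rev(dH)
  dh_next <- if (is.null(dh_final)) matrix(0, B, Hs) else dh_final
  dc_next <- if (is.null(dc_final)) matrix(0, B, Hs) else dc_final
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  dA_all <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    dh <- dH[[t]] + dh_next
    tc <- tanh(cache$cc[[t]])
    o_ <- cache$go[[t]]; i_ <- cache$gi[[t]]
    f_ <- cache$gf[[t]]; g_ <- cache$gg[[t]]
    do_ <- dh * tc
    dc <- dh * o_ * (1 - tc^2) + dc_next
    di <- dc * g_
    df <- dc * cache$cp[[t]]
    dg <- dc * i_
    dA <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_))
    dA_all[[t]] <- dA
    dWh <- dWh + crossprod(cache$hp[[t]], dA)
    dh_next <- dA %*% t(layer$Wh)
    dc_next <- dc * f_
  }
  DA <- do.call(rbind, dA_all)
  dWx <- crossprod(cache$XX, DA)
  db <- colSums(DA)
  dX_flat <- DA %*% t(layer$Wx)
  dX <- lapply(seq_len(T_), function(t) {
    dX_flat[(t - 1) * B + seq_len(B), , drop = FALSE]
  })
  if (cache$reverse) dX <- rev(dX)
  list(grads = list(Wx = dWx, Wh = dWh, b_ih = db, b_hh = db),
       dX = dX, dh0 = dh_next, dc0 = dc_next)
}

# ---- full network forward/backward ---------------------------------------

#' Forward pass of a recurrent network
#'
#' @param model an `rnn_model`
#' @param X list of `T` input matrices (`B x input_size`), or a single
#'   `T x input_size` matrix (treated as batch size 1)
#' @param state optional list of per-layer `(h, c)` pairs to start from
#'   (unidirectional models only); default zero state
#' @param dropout inverted-dropout probability applied between LSTM layers
#'   (training only; masks drawn from the current RNG)
#' @param keep_cache retain the quantities needed by [rnn_backward()]
#' @return list with `Y` (list of `B x output_size` logits per step),
#'   `state` (final per-layer states), and `cache` if requested
#' @export
rnn_forward <- function(model, X, state = NULL, dropout = 0,
                        keep_cache = FALSE) {
  if (is.matrix(X)) X <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  T_ <- length(X)
  B <- nrow(X[[1]])
  inp <- X
  caches <- vector("list", model$n_layers)
  masks <- vector("list", model$n_layers)
  new_state <- vector("list", model$n_layers)
  for (l in seq_len(model$n_layers)) {
    st <- if (!is.null(state)) state[[l]] else NULL
    fwd <- lstm_layer_forward(inp, model$layers[[l]]$f,
                              h0 = st$h, c0 = st$c, reverse = FALSE)
    if (model$bidirectional) {
      bwd <- lstm_layer_forward(inp, model$layers[[l]]$b, reverse = TRUE)
      out <- lapply(seq_len(T_), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
      caches[[l]] <- list(f = fwd$cache, b = bwd$cache)
    } else {
      out <- fwd$H
      caches[[l]] <- list(f = fwd$cache)
      new_state[[l]] <- list(h = fwd$h_final, c = fwd$c_final)
    }
    if (dropout > 0 && l < model$n_layers) {
      masks[[l]] <- lapply(seq_len(T_), function(t) {
        matrix(stats::rbinom(length(out[[t]]), 1, 1 - dropout),
               nrow(out[[t]])) / (1 - dropout)
      })
      out <- lapply(seq_len(T_), function(t) out[[t]] * masks[[l]][[t]])
    }
    inp <- out
  }
  HH <- do.call(rbind, inp)
  YY <- HH %*% model$head$W +
    matrix(model$head$b, nrow(HH), model$output_size, byrow = TRUE)
  Y <- lapply(seq_len(T_), function(t) YY[(t - 1) * B + seq_len(B), ,
                                          drop = FALSE])
  res <- list(Y = Y, state = if (!model$bidirectional) new_state else NULL)
  if (keep_cache) {
    res$cache <- list(layer_caches = caches, masks = masks, HH = HH,
                      T_ = T_, B = B, dropout = dropout)
  }
  res
}

#' Backward pass (backpropagation through time)
#'
#' Given output-logit gradients, computes gradients for every parameter and
#' for the inputs.
#'
#' @param model an `rnn_model`
#' @param cache the cache from `rnn_forward(..., keep_cache = TRUE)`
#' @param dY list of `T` gradient matrices (`B x output_size`)
#' @return list with `grads` (mirroring the model's parameter structure)
#'   and `dX` (list of `T` input-gradient matrices)
#' @export
rnn_backward <- function(model, cache, dY) {
  T_ <- cache$T_; B <- cache$B
  DY <- do.call(rbind, dY)
  grads <- list(layers = vector("list", model$n_layers),
                head = list(W = crossprod(cache$HH, DY), b = colSums(DY)))
  dH_flat <- DY %*% t(model$head$W)
  dH <- lapply(seq_len(T_), function(t) dH_flat[(t - 1) * B + seq_len(B), ,
                                                drop = FALSE])
  Hs <- model$hidden_size
  for (l in rev(seq_len(model$n_layers))) {
    if (cache$dropout > 0 && l < model$n_layers) {
      dH <- lapply(seq_len(T_), function(t) dH[[t]] * cache$masks[[l]][[t]])
    }
    if (model$bidirectional) {
      dHf <- lapply(dH, function(m) m[, seq_len(Hs), drop = FALSE])
      dHb <- lapply(dH, function(m) m[, Hs + seq_len(Hs), drop = FALSE])
      bf <- lstm_layer_backward(dHf, cache$layer_caches[[l]]$f,
                                model$layers[[l]]$f)
      bb <- lstm_layer_backward(dHb, cache$layer_caches[[l]]$b,
                                model$layers[[l]]$b)
      grads$layers[[l]] <- list(f = bf$grads, b = bb$grads)
      dH <- lapply(seq_len(T_), function(t) bf$dX[[t]] + bb$dX[[t]])
    } else {
      bf <- lstm_layer_backward(dH, cache$layer_caches[[l]]$f,
                                model$layers[[l]]$f)
      grads$layers[[l]] <- list(f = bf$grads)
      dH <- bf$dX
    }
  }
  list(grads = grads, dX = dH)
}

# ---- optimiser ------------------------------------------------------------

# RMSprop-adapted SGD: v <- alpha v + (1 - alpha) g^2;
# p <- p - lr g / (sqrt(v) + eps).
rmsprop_init <- function(params) {
  if (is.list(params)) lapply(params, rmsprop_init) else params * 0
}

rmsprop_step <- function(params, grads, v, lr = 1e-3, alpha = 0.99,
                         eps = 1e-8) {
  if (is.list(params)) {
    upd <- Map(rmsprop_step, params, grads, v,
               MoreArgs = list(lr = lr, alpha = alpha, eps = eps))
    return(list(params = lapply(upd, `[[`, "params"),
                v = lapply(upd, `[[`, "v")))
  }
  v <- alpha * v + (1 - alpha) * grads^2
  list(params = params - lr * grads / (sqrt(v) + eps), v = v)
}

# Apply one optimiser step to a model's parameters in place.
apply_update <- function(model, grads, opt, lr) {
  upd_l <- rmsprop_step(model$layers, grads$layers, opt$layers, lr = lr)
  upd_h <- rmsprop_step(model$head, grads$head, opt$head, lr = lr)
  model$layers <- upd_l$params
  model$head <- upd_h$params
  list(model = model, opt = list(layers = upd_l$v, head = upd_h$v))
}

# Single-step forward for streaming prediction (unidirectional models).
# x is one input vector; state a list of per-layer (h, c). Arithmetic
# matches lstm_layer_forward exactly, so streaming equals batch processing.
rnn_step <- function(model, x, state = NULL) {
  stopifnot(!model$bidirectional)
  Hs <- model$hidden_size
  if (is.null(state)) {
    state <- lapply(seq_len(model$n_layers),
                    function(l) list(h = matrix(0, 1, Hs),
                                     c = matrix(0, 1, Hs)))
  }
  inp <- matrix(x, 1)
  ix <- seq_len(Hs)
  for (l in seq_len(model$n_layers)) {
    ly <- model$layers[[l]]$f
    A <- (inp %*% ly$Wx + state[[l]]$h %*% ly$Wh) +
      matrix(ly$b_ih + ly$b_hh, 1)
    i_ <- sigmoid(A[, ix, drop = FALSE])
    f_ <- sigmoid(A[, ix + Hs, drop = FALSE])
    g_ <- tanh(A[, ix + 2 * Hs, drop = FALSE])
    o_ <- sigmoid(A[, ix + 3 * Hs, drop = FALSE])
    c_ <- f_ * state[[l]]$c + i_ * g_
    h_ <- o_ * tanh(c_)
    state[[l]] <- list(h = h_, c = c_)
    inp <- h_
  }
  logits <- (inp %*% model$head$W + matrix(model$head$b, 1))[1, ]
  list(logits = logits, state = state)
}
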