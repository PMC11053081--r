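# Recurrent-network engine: parameter accounting, gradients, determinism.

test_that("parameter counts match the closed-form per-layer formula", {
  # a layer with input i and h units has 4h(i+h) + 8h parameters
  layer_count <- function(i, h) 4 * h * (i + h) + 8 * h
  m1 <- rnn_model(1, 1, n_layers = 1, output_size = 1)
  expect_equal(count_parameters(m1), layer_count(1, 1) + 1 * 1 + 1)
  # the layer alone: 16 scalars for i = h = 1
  expect_equal(layer_count(1, 1), 16)

  m2 <- rnn_model(5, 8, n_layers = 2, output_size = 3)
  expect_equal(count_parameters(m2),
               layer_count(5, 8) + layer_count(8, 8) + 8 * 3 + 3)
  m3 <- rnn_model(5, 8, n_layers = 2, output_size = 3, bidirectional = TRUE)
  expect_equal(count_parameters(m3),
               2 * layer_count(5, 8) + 2 * layer_count(16, 8) + 16 * 3 + 3)
})

test_that("backpropagation matches central finite differences", {
  for (bidir in c(FALSE, TRUE)) {
    m <- rnn_model(3, 4, n_layers = 2, output_size = 2,
                   bidirectional = bidir, seed = 9)
    set.seed(4)
    X <- lapply(1:5, function(t) matrix(rnorm(6), 2, 3))
    dY <- lapply(1:5, function(t) matrix(rnorm(4), 2, 2))
    loss <- function(mm) {
      sum(mapply(function(y, d) sum(y * d), rnn_forward(mm, X)$Y, dY))
    }
    fw <- rnn_forward(m, X, keep_cache = TRUE)
    bk <- rnn_backward(m, fw$cache, dY)
    eps <- 1e-6
    # every parameter tensor, one sampled element each
    for (l in 1:2) for (d in names(m$layers[[l]])) {
      for (nm in c("Wx", "Wh", "b_ih")) {
        m1 <- m; m2 <- m
        m1$layers[[l]][[d]][[nm]][2] <- m1$layers[[l]][[d]][[nm]][2] + eps
        m2$layers[[l]][[d]][[nm]][2] <- m2$layers[[l]][[d]][[nm]][2] - eps
        num <- (loss(m1) - loss(m2)) / (2 * eps)
        expect_equal(bk$grads$layers[[l]][[d]][[nm]][2], num,
                     tolerance = 1e-4)
      }
    }
    m1 <- m; m1$head$W[1] <- m1$head$W[1] + eps
    m2 <- m; m2$head$W[1] <- m2$head$W[1] - eps
    expect_equal(bk$grads$head$W[1], (loss(m1) - loss(m2)) / (2 * eps),
                 tolerance = 1e-4)
    # input gradients
    X1 <- X; X1[[3]][1, 2] <- X1[[3]][1, 2] + eps
    X2 <- X; X2[[3]][1, 2] <- X2[[3]][1, 2] - eps
    num <- (sum(mapply(function(y, d) sum(y * d), rnn_forward(m, X1)$Y, dY)) -
              sum(mapply(function(y, d) sum(y * d),
                         rnn_forward(m, X2)$Y, dY))) / (2 * eps)
    expect_equal(bk$dX[[3]][1, 2], num, tolerance = 1e-4)
  }
})

test_that("single-step streaming prediction equals the batched forward pass", {
  m <- rnn_model(5, 7, n_layers = 2, output_size = 2, seed = 2)
  set.seed(1)
  Xm <- matrix(rnorm(100), 20, 5)
  fw <- rnn_forward(m, Xm)
  st <- NULL
  for (t in 1:20) {
    r <- ecogspeech:::rnn_step(m, Xm[t, ], st)
    st <- r$state
    expect_equal(r$logits, fw$Y[[t]][1, ], tolerance = 1e-12)
  }
})

test_that("initialisation and dropout are seed-deterministic", {
  expect_identical(rnn_model(4, 6, seed = 3), rnn_model(4, 6, seed = 3))
  expect_false(identical(rnn_model(4, 6, seed = 3),
                         rnn_model(4, 6, seed = 4)))
  m <- rnn_model(3, 4, seed = 1)
  X <- lapply(1:4, function(t) matrix(1, 1, 3))
  set.seed(5); a <- rnn_forward(m, X, dropout = 0.5)$Y
  set.seed(5); b <- rnn_forward(m, X, dropout = 0.5)$Y
  set.seed(6); c <- rnn_forward(m, X, dropout = 0.5)$Y
  expect_identical(a, b)
  expect_false(identical(a, c))
})
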