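# Architecture: shape contracts, attention fidelity, parameter economy,
# and an end-to-end finite-difference gradient check.

test_that("dsconv_param_count follows the closed forms", {
  expect_equal(dsconv_param_count(16, 32, 3),
               c(dsconv = 944, standard = 13824))
  expect_equal(dsconv_param_count(1, 1, 1), c(dsconv = 2, standard = 1))
  r <- dsconv_param_count(64, 128, 3)
  expect_equal(unname(r["dsconv"] / r["standard"]), 1 / 128 + 1 / 27,
               tolerance = 1e-12)
  # economy holds at every encoder stage of the default configuration
  ch <- c(16, 32, 64, 128, 256)
  for (k in 1:4) {
    r <- dsconv_param_count(ch[k], ch[k + 1], 3)
    expect_lt(r["dsconv"], r["standard"])
  }
})

test_that("net_config validates its invariants", {
  expect_error(net_config(input_size = c(100, 64, 16)), "divisible by 16")
  expect_error(net_config(stage_channels = c(32, 64, 128, 512)), "doubling chain")
  expect_error(net_config(input_size = c(48, 48, 32)), "divisible by n_heads")
  cfg <- net_config(input_size = c(64, 64, 16))
  expect_identical(bottleneck_shape(cfg), c(4L, 4L, 1L, 256L))
  expect_identical(token_shape(cfg), c(256L, 16L))
  # canonical configuration, checked structurally
  canon <- net_config()
  expect_identical(bottleneck_shape(canon), c(16L, 16L, 2L, 256L))
  expect_identical(token_shape(canon), c(256L, 512L))
})

test_that("encoder produces the contracted bottleneck and four skips", {
  cfg <- net_config(input_size = c(64, 64, 16), dropout = 0)
  model <- init_network(cfg, 1)
  set.seed(2)
  x <- array(runif(64 * 64 * 16), c(64, 64, 16))
  enc <- encode(model, x)
  expect_identical(dim(enc$bottleneck), c(4L, 4L, 1L, 256L))
  expect_length(enc$skips, 4)
  expect_identical(dim(enc$skips[[1]]), c(64L, 64L, 16L, 32L))
  expect_identical(dim(enc$skips[[4]]), c(8L, 8L, 2L, 256L))
  expect_error(encode(model, array(0, c(48, 64, 16))), "does not match")
  expect_error(encode(model, array(0, c(100, 64, 16))), "not divisible by 16")
})

test_that("tokenize yields C' tokens of dimension N and validates channels", {
  cfg <- net_config(input_size = c(64, 64, 16), dropout = 0)
  model <- init_network(cfg, 1)
  set.seed(3)
  x <- array(runif(64 * 64 * 16), c(64, 64, 16))
  enc <- encode(model, x)
  tok <- tokenize(model, enc$bottleneck)
  expect_identical(dim(tok), c(256L, 16L))
  expect_error(tokenize(model, array(0, c(4, 4, 1, 128))), "requires 256")
  # with zero positional embedding and identity projection, tokenize is a
  # pure reshape: token t is channel t's flattened spatial map
  m2 <- model
  m2$params$pos[] <- 0
  m2$params$proj$pw <- diag(256)
  m2$params$proj$b[] <- 0
  tok2 <- tokenize(m2, enc$bottleneck)
  expect_equal(tok2[5, ], as.vector(enc$bottleneck[, , , 5]), tolerance = 1e-12)
})

test_that("multi-head attention equals the term-by-term oracle", {
  set.seed(4)
  N <- 8; n_heads <- 2
  p <- list(Wq = matrix(rnorm(N * N), N), Wk = matrix(rnorm(N * N), N),
            Wv = matrix(rnorm(N * N), N), Wo = matrix(rnorm(N * N), N))
  Q <- matrix(rnorm(4 * N), 4); K <- matrix(rnorm(4 * N), 4); V <- matrix(rnorm(4 * N), 4)
  out <- multi_head_attention(Q, K, V, p, n_heads)
  expect_equal(out, bf_multi_head_attention(Q, K, V, p, n_heads), tolerance = 1e-6)
  expect_error(multi_head_attention(Q, K[, 1:4], V, p, n_heads), "model dimension")
})

test_that("attention rows are a probability distribution; degenerate cases behave", {
  set.seed(5)
  N <- 8
  p <- list(Wq = matrix(rnorm(N * N), N), Wk = matrix(rnorm(N * N), N),
            Wv = matrix(rnorm(N * N), N), Wo = matrix(rnorm(N * N), N))
  X <- matrix(rnorm(6 * N), 6)
  att <- adrenalseg:::mha_fwd(X, X, X, p, 2L)
  for (A in att$cache$A) {
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  }
  # all keys identical -> uniform attention rows
  Xc <- matrix(rep(rnorm(N), each = 6), 6)
  attc <- adrenalseg:::mha_fwd(X, Xc, X, p, 2L)
  for (A in attc$cache$A) {
    expect_equal(A, matrix(1 / 6, 6, 6), tolerance = 1e-9)
  }
  # a single key-value pair: softmax over one element is 1, so the output
  # ignores Q entirely
  v1 <- matrix(rnorm(N), 1)
  q1 <- matrix(rnorm(N), 1); q2 <- matrix(rnorm(N), 1)
  expect_equal(multi_head_attention(q1, v1, v1, p, 2L),
               multi_head_attention(q2, v1, v1, p, 2L), tolerance = 1e-12)
})

test_that("transformer stack: ablation identity, shape preservation, parameter count", {
  set.seed(6)
  N <- 16
  layers <- lapply(1:4, function(l) adrenalseg:::tf_layer_init(N, 4L))
  tokens <- matrix(rnorm(32 * N), 32)
  expect_identical(transformer_stack(tokens, layers, n_layers = 0L), tokens)
  out <- transformer_stack(tokens, layers, n_layers = 4L, n_heads = 8L)
  expect_identical(dim(out), dim(tokens))
  expect_error(transformer_stack(tokens, layers, n_layers = -1L), "non-negative")
  expect_error(transformer_stack(tokens, layers, n_layers = 6L), "available")
  # analytic per-layer count (attention + 2 layer norms + FFN)
  expect_equal(adrenalseg:::param_sum(layers[[1]], length), bf_tf_layer_params(N, 4))
  model <- init_network(net_config(input_size = c(64, 64, 16), dropout = 0), 1)
  expect_equal(adrenalseg:::param_sum(model$params$tf, length),
               4 * bf_tf_layer_params(16, 4))
})

test_that("full forward preserves the grid and emits probabilities", {
  model <- tiny_net()
  set.seed(7)
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  prob <- net_forward(model, x)
  expect_identical(dim(prob), c(32L, 32L, 16L))
  expect_true(min(prob) >= 0 && max(prob) <= 1)
  # zeroed head -> sigmoid(0) = 0.5 everywhere
  m0 <- model
  m0$params$head$pw[] <- 0
  m0$params$head$b[] <- 0
  expect_true(all(net_forward(m0, x) == 0.5))
})

test_that("ablated variants run end-to-end and shrink the parameter count", {
  set.seed(8)
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  full <- init_network(net_config(input_size = c(32, 32, 16), stem_channels = 2,
                                  n_heads = 2, dropout = 0), 1)
  no_tf <- init_network(net_config(input_size = c(32, 32, 16), stem_channels = 2,
                                   use_transformer = FALSE, dropout = 0), 1)
  plain <- init_network(net_config(input_size = c(32, 32, 16), stem_channels = 2,
                                   use_transformer = FALSE, use_skip = FALSE,
                                   dropout = 0), 1)
  for (m in list(no_tf, plain)) {
    p <- net_forward(m, x)
    expect_identical(dim(p), dim(x))
  }
  expect_lt(n_parameters(no_tf), n_parameters(full))
  expect_lt(n_parameters(plain), n_parameters(no_tf))
  # the ED-only variant has no transformer parameter groups at all
  expect_false(any(c("proj", "pos", "tf") %in% names(plain$params)))
})

test_that("backward gradients match central finite differences", {
  model <- tiny_net()
  set.seed(9)
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  target <- array(0, c(32, 32, 16)); target[10:15, 10:15, 5:9] <- 1
  loss_fn <- function(m) {
    dice_loss(adrenalseg:::plogis_arr(adrenalseg:::net_forward_cache(m, x)$logits), target)
  }
  fwd <- adrenalseg:::net_forward_cache(model, x)
  prob <- adrenalseg:::plogis_arr(fwd$logits)
  gl <- adrenalseg:::dice_loss_grad(prob, target) * prob * (1 - prob)
  grads <- adrenalseg:::net_backward(model, fwd$cache, gl)

  # gradient flows to the positional embedding
  expect_gt(sqrt(sum(grads$pos^2)), 0)

  paths <- list(list("stem", "dw"), list("enc", 2L, "u1", "pw"),
                list("enc", 3L, "down", "w"), list("tf", 1L, "att", "Wq"),
                list("tf", 4L, "ffn", "W1"), list("dec", 1L, "up", "W"),
                list("dec", 4L, "fuse", "dw"), list("head", "pw"))
  get <- function(tree, path) { for (k in path) tree <- tree[[k]]; tree }
  setp <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- setp(tree[[path[[1]]]], path[-1], val)
    tree
  }
  eps <- 1e-6
  for (pa in paths) {
    arr <- get(model$params, pa)
    ga <- get(grads, pa)
    expect_gt(length(arr), 0)   # guard: the path must resolve to parameters
    set.seed(sum(utf8ToInt(paste(unlist(pa), collapse = ""))))
    for (i in sample(length(arr), 2)) {
      m2 <- model
      a <- arr; a[i] <- arr[i] + eps
      m2$params <- setp(m2$params, pa, a)
      lp <- loss_fn(m2)
      a[i] <- arr[i] - eps
      m2$params <- setp(m2$params, pa, a)
      lm <- loss_fn(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_equal(ga[i], fd, tolerance = 1e-3,
                   label = paste("analytic grad at", paste(pa, collapse = "/")))
    }
  }
})

test_that("checkpoints round-trip through save_model/load_model", {
  model <- tiny_net()
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  set.seed(10)
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  expect_identical(net_forward(back, x), net_forward(model, x))
  bad <- tempfile(fileext = ".rds"); saveRDS(1:3, bad)
  expect_error(load_model(bad), "not a model checkpoint")
})
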