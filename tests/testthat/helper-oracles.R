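# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the implementation.

# All-pairs directed Hausdorff / average surface distance on point matrices.
bf_directed_min <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt(colSums((t(b) - a[i, ])^2)))
  }, numeric(1))
}

bf_hausdorff <- function(a, b) {
  max(max(bf_directed_min(a, b)), max(bf_directed_min(b, a)))
}

bf_asd <- function(a, b) mean(bf_directed_min(a, b))

# Exact-counting overlap metrics on binary arrays.
bf_dice <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(1)
  2 * sum(x & y) / (sum(x) + sum(y))
}
bf_iou <- function(x, y) {
  if (sum(x | y) == 0) return(1)
  sum(x & y) / sum(x | y)
}
bf_mae <- function(x, y) mean(abs(x - y))

# Term-by-term evaluation of scaled dot-product multi-head attention with
# explicit loops: head_h = softmax(Q Wq_h (K Wk_h)^T / sqrt(d)) V Wv_h,
# concatenated then multiplied by Wo.
bf_multi_head_attention <- function(Q, K, V, p, n_heads) {
  N <- ncol(Q)
  d <- N / n_heads
  S <- nrow(Q)
  Sk <- nrow(K)
  heads <- matrix(0, S, 0)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    Qh <- Q %*% p$Wq[, cols]
    Kh <- K %*% p$Wk[, cols]
    Vh <- V %*% p$Wv[, cols]
    Oh <- matrix(0, S, d)
    for (i in seq_len(S)) {
      scores <- numeric(Sk)
      for (j in seq_len(Sk)) scores[j] <- sum(Qh[i, ] * Kh[j, ]) / sqrt(d)
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      for (j in seq_len(Sk)) Oh[i, ] <- Oh[i, ] + w[j] * Vh[j, ]
    }
    heads <- cbind(heads, Oh)
  }
  heads %*% p$Wo
}

# Analytic per-layer transformer parameter count: 4 N^2 attention weights,
# two layer norms, and the two FFN linears with biases.
bf_tf_layer_params <- function(N, ffn_ratio) {
  4 * N^2 + 2 * (2 * N) + (N * ffn_ratio * N + ffn_ratio * N) +
    (ffn_ratio * N * N + N)
}

# Random binary mask pair on a small grid with a controllable foreground
# density; guarantees non-empty masks.
random_mask_pair <- function(dims, p = 0.15) {
  repeat {
    a <- array(as.numeric(stats::runif(prod(dims)) < p), dims)
    b <- array(as.numeric(stats::runif(prod(dims)) < p), dims)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = a, b = b))
  }
}

# Tiny network fixture shared by the structural/gradient tests.
tiny_net <- function(seed = 7, dropout = 0) {
  cfg <- net_config(input_size = c(32L, 32L, 16L), stem_channels = 2L,
                    n_heads = 2L, dropout = dropout)
  init_network(cfg, seed = seed)
}

# Preprocessed micro-cohort for training smoke tests: phantoms on a 64-grid
# so the network sees 32 x 32 in-plane after preprocessing.
micro_cases <- function(n, seed = 1000, d_range = c(20L, 26L)) {
  cases <- make_cohort(n, bilateral_fraction = 0.25, seed = seed,
                       grid_wh = 64L, d_range = d_range)
  lapply(cases, preprocess_case)
}
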