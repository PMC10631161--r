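# Channel-token transformer bottleneck. The bottleneck feature map
# (C' channels at 1/16 resolution) is projected by one pointwise
# convolution and reshaped so that token t is channel t's flattened spatial
# map: a sequence of C' tokens of dimension N = (W/16)(H/16)(D/16), to
# which a learnable positional embedding (C' x N) is added. Layers are
# pre-norm residual: x + MHA(LN(x)), then x + FFN(LN(x)).

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + EPS_NORM)
  xhat <- xc * inv_sd
  list(out = sweep(xhat, 2, gamma, `*`) + rep(beta, each = nrow(x)),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

layernorm_bwd <- function(cache, gout) {
  xhat <- cache$xhat
  ggamma <- colSums(gout * xhat)
  gbeta <- colSums(gout)
  dxhat <- sweep(gout, 2, cache$gamma, `*`)
  gx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_sd
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

#' Multi-head scaled dot-product attention
#'
#' `head_h = softmax(Q W_h^Q (K W_h^K)^T / sqrt(d_k)) V W_h^V`, heads
#' concatenated and mapped by one shared output projection `W^O`. Self- and
#' cross-attention are both supported; `d_k = d_v = N / n_heads`.
#'
#' @param Q,K,V Token matrices (rows = tokens, columns = model dim N).
#' @param params List with square `Wq`, `Wk`, `Wv`, `Wo` matrices (N x N,
#'   heads stored in contiguous column blocks).
#' @param n_heads Number of attention heads (default 8).
#' @return The output token matrix, same shape as `Q`.
#' @export
multi_head_attention <- function(Q, K, V, params, n_heads = 8L) {
  mha_fwd(Q, K, V, params, n_heads)$out
}

mha_fwd <- function(Q, K, V, p, n_heads) {
  N <- ncol(Q)
  if (ncol(K) != N || ncol(V) != N) stop("Q, K, V must share the model dimension")
  if (!all(dim(p$Wq) == N) || !all(dim(p$Wk) == N) ||
      !all(dim(p$Wv) == N) || !all(dim(p$Wo) == N)) {
    stop("projection matrices must be ", N, "x", N)
  }
  if (N %% n_heads != 0) stop("model dim ", N, " not divisible by ", n_heads, " heads")
  d <- N %/% n_heads
  Qp <- Q %*% p$Wq
  Kp <- K %*% p$Wk
  Vp <- V %*% p$Wv
  A <- vector("list", n_heads)
  H <- matrix(0, nrow(Q), N)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    Ah <- softmax_rows(Qp[, cols, drop = FALSE] %*% t(Kp[, cols, drop = FALSE]) / sqrt(d))
    A[[h]] <- Ah
    H[, cols] <- Ah %*% Vp[, cols, drop = FALSE]
  }
  list(out = H %*% p$Wo,
       cache = list(Q = Q, K = K, V = V, Qp = Qp, Kp = Kp, Vp = Vp, A = A,
                    H = H, d = d, n_heads = n_heads, p = p))
}

mha_bwd <- function(cache, gout) {
  p <- cache$p
  d <- cache$d
  gWo <- crossprod(cache$H, gout)
  gH <- gout %*% t(p$Wo)
  gQp <- gKp <- gVp <- matrix(0, nrow(gH), ncol(gH))
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    Ah <- cache$A[[h]]
    gOh <- gH[, cols, drop = FALSE]
    Vh <- cache$Vp[, cols, drop = FALSE]
    gA <- gOh %*% t(Vh)
    gVp[, cols] <- crossprod(Ah, gOh)
    gS <- Ah * (gA - rowSums(gA * Ah))
    gQp[, cols] <- gS %*% cache$Kp[, cols, drop = FALSE] / sqrt(d)
    gKp[, cols] <- crossprod(gS, cache$Qp[, cols, drop = FALSE]) / sqrt(d)
  }
  list(gQ = gQp %*% t(p$Wq), gK = gKp %*% t(p$Wk), gV = gVp %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$Q, gQp), Wk = crossprod(cache$K, gKp),
                    Wv = crossprod(cache$V, gVp), Wo = gWo))
}

ffn_fwd <- function(x, p) {
  H1 <- sweep(x %*% p$W1, 2, p$b1, `+`)
  G <- gelu(H1)
  out <- sweep(G %*% p$W2, 2, p$b2, `+`)
  list(out = out, cache = list(x = x, H1 = H1, G = G, p = p))
}

ffn_bwd <- function(cache, gout) {
  p <- cache$p
  gb2 <- colSums(gout)
  gW2 <- crossprod(cache$G, gout)
  gG <- gout %*% t(p$W2)
  gH1 <- gG * gelu_grad(cache$H1)
  gb1 <- colSums(gH1)
  gW1 <- crossprod(cache$x, gH1)
  list(gx = gH1 %*% t(p$W1), grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim = dim(x))
  list(out = x * mask, mask = mask)
}

tf_layer_init <- function(N, ffn_ratio, rnorm_fn = stats::rnorm) {
  xavier <- function(n_in, n_out) matrix(rnorm_fn(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
  list(ln1 = list(g = rep(1, N), b = numeric(N)),
       att = list(Wq = xavier(N, N), Wk = xavier(N, N),
                  Wv = xavier(N, N), Wo = xavier(N, N)),
       ln2 = list(g = rep(1, N), b = numeric(N)),
       ffn = list(W1 = xavier(N, ffn_ratio * N), b1 = numeric(ffn_ratio * N),
                  W2 = xavier(ffn_ratio * N, N), b2 = numeric(N)))
}

tf_layer_fwd <- function(x, p, n_heads, dropout = 0, training = FALSE) {
  ln1 <- layernorm_fwd(x, p$ln1$g, p$ln1$b)
  att <- mha_fwd(ln1$out, ln1$out, ln1$out, p$att, n_heads)
  dr1 <- dropout_fwd(att$out, dropout, training)
  x1 <- x + dr1$out
  ln2 <- layernorm_fwd(x1, p$ln2$g, p$ln2$b)
  ffn <- ffn_fwd(ln2$out, p$ffn)
  dr2 <- dropout_fwd(ffn$out, dropout, training)
  list(out = x1 + dr2$out,
       cache = list(ln1 = ln1$cache, att = att$cache, dr1 = dr1$mask,
                    ln2 = ln2$cache, ffn = ffn$cache, dr2 = dr2$mask))
}

tf_layer_bwd <- function(cache, gout) {
  gf <- if (is.null(cache$dr2)) gout else gout * cache$dr2
  ffn <- ffn_bwd(cache$ffn, gf)
  ln2 <- layernorm_bwd(cache$ln2, ffn$gx)
  gx1 <- gout + ln2$gx
  ga <- if (is.null(cache$dr1)) gx1 else gx1 * cache$dr1
  att <- mha_bwd(cache$att, ga)
  ln1 <- layernorm_bwd(cache$ln1, att$gQ + att$gK + att$gV)
  list(gx = gx1 + ln1$gx,
       grads = list(ln1 = list(g = ln1$ggamma, b = ln1$gbeta), att = att$grads,
                    ln2 = list(g = ln2$ggamma, b = ln2$gbeta), ffn = ffn$grads))
}

#' Run a stack of transformer layers
#'
#' `n_layers = 0` (the ablated transformer) is the identity on the token
#' sequence. Each layer is pre-norm residual MHA + FFN; shapes are
#' preserved throughout.
#'
#' @param tokens Token matrix (C' x N).
#' @param layers List of layer parameter sets (as built inside
#'   [init_network()]); only the first `n_layers` are used.
#' @param n_layers Number of layers to apply.
#' @param n_heads Attention heads.
#' @return Token matrix of the same shape.
#' @export
transformer_stack <- function(tokens, layers, n_layers = length(layers),
                              n_heads = 8L) {
  if (n_layers < 0) stop("n_layers must be non-negative")
  if (n_layers > length(layers)) stop("only ", length(layers), " layers available")
  for (l in seq_len(n_layers)) {
    tokens <- tf_layer_fwd(tokens, layers[[l]], n_heads)$out
  }
  tokens
}
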