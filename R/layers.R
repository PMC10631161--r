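# Network building blocks with hand-authored forward/backward passes.
# Feature maps are 4D arrays [X, Y, Z, C]; channel last, so dropping the
# dim attribute to [voxels, C] makes pointwise convolutions plain matrix
# products without copying data. Convolutions carry no bias: a group
# normalization with learnable shift follows each one.

EPS_NORM <- 1e-5

# cheap reshapes: the objects are function-local, so `dim<-` does not copy
reshape2 <- function(x, v, c) { dim(x) <- c(v, c); x }
reshape4 <- function(x, spatial, c) { dim(x) <- c(spatial, c); x }

# ---- depthwise 3x3x3 (compiled kernel) -------------------------------------

dwconv_bwd_input <- function(gout, w) {
  dwconv3_fwd(gout, w[27:1, , drop = FALSE])   # flipped taps
}

# ---- group normalization (channel-matrix layout) ---------------------------

gn_groups <- function(channels) {
  g <- min(8L, channels)
  if (channels %% g != 0) stop("channel count ", channels, " not divisible into ", g, " groups")
  g
}

groupnorm_fwd <- function(m, gamma, beta) {
  ng <- gn_groups(ncol(m))
  r <- gn_fwd_cpp(m, gamma, beta, ng)
  list(out = r$out,
       cache = list(xhat = r$xhat, inv_g = r$inv_g, gamma = gamma, ng = ng))
}

groupnorm_bwd <- function(cache, gm) {
  gn_bwd_cpp(gm, cache$xhat, cache$inv_g, cache$gamma, cache$ng)
}

# ---- DSConv unit: depthwise 3^3 -> pointwise -> group norm -> ReLU ---------

dsconv_unit_init <- function(c_in, c_out, rnorm_fn = stats::rnorm) {
  list(dw = matrix(rnorm_fn(27 * c_in, sd = sqrt(2 / 27)), 27, c_in),
       pw = matrix(rnorm_fn(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       g = rep(1, c_out), be = numeric(c_out))
}

dsconv_unit_fwd <- function(x, p) {
  d <- dim(x)
  spatial <- d[1:3]
  v <- prod(spatial)
  h1 <- reshape2(dwconv3_fwd(x, p$dw), v, d[4])
  h2 <- h1 %*% p$pw
  gn <- groupnorm_fwd(h2, p$g, p$be)
  act <- gn$out > 0
  out <- gn$out * act
  list(out = reshape4(out, spatial, ncol(p$pw)),
       cache = list(x = x, h1 = h1, gn = gn$cache, act = act,
                    spatial = spatial, p = p))
}

dsconv_unit_bwd <- function(cache, gout) {
  p <- cache$p
  v <- prod(cache$spatial)
  gr <- reshape2(gout, v, ncol(p$pw)) * cache$act
  gn <- groupnorm_bwd(cache$gn, gr)
  gpw <- crossprod(cache$h1, gn$gx)
  gh1 <- reshape4(tcrossprod(gn$gx, p$pw), cache$spatial, nrow(p$pw))
  gdw <- dwconv3_wgrad(cache$x, gh1)
  gx <- dwconv_bwd_input(gh1, p$dw)
  list(gx = gx, grads = list(dw = gdw, pw = gpw, g = gn$ggamma, be = gn$gbeta))
}

# ---- strided (2,2,2) depthwise downsampling: learned 2x2x2 pooling ---------

down_init <- function(channels, rnorm_fn = stats::rnorm) {
  list(w = matrix(rnorm_fn(8 * channels, sd = sqrt(2 / 8)), 8, channels))
}

down_fwd <- function(x, p) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) stop("downsampling needs even spatial dims, got ",
                                    paste(d[1:3], collapse = "x"))
  C <- d[4]
  d2 <- d[1:3] %/% 2L
  v2 <- prod(d2)
  out <- array(0, c(d2, C))
  slices <- vector("list", 8L)
  for (t in 0:7) {
    o <- c(t %% 2L, (t %/% 2L) %% 2L, t %/% 4L)
    sl <- x[seq(1L + o[1], d[1], 2L), seq(1L + o[2], d[2], 2L),
            seq(1L + o[3], d[3], 2L), , drop = FALSE]
    slices[[t + 1]] <- sl
    out <- out + sl * rep(p$w[t + 1, ], each = v2)
  }
  list(out = out, cache = list(slices = slices, dims = d, p = p))
}

down_bwd <- function(cache, gout) {
  d <- cache$dims
  C <- d[4]
  v2 <- prod(d[1:3] %/% 2L)
  gw <- matrix(0, 8, C)
  gx <- array(0, d)
  for (t in 0:7) {
    o <- c(t %% 2L, (t %/% 2L) %% 2L, t %/% 4L)
    gw[t + 1, ] <- colSums(reshape2(gout * cache$slices[[t + 1]], v2, C))
    gx[seq(1L + o[1], d[1], 2L), seq(1L + o[2], d[2], 2L),
       seq(1L + o[3], d[3], 2L), ] <- gout * rep(cache$p$w[t + 1, ], each = v2)
  }
  list(gx = gx, grads = list(w = gw))
}

# ---- transposed convolution, kernel 2 stride 2 (non-overlapping) -----------
# W columns are ordered tap-major: col = t * c_out + j for tap t in 0..7.

up_init <- function(c_in, c_out, rnorm_fn = stats::rnorm) {
  list(W = matrix(rnorm_fn(c_in * 8 * c_out, sd = sqrt(2 / c_in)), c_in, 8 * c_out),
       b = numeric(c_out))
}

up_fwd <- function(x, p) {
  d <- dim(x)
  c_out <- length(p$b)
  m <- reshape2(x, prod(d[1:3]), d[4])
  H <- m %*% p$W
  d2 <- d[1:3] * 2L
  out <- array(0, c(d2, c_out))
  for (t in 0:7) {
    o <- c(t %% 2L, (t %/% 2L) %% 2L, t %/% 4L)
    out[seq(1L + o[1], d2[1], 2L), seq(1L + o[2], d2[2], 2L),
        seq(1L + o[3], d2[3], 2L), ] <- H[, (t * c_out + 1):((t + 1) * c_out)]
  }
  out <- out + rep(p$b, each = prod(d2))
  list(out = out, cache = list(m = m, dims = d, c_out = c_out, p = p))
}

up_bwd <- function(cache, gout) {
  d <- cache$dims
  c_out <- cache$c_out
  d2 <- d[1:3] * 2L
  v <- prod(d[1:3])
  gH <- matrix(0, v, 8 * c_out)
  for (t in 0:7) {
    o <- c(t %% 2L, (t %/% 2L) %% 2L, t %/% 4L)
    sl <- gout[seq(1L + o[1], d2[1], 2L), seq(1L + o[2], d2[2], 2L),
               seq(1L + o[3], d2[3], 2L), , drop = FALSE]
    gH[, (t * c_out + 1):((t + 1) * c_out)] <- sl
  }
  gb <- colSums(reshape2(gout, prod(d2), c_out))
  gW <- crossprod(cache$m, gH)
  gx <- reshape4(tcrossprod(gH, cache$p$W), d[1:3], d[4])
  list(gx = gx, grads = list(W = gW, b = gb))
}

# ---- pointwise projection / head -------------------------------------------

pointwise_fwd <- function(x, W, b) {
  d <- dim(x)
  m <- reshape2(x, prod(d[1:3]), d[4])
  out <- m %*% W + rep(b, each = nrow(m))
  list(out = reshape4(out, d[1:3], ncol(W)),
       cache = list(m = m, W = W, spatial = d[1:3]))
}

pointwise_bwd <- function(cache, gout) {
  gm <- reshape2(gout, prod(cache$spatial), ncol(cache$W))
  list(gx = reshape4(tcrossprod(gm, cache$W), cache$spatial, nrow(cache$W)),
       grads = list(pw = crossprod(cache$m, gm), b = colSums(gm)))
}

# ---- recursive parameter-tree helpers --------------------------------------

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(p, q, f) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- param_map2(p[[i]], q[[i]], f)
    out
  } else f(p, q)
}

param_sum <- function(p, f = function(x) sum(abs(x))) {
  if (is.list(p)) sum(vapply(p, param_sum, numeric(1), f = f)) else f(p)
}

#' Total number of trainable scalars in a parameter tree
#'
#' @param params A model (`dst_net`) or a nested parameter list.
#' @return Integer count.
#' @export
n_parameters <- function(params) {
  if (inherits(params, "dst_net")) params <- params$params
  param_sum(params, f = length)
}
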