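# The segmentation network: a DSConv encoder that downsamples four times
# (channels doubling each stage up to C'), a channel-token transformer
# bottleneck, and a decoder that upsamples four times with skip
# concatenation, ending in a single-channel sigmoid head. Ablation switches
# remove the skip connections and/or the transformer.

#' Network configuration
#'
#' Architectural description of the model. The default stage widths are the
#' unique doubling chain of length 4 ending at the bottleneck width
#' `C' = 256` (stem 16 -> 32, 64, 128, 256); the canonical input is
#' 256 x 256 x 32, giving 256 tokens of dimension `N = 16 * 16 * 2 = 512`
#' in the transformer.
#'
#' @param input_size Integer (W, H, D), each divisible by 16.
#' @param in_channels Input channels (CT: 1).
#' @param stem_channels Stem width; stage widths double from it.
#' @param stage_channels Four stage widths, each double its predecessor;
#'   the last is the bottleneck width C'.
#' @param n_transformer_layers Transformer depth (0, 2, 4, 6 or 8; 0 only
#'   via `use_transformer = FALSE`).
#' @param n_heads Attention heads (8).
#' @param use_skip Keep the encoder-decoder skip connections.
#' @param use_transformer Keep the transformer bottleneck.
#' @param ffn_ratio FFN hidden width as a multiple of N.
#' @param dropout Dropout rate inside transformer layers (training only).
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_size = c(256L, 256L, 32L), in_channels = 1L,
                       stem_channels = 16L,
                       stage_channels = stem_channels * c(2L, 4L, 8L, 16L),
                       n_transformer_layers = 4L, n_heads = 8L,
                       use_skip = TRUE, use_transformer = TRUE,
                       ffn_ratio = 4L, dropout = 0.1) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L || any(input_size <= 0)) stop("input_size must be 3 positive integers")
  if (any(input_size %% 16L != 0L)) {
    stop("input dimensions must be divisible by 16, got ",
         paste(input_size, collapse = "x"))
  }
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != 4L) stop("stage_channels must have length 4")
  if (stage_channels[1] != 2L * stem_channels ||
      any(stage_channels[-1] != 2L * stage_channels[-4])) {
    stop("stage widths must form a doubling chain from the stem")
  }
  if (n_transformer_layers < 0) stop("n_transformer_layers must be non-negative")
  N <- prod(input_size %/% 16L)
  if (use_transformer && N %% n_heads != 0L) {
    stop("token dimension N = ", N, " must be divisible by n_heads = ", n_heads)
  }
  structure(list(input_size = input_size, in_channels = as.integer(in_channels),
                 stem_channels = as.integer(stem_channels),
                 stage_channels = stage_channels,
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_heads = as.integer(n_heads), use_skip = isTRUE(use_skip),
                 use_transformer = isTRUE(use_transformer),
                 ffn_ratio = as.integer(ffn_ratio), dropout = dropout),
            class = "net_config")
}

#' Bottleneck and token shapes implied by a configuration
#'
#' Structural shape arithmetic: after four downsamplings the bottleneck is
#' `C' x W/16 x H/16 x D/16`, and the token sequence is `C'` tokens of
#' dimension `N = (W/16)(H/16)(D/16)`.
#'
#' @param cfg A [net_config()].
#' @return `bottleneck_shape()`: integer (W/16, H/16, D/16, C');
#'   `token_shape()`: integer (C', N).
#' @export
bottleneck_shape <- function(cfg) {
  c(cfg$input_size %/% 16L, cfg$stage_channels[4])
}

#' @rdname bottleneck_shape
#' @export
token_shape <- function(cfg) {
  c(cfg$stage_channels[4], as.integer(prod(cfg$input_size %/% 16L)))
}

#' Parameter counts: depthwise separable vs standard convolution
#'
#' For a k x k x k convolution mapping `c_in` to `c_out` channels (bias
#' excluded): a DSConv factorization costs `k^3 * c_in + c_in * c_out`
#' weights against `k^3 * c_in * c_out` for the full convolution - fewer
#' whenever `c_out > 1` and `k > 1`.
#'
#' @param c_in,c_out Channel counts.
#' @param k Spatial kernel size.
#' @return Named numeric: `dsconv`, `standard`.
#' @export
dsconv_param_count <- function(c_in, c_out, k = 3L) {
  stopifnot(c_in > 0, c_out > 0, k > 0)
  c(dsconv = k^3 * c_in + c_in * c_out, standard = k^3 * c_in * c_out)
}

#' Initialize a segmentation model
#'
#' Builds the parameter tree for a configuration: He-initialized
#' convolutions, Xavier-initialized transformer projections, unit
#' normalization gains, and a small-random learnable positional embedding.
#' Deterministic given `seed`; the caller's RNG state is restored.
#'
#' @param cfg A [net_config()].
#' @param seed Weight-initialization seed (default the training seed 1000).
#' @return An object of class `dst_net`: `cfg` plus `params`.
#' @export
init_network <- function(cfg, seed = 1000L) {
  stopifnot(inherits(cfg, "net_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  ch <- c(cfg$stem_channels, cfg$stage_channels)   # c0..c4
  p <- list(stem = dsconv_unit_init(cfg$in_channels, ch[1]))
  p$enc <- lapply(1:4, function(k) {
    list(u1 = dsconv_unit_init(ch[k], ch[k + 1]),
         u2 = dsconv_unit_init(ch[k + 1], ch[k + 1]),
         down = down_init(ch[k + 1]))
  })
  if (cfg$use_transformer) {
    S <- cfg$stage_channels[4]
    N <- prod(cfg$input_size %/% 16L)
    p$proj <- list(pw = matrix(stats::rnorm(S * S, sd = sqrt(2 / S)), S, S),
                   b = numeric(S))
    p$pos <- matrix(stats::rnorm(S * N, sd = 0.02), S, N)
    p$tf <- lapply(seq_len(cfg$n_transformer_layers), function(l) {
      tf_layer_init(N, cfg$ffn_ratio)
    })
  }
  p$dec <- lapply(1:4, function(j) {
    c_in <- ch[6 - j]        # 256, 128, 64, 32
    c_out <- ch[5 - j]       # 128, 64, 32, 16
    c_fuse_in <- if (cfg$use_skip) c_out + ch[6 - j] else c_out
    list(up = up_init(c_in, c_out),
         fuse = dsconv_unit_init(c_fuse_in, c_out))
  })
  p$head <- list(pw = matrix(stats::rnorm(ch[1], sd = sqrt(2 / ch[1])), ch[1], 1),
                 b = numeric(1))
  structure(list(cfg = cfg, params = p), class = "dst_net")
}

#' @export
print.dst_net <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<dst_net %s, stem %d -> C'=%d, %s transformer (%d layers, %d heads), %s skips, %s parameters>\n",
              paste(cfg$input_size, collapse = "x"), cfg$stem_channels,
              cfg$stage_channels[4],
              if (cfg$use_transformer) "with" else "no",
              cfg$n_transformer_layers, cfg$n_heads,
              if (cfg$use_skip) "with" else "no",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

check_input_dims <- function(cfg, d) {
  if (any(d %% 16L != 0L)) {
    stop("input spatial dims ", paste(d, collapse = "x"),
         " are not divisible by 16")
  }
  if (!all(d == cfg$input_size)) {
    stop("input ", paste(d, collapse = "x"), " does not match the configured ",
         paste(cfg$input_size, collapse = "x"))
  }
}

#' Run the encoder
#'
#' Four stages of two DSConv units each, every stage followed by a learned
#' stride-2 depthwise downsampling; the pre-downsampling feature map of
#' each stage is retained for the decoder's skip connections.
#'
#' @param model A `dst_net` from [init_network()].
#' @param x 3D input array (normalized intensities) matching the configured
#'   input size.
#' @return List with `bottleneck` (array W/16 x H/16 x D/16 x C') and
#'   `skips` (four feature maps, stage 1 at full resolution to stage 4 at
#'   1/8).
#' @export
encode <- function(model, x) {
  enc <- encode_fwd(model, x)
  list(bottleneck = enc$bottleneck, skips = enc$skips)
}

encode_fwd <- function(model, x) {
  cfg <- model$cfg
  d <- dim(x)
  if (length(d) != 3L) stop("expected a 3D input volume")
  check_input_dims(cfg, d)
  p <- model$params
  x4 <- array(x, c(d, 1L))
  stem <- dsconv_unit_fwd(x4, p$stem)
  cur <- stem$out
  skips <- vector("list", 4L)
  caches <- list(stem = stem$cache, stages = vector("list", 4L))
  for (k in 1:4) {
    u1 <- dsconv_unit_fwd(cur, p$enc[[k]]$u1)
    u2 <- dsconv_unit_fwd(u1$out, p$enc[[k]]$u2)
    skips[[k]] <- u2$out
    dn <- down_fwd(u2$out, p$enc[[k]]$down)
    caches$stages[[k]] <- list(u1 = u1$cache, u2 = u2$cache, down = dn$cache)
    cur <- dn$out
  }
  list(bottleneck = cur, skips = skips, caches = caches)
}

#' Tokenize the bottleneck feature map
#'
#' One pointwise convolutional projection, then a reshape in which token t
#' is channel t's flattened spatial map (C' tokens of dimension N), plus
#' the learnable positional embedding. The channel count must equal the
#' configured bottleneck width (256 in the default configuration).
#'
#' @param model A `dst_net` with an active transformer.
#' @param bottleneck Bottleneck array from [encode()].
#' @return Token matrix C' x N.
#' @export
tokenize <- function(model, bottleneck) {
  if (!model$cfg$use_transformer) stop("model was built without a transformer")
  tokenize_fwd(model, bottleneck)$out
}

tokenize_fwd <- function(model, bottleneck) {
  S <- model$cfg$stage_channels[4]
  d <- dim(bottleneck)
  if (d[4] != S) {
    stop("bottleneck has ", d[4], " channels; the token layout requires ", S)
  }
  proj <- pointwise_fwd(bottleneck, model$params$proj$pw, model$params$proj$b)
  tokens <- t(reshape2(proj$out, prod(d[1:3]), S)) + model$params$pos
  list(out = tokens, cache = list(proj = proj$cache, spatial = d[1:3]))
}

#' Full forward pass
#'
#' Encoder, transformer bottleneck (when enabled), decoder with skip
#' concatenation (when enabled), pointwise head. Returns per-voxel
#' foreground probabilities on the input grid.
#'
#' @param model A `dst_net`.
#' @param x 3D input array, normalized intensities, dims = configured
#'   input size.
#' @param training Apply dropout (training mode).
#' @return 3D array of probabilities in [0, 1] (`net_forward()`); the
#'   internal variant also returns the cache for the backward pass.
#' @export
net_forward <- function(model, x, training = FALSE) {
  plogis_arr(net_forward_cache(model, x, training)$logits)
}

plogis_arr <- function(z) {
  p <- 1 / (1 + exp(-z))
  array(p, dim = dim(z))
}

net_forward_cache <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  enc <- encode_fwd(model, x)
  cur <- enc$bottleneck
  cache <- list(enc = enc$caches)

  if (cfg$use_transformer) {
    tok <- tokenize_fwd(model, cur)
    tokens <- tok$out
    tf_caches <- vector("list", cfg$n_transformer_layers)
    for (l in seq_len(cfg$n_transformer_layers)) {
      step <- tf_layer_fwd(tokens, p$tf[[l]], cfg$n_heads, cfg$dropout, training)
      tokens <- step$out
      tf_caches[[l]] <- step$cache
    }
    cur <- reshape4(t(tokens), tok$cache$spatial, nrow(tokens))   # feature mapping
    cache$tok <- tok$cache
    cache$tf <- tf_caches
  }

  dec_caches <- vector("list", 4L)
  for (j in 1:4) {
    up <- up_fwd(cur, p$dec[[j]]$up)
    merged <- up$out
    if (cfg$use_skip) {
      skip <- enc$skips[[5 - j]]
      merged <- array(c(merged, skip), c(dim(merged)[1:3], dim(merged)[4] + dim(skip)[4]))
    }
    fuse <- dsconv_unit_fwd(merged, p$dec[[j]]$fuse)
    dec_caches[[j]] <- list(up = up$cache, fuse = fuse$cache,
                            n_up = dim(up$out)[4])
    cur <- fuse$out
  }
  head <- pointwise_fwd(cur, p$head$pw, p$head$b)
  cache$dec <- dec_caches
  cache$head <- head$cache
  list(logits = array(head$out, dim(head$out)[1:3]), cache = cache)
}

# Backward pass: gradient of a scalar loss wrt all parameters, given
# d loss / d logits. Returns a tree matching model$params.
net_backward <- function(model, cache, glogits) {
  cfg <- model$cfg
  g <- list()
  hd <- pointwise_bwd(cache$head, array(glogits, c(dim(glogits), 1L)))
  g$head <- hd$grads
  gcur <- hd$gx

  g$dec <- vector("list", 4L)
  gskips <- vector("list", 4L)
  for (j in 4:1) {
    dc <- cache$dec[[j]]
    fuse <- dsconv_unit_bwd(dc$fuse, gcur)
    gmerged <- fuse$gx
    if (cfg$use_skip) {
      n_up <- dc$n_up
      gup_in <- gmerged[, , , seq_len(n_up), drop = FALSE]
      gskips[[5 - j]] <- gmerged[, , , -seq_len(n_up), drop = FALSE]
    } else {
      gup_in <- gmerged
    }
    up <- up_bwd(dc$up, gup_in)
    g$dec[[j]] <- list(up = up$grads, fuse = fuse$grads)
    gcur <- up$gx
  }

  if (cfg$use_transformer) {
    gtokens <- t(reshape2(gcur, prod(dim(gcur)[1:3]), dim(gcur)[4]))
    g$tf <- vector("list", cfg$n_transformer_layers)
    for (l in rev(seq_len(cfg$n_transformer_layers))) {
      step <- tf_layer_bwd(cache$tf[[l]], gtokens)
      g$tf[[l]] <- step$grads
      gtokens <- step$gx
    }
    g$pos <- gtokens
    proj <- pointwise_bwd(cache$tok$proj, reshape4(t(gtokens), cache$tok$spatial, nrow(gtokens)))
    g$proj <- list(pw = proj$grads$pw, b = proj$grads$b)
    gcur <- proj$gx
  }

  g$enc <- vector("list", 4L)
  for (k in 4:1) {
    st <- cache$enc$stages[[k]]
    dn <- down_bwd(st$down, gcur)
    gu2_out <- dn$gx
    if (cfg$use_skip && !is.null(gskips[[k]])) {
      gu2_out <- gu2_out + gskips[[k]]
    }
    u2 <- dsconv_unit_bwd(st$u2, gu2_out)
    u1 <- dsconv_unit_bwd(st$u1, u2$gx)
    g$enc[[k]] <- list(u1 = u1$grads, u2 = u2$grads, down = dn$grads)
    gcur <- u1$gx
  }
  stem <- dsconv_unit_bwd(cache$enc$stem, gcur)
  g$stem <- stem$grads
  g[names(model$params)]   # order like the parameter tree
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration and the parameter tree together
#' (RDS container).
#'
#' @param model A `dst_net`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the `dst_net`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dst_net"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dst_net")) stop("not a model checkpoint: ", path)
  model
}
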