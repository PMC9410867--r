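#' Model configuration for the CFSG U-Net
#'
#' A residual 3D U-Net with four encoder and three decoder stages. Skip
#' connections are refined by a channel-wise fusion attention module (CFAM):
#' global average pooling of the encoder and decoder feature maps gives two
#' length-C statistics which are concatenated and passed through a 1D
#' convolution of kernel size `cfam_kernel` plus a sigmoid, yielding one
#' channel attention map for each side. Decoder features are then refined by
#' a spatial-wise group attention module (SGAM): channels are split into
#' `sgam_groups` contiguous groups, each collapsed by its own pointwise
#' convolution and mapped through its own 7x7x7 convolution plus sigmoid to a
#' spatial attention map that reweights that group. `use_cfam`/`use_sgam`
#' reproduce the ablation variants (both off = the plain residual U-Net
#' backbone).
#'
#' @param base_channels channels of the first encoder stage; doubled per
#'   stage (default 32, giving 32/64/128/256).
#' @param n_encoders,n_decoders stage counts (fixed at 4 and 3).
#' @param cfam_kernel odd 1D-convolution kernel size n (default 5).
#' @param sgam_groups group count G (default 4); must divide every
#'   decoder-stage channel count, i.e. `base_channels`.
#' @param sgam_kernel spatial attention kernel (default 7).
#' @param use_cfam,use_sgam attention toggles.
#' @param cfam_shared one shared 1D convolution producing both attention maps
#'   (default) or two separate convolutions.
#' @return A list of class `model_config`.
#' @export
model_config <- function(base_channels = 32L, n_encoders = 4L,
                         n_decoders = 3L, cfam_kernel = 5L,
                         sgam_groups = 4L, sgam_kernel = 7L,
                         use_cfam = TRUE, use_sgam = TRUE,
                         cfam_shared = TRUE) {
  base_channels <- as.integer(base_channels)
  cfam_kernel <- as.integer(cfam_kernel)
  sgam_groups <- as.integer(sgam_groups)
  if (cfam_kernel %% 2L == 0L)
    stop("cfam_kernel must be odd, got ", cfam_kernel)
  if (sgam_groups < 1L) stop("sgam_groups must be >= 1")
  if (n_encoders != 4L || n_decoders != 3L)
    stop("architecture is fixed at 4 encoder and 3 decoder stages")
  if (use_sgam && base_channels %% sgam_groups != 0L)
    stop("sgam_groups (", sgam_groups, ") must divide every decoder-stage ",
         "channel count; smallest is base_channels (", base_channels, ")")
  structure(list(base_channels = base_channels, n_encoders = 4L,
                 n_decoders = 3L, cfam_kernel = cfam_kernel,
                 sgam_groups = sgam_groups,
                 sgam_kernel = as.integer(sgam_kernel),
                 use_cfam = isTRUE(use_cfam), use_sgam = isTRUE(use_sgam),
                 cfam_shared = isTRUE(cfam_shared)),
            class = "model_config")
}

enc_channels <- function(cfg) cfg$base_channels * 2L^(0:3)

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_par <- function(K, Cin, Cout) {
  list(w = he_init(c(K, K, K, Cin, Cout), K^3 * Cin), b = numeric(Cout))
}

bn_par <- function(C) list(gamma = rep(1, C), beta = numeric(C))

#' Construct a CFSG U-Net model with freshly initialized weights
#'
#' Convolution weights use He-normal initialization (sd `sqrt(2/fan_in)`),
#' biases zero, batch-norm gain 1 / bias 0. All randomness flows through R's
#' RNG, so `seed` makes initialization reproducible.
#'
#' @param config a [model_config].
#' @param seed integer seed for weight initialization.
#' @return List of class `cfsg_model` with elements `config`, `params`
#'   (named list of arrays) and `bn` (running batch-norm statistics).
#' @export
cfsg_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  ch <- enc_channels(config)
  p <- list()
  cin <- 1L
  for (k in 1:4) {
    co <- ch[k]
    p[[paste0("e", k, ".conv1")]] <- conv_par(3L, cin, co)
    p[[paste0("e", k, ".bn1")]] <- bn_par(co)
    p[[paste0("e", k, ".conv2")]] <- conv_par(3L, co, co)
    p[[paste0("e", k, ".bn2")]] <- bn_par(co)
    p[[paste0("e", k, ".proj")]] <- conv_par(1L, cin, co)
    cin <- co
  }
  for (s in 3:1) {
    C <- ch[s]
    pre <- paste0("d", s)
    up <- list(w = he_init(c(2, 2, 2, 2L * C, C), 8 * 2 * C),
               b = numeric(C))
    p[[paste0(pre, ".up")]] <- up
    if (config$use_cfam) {
      n <- config$cfam_kernel
      if (config$cfam_shared) {
        p[[paste0(pre, ".cfam")]] <- list(w = he_init(n, n), b = 0)
      } else {
        p[[paste0(pre, ".cfam")]] <- list(w_e = he_init(n, n), b_e = 0,
                                          w_d = he_init(n, n), b_d = 0)
      }
    }
    p[[paste0(pre, ".fuse")]] <- conv_par(3L, 2L * C, C)
    p[[paste0(pre, ".fusebn")]] <- bn_par(C)
    if (config$use_sgam) {
      G <- config$sgam_groups
      Cg <- C %/% G
      ks <- config$sgam_kernel
      for (g in seq_len(G)) {
        p[[paste0(pre, ".sgam.g", g, ".pw")]] <- conv_par(1L, Cg, 1L)
        p[[paste0(pre, ".sgam.g", g, ".sp")]] <- conv_par(ks, 1L, 1L)
      }
    }
    p[[paste0(pre, ".post")]] <- conv_par(3L, C, C)
    p[[paste0(pre, ".postbn")]] <- bn_par(C)
  }
  p[["head"]] <- conv_par(1L, ch[1], 1L)
  # fracture voxels are rare; start the output near the background rate so
  # early training is not dominated by driving the background down
  p[["head"]]$b <- -2
  bn <- new.env(parent = emptyenv())
  bn$bn <- list()
  structure(list(config = config, params = p, bn = bn),
            class = "cfsg_model")
}

#' Number of trainable parameters
#' @param model a `cfsg_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params,
             function(layer) sum(vapply(layer, length, 1L)), 1L))
}

#' @export
print.cfsg_model <- function(x, ...) {
  cfgs <- x$config
  cat(sprintf(
    "CFSG U-Net: base %d channels (%s), CFAM %s (n=%d), SGAM %s (G=%d), %d parameters\n",
    cfgs$base_channels, paste(enc_channels(cfgs), collapse = "/"),
    if (cfgs$use_cfam) "on" else "off", cfgs$cfam_kernel,
    if (cfgs$use_sgam) "on" else "off", cfgs$sgam_groups,
    count_params(x)))
  invisible(x)
}

# ---- conversions between the public C x L x W x H convention and the
# internal (L, W, H, C, N) layout --------------------------------------------

as_internal <- function(F) {
  stopifnot(length(dim(F)) == 4L)
  x <- aperm(F, c(2, 3, 4, 1))
  dim(x) <- c(dim(x), 1L)
  x
}

as_public <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 5L, d[5] == 1L)
  dim(x) <- d[1:4]
  aperm(x, c(4, 1, 2, 3))
}

#' Global average pooling
#'
#' Collapses a feature map `F` of shape C x L x W x H to a length-C vector
#' of per-channel spatial means.
#'
#' @param F rank-4 array, channels first.
#' @return Numeric vector of length C.
#' @export
gap <- function(F) {
  stopifnot(length(dim(F)) == 4L, all(is.finite(F)))
  as.numeric(apply(F, 1, mean))
}

# internal builders on tape nodes -------------------------------------------

cfam_build <- function(tape, fe, fd, w, shared) {
  C <- dim5(fe$value)[4]
  se <- op_gap(tape, fe)
  sd_ <- op_gap(tape, fd)
  s <- op_rbind(tape, se, sd_)
  if (shared) {
    a <- op_sigmoid_m(tape, op_conv1d(tape, s, w$w, w$b))
    me <- op_rows(tape, a, seq_len(C))
    md <- op_rows(tape, a, C + seq_len(C))
  } else {
    ae <- op_sigmoid_m(tape, op_conv1d(tape, s, w$w_e, w$b_e))
    ad <- op_sigmoid_m(tape, op_conv1d(tape, s, w$w_d, w$b_d))
    me <- op_rows(tape, ae, seq_len(C))
    md <- op_rows(tape, ad, C + seq_len(C))
  }
  list(fe = op_scale_c(tape, fe, me), fd = op_scale_c(tape, fd, md),
       me = me, md = md)
}

sgam_build <- function(tape, x, wlist, G, ks) {
  C <- dim5(x$value)[4]
  if (C %% G != 0L)
    stop("SGAM group count ", G, " does not divide channel count ", C)
  Cg <- C %/% G
  parts <- vector("list", G)
  for (g in seq_len(G)) {
    chans <- (g - 1L) * Cg + seq_len(Cg)
    xg <- op_slice_c(tape, x, chans)
    wg <- wlist[[g]]
    sg <- op_conv3d(tape, xg, wg$pw_w, wg$pw_b, K = 1L, pad = 0L)
    zg <- op_conv3d(tape, sg, wg$sp_w, wg$sp_b, K = ks,
                    pad = (ks - 1L) %/% 2L)
    att <- op_sigmoid(tape, zg)
    parts[[g]] <- op_scale_s(tape, xg, att)
  }
  out <- parts[[1]]
  if (G > 1L) for (g in 2:G) out <- op_concat_c(tape, out, parts[[g]])
  out
}

#' Channel-wise fusion attention (CFAM) forward pass
#'
#' Computes the per-channel spatial statistics of the encoder-side and
#' decoder-side feature maps by global average pooling, concatenates them
#' into a length-2C sequence, applies a 1D convolution (kernel `n`, same
#' padding, single channel, with bias) and a sigmoid, and uses the first C
#' outputs to reweight `F_e` and the last C to reweight `F_d` channel-wise.
#'
#' @param F_e,F_d feature maps of identical shape C x L x W x H.
#' @param weights list with `w` (length-n kernel) and `b` (scalar bias);
#'   for the unshared variant, `w_e`, `b_e`, `w_d`, `b_d`.
#' @param shared use one shared convolution for both maps (default).
#' @return List with `F_e_prime`, `F_d_prime` (same shapes as the inputs)
#'   and the attention vectors `M_e`, `M_d` (length C, values in (0,1)).
#' @export
cfam_forward <- function(F_e, F_d, weights, shared = TRUE) {
  if (!identical(dim(F_e), dim(F_d)))
    stop("F_e and F_d must have identical shapes")
  n <- length(if (shared) weights$w else weights$w_e)
  if (n %% 2L == 0L) stop("CFAM kernel size must be odd, got ", n)
  fe <- ag_leaf(as_internal(F_e))
  fd <- ag_leaf(as_internal(F_d))
  wn <- lapply(weights, ag_leaf)
  r <- cfam_build(NULL, fe, fd, wn, shared)
  list(F_e_prime = as_public(r$fe$value), F_d_prime = as_public(r$fd$value),
       M_e = as.numeric(r$me$value), M_d = as.numeric(r$md$value))
}

#' Spatial-wise group attention (SGAM) forward pass
#'
#' Splits the channels of `F` into `G` contiguous groups. Each group is
#' collapsed to a single channel by its own pointwise (1x1x1) convolution,
#' mapped through its own `kernel`^3 convolution plus sigmoid to a spatial
#' attention map in (0,1), and multiplied back over the group's channels.
#' Groups are re-concatenated in their original order.
#'
#' @param F feature map, C x L x W x H; G must divide C.
#' @param weights list of length G; element g has `pw_w` (1x1x1 x Cg x 1),
#'   `pw_b` (scalar), `sp_w` (k x k x k x 1 x 1), `sp_b` (scalar).
#' @param G group count.
#' @param kernel spatial attention kernel size (default 7).
#' @return Refined feature map, same shape as `F`.
#' @export
sgam_forward <- function(F, weights, G, kernel = 7L) {
  stopifnot(length(dim(F)) == 4L)
  C <- dim(F)[1]
  if (C %% G != 0L)
    stop("SGAM group count ", G, " does not divide channel count ", C)
  x <- ag_leaf(as_internal(F))
  wl <- lapply(weights, function(wg) list(
    pw_w = ag_leaf(array(wg$pw_w, c(1, 1, 1, C %/% G, 1))),
    pw_b = ag_leaf(wg$pw_b),
    sp_w = ag_leaf(array(wg$sp_w, c(kernel, kernel, kernel, 1, 1))),
    sp_b = ag_leaf(wg$sp_b)))
  out <- sgam_build(NULL, x, wl, as.integer(G), as.integer(kernel))
  as_public(out$value)
}

wrap_params <- function(params) {
  lapply(params, function(layer) lapply(layer, ag_leaf))
}

enc_block_build <- function(tape, x, pw, key, state, train) {
  h <- op_conv3d(tape, x, pw[[paste0(key, ".conv1")]]$w,
                 pw[[paste0(key, ".conv1")]]$b, K = 3L)
  h <- op_batchnorm(tape, h, pw[[paste0(key, ".bn1")]]$gamma,
                    pw[[paste0(key, ".bn1")]]$beta, state,
                    paste0(key, ".bn1"), train)
  h <- op_relu(tape, h)
  h <- op_conv3d(tape, h, pw[[paste0(key, ".conv2")]]$w,
                 pw[[paste0(key, ".conv2")]]$b, K = 3L)
  h <- op_batchnorm(tape, h, pw[[paste0(key, ".bn2")]]$gamma,
                    pw[[paste0(key, ".bn2")]]$beta, state,
                    paste0(key, ".bn2"), train)
  r <- op_conv3d(tape, x, pw[[paste0(key, ".proj")]]$w,
                 pw[[paste0(key, ".proj")]]$b, K = 1L, pad = 0L)
  op_relu(tape, op_add(tape, h, r))
}

dec_block_build <- function(tape, fe, fd, key, cfg, pw, state, train) {
  # fd has already been upsampled to fe's spatial shape and channel count
  if (!identical(dim5(fe$value)[1:3], dim5(fd$value)[1:3]))
    stop("decoder block: spatial shapes of skip and upsampled features differ")
  if (cfg$use_cfam) {
    r <- cfam_build(tape, fe, fd, pw[[paste0(key, ".cfam")]],
                    cfg$cfam_shared)
    fe <- r$fe
    fd <- r$fd
  }
  cat_ <- op_concat_c(tape, fe, fd)
  ff <- op_conv3d(tape, cat_, pw[[paste0(key, ".fuse")]]$w,
                  pw[[paste0(key, ".fuse")]]$b, K = 3L)
  ff <- op_batchnorm(tape, ff, pw[[paste0(key, ".fusebn")]]$gamma,
                     pw[[paste0(key, ".fusebn")]]$beta, state,
                     paste0(key, ".fusebn"), train)
  ff <- op_relu(tape, ff)
  fs <- if (cfg$use_sgam) {
    G <- cfg$sgam_groups
    wl <- lapply(seq_len(G), function(g) {
      lp <- pw[[paste0(key, ".sgam.g", g, ".pw")]]
      ls <- pw[[paste0(key, ".sgam.g", g, ".sp")]]
      list(pw_w = lp$w, pw_b = lp$b, sp_w = ls$w, sp_b = ls$b)
    })
    sgam_build(tape, ff, wl, G, cfg$sgam_kernel)
  } else ff
  h <- op_conv3d(tape, fs, pw[[paste0(key, ".post")]]$w,
                 pw[[paste0(key, ".post")]]$b, K = 3L)
  h <- op_batchnorm(tape, h, pw[[paste0(key, ".postbn")]]$gamma,
                    pw[[paste0(key, ".postbn")]]$beta, state,
                    paste0(key, ".postbn"), train)
  op_relu(tape, op_add(tape, h, fs))
}

net_forward <- function(tape, pw, x, cfg, state, train) {
  e1 <- enc_block_build(tape, x, pw, "e1", state, train)
  e2 <- enc_block_build(tape, op_maxpool2(tape, e1), pw, "e2", state, train)
  e3 <- enc_block_build(tape, op_maxpool2(tape, e2), pw, "e3", state, train)
  e4 <- enc_block_build(tape, op_maxpool2(tape, e3), pw, "e4", state, train)
  d <- e4
  skips <- list(e1, e2, e3)
  for (s in 3:1) {
    key <- paste0("d", s)
    up <- op_convtr2(tape, d, pw[[paste0(key, ".up")]]$w,
                     pw[[paste0(key, ".up")]]$b)
    d <- dec_block_build(tape, skips[[s]], up, key, cfg, pw, state, train)
  }
  z <- op_conv3d(tape, d, pw[["head"]]$w, pw[["head"]]$b, K = 1L, pad = 0L)
  op_sigmoid(tape, z)
}

#' Residual encoder block forward pass
#'
#' Two 3x3x3 convolution + batch-norm + ReLU layers with an additive
#' residual connection through a 1x1x1 projection; spatial shape is
#' preserved, channels follow the stage-doubling scheme.
#'
#' @param model a [cfsg_model].
#' @param F input feature map, C x L x W x H (C = 1 for stage 1).
#' @param stage encoder stage 1..4.
#' @param train batch-norm mode: batch statistics (`TRUE`) or running
#'   averages (`FALSE`, default).
#' @return Feature map of shape `base_channels * 2^(stage-1)` x L x W x H.
#' @export
encoder_block <- function(model, F, stage, train = FALSE) {
  stopifnot(inherits(model, "cfsg_model"), stage %in% 1:4)
  pw <- wrap_params(model$params)
  out <- enc_block_build(NULL, ag_leaf(as_internal(F)), pw,
                         paste0("e", stage), model$bn, train)
  as_public(out$value)
}

#' Decoder block forward pass
#'
#' Applies the decoder-stage sequence CFAM -> channel concatenation ->
#' fusion convolution block -> SGAM -> convolution block with residual
#' connection. `F_d` must already be upsampled to `F_e`'s spatial shape and
#' channel count. The `use_cfam`/`use_sgam` toggles of the model
#' configuration replace the respective module by the identity.
#'
#' @param model a [cfsg_model].
#' @param F_e skip (encoder) features, C x L x W x H.
#' @param F_d upsampled decoder features, same shape.
#' @param stage decoder stage 1..3 (stage s has `base_channels * 2^(s-1)`
#'   channels).
#' @param train batch-norm mode.
#' @return Feature map with `F_e`'s shape.
#' @export
decoder_block <- function(model, F_e, F_d, stage, train = FALSE) {
  stopifnot(inherits(model, "cfsg_model"), stage %in% 1:3)
  pw <- wrap_params(model$params)
  out <- dec_block_build(NULL, ag_leaf(as_internal(F_e)),
                         ag_leaf(as_internal(F_d)), paste0("d", stage),
                         model$config, pw, model$bn, train)
  as_public(out$value)
}

#' Full CFSG U-Net forward pass
#'
#' Maps a normalized patch to a voxelwise fracture probability map of the
#' same spatial shape. Spatial dimensions must be divisible by 8 (three
#' max-pooling stages).
#'
#' @param model a [cfsg_model].
#' @param patch 3D array in \[0,1\] (or 1 x L x W x H).
#' @param train batch-norm mode.
#' @return 3D array of probabilities in (0,1), same spatial shape.
#' @export
cfsg_forward <- function(model, patch, train = FALSE) {
  stopifnot(inherits(model, "cfsg_model"))
  d <- dim(patch)
  if (length(d) == 4L) {
    stopifnot(d[1] == 1L)
    patch <- array(patch, d[2:4])
    d <- d[2:4]
  }
  if (any(d %% 8L != 0L))
    stop("patch spatial dimensions must be divisible by 8, got ",
         paste(d, collapse = "x"))
  x <- array(patch, c(d, 1L, 1L))
  pw <- wrap_params(model$params)
  out <- net_forward(NULL, pw, ag_leaf(x), model$config, model$bn, train)
  array(out$value, d)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the [model_config], all weights, batch-norm running
#' statistics and (when saved from a fit) the training history, so a
#' checkpoint is self-describing.
#'
#' @param model a `cfsg_model` or `cfsg_unet` fit.
#' @param path destination file.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("cfsg_model", "cfsg_unet")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("cfsg_model", "cfsg_unet")))
    stop("not a model checkpoint: ", path)
  obj
}
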