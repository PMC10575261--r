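# Denoiser network: DiffWave-lineage residual blocks in which SPADE layers
# act as the diffusion layers, with a three-level diffusion-step embedding
# and multilabel conditioning injected in every block and once more after
# the skip-sum.

#' Denoiser model configuration
#'
#' The reference (GPU-scale) configuration is 4 residual layers, 256
#' residual and 256 skip channels, diffusion embedding dims (128, 256, 256),
#' 8 generated leads and L = 1000. The desk-scale defaults here are small
#' enough to train on one CPU in minutes.
#'
#' @param n_residual_layers number of residual blocks
#' @param residual_channels,skip_channels widths of the residual and skip
#'   streams; `residual_channels` must equal `spade$d_model`, and
#'   `skip_channels` must equal `residual_channels` (single SPADE width)
#' @param diff_embed_dims integer vector of exactly three widths for the
#'   sinusoidal + two-stage diffusion-step embedding
#' @param label_dim length C of the binary condition vector
#' @param signal_channels number of generated leads
#' @param L timesteps per record
#' @param spade a [spade_config()]; defaults to one matching
#'   `residual_channels`
#' @param n_local_layers local layers stacked above the global layer inside
#'   each block
#' @return object of class `dsat_config`
#' @export
dsat_config <- function(n_residual_layers = 2L, residual_channels = 32L,
                        skip_channels = 32L, diff_embed_dims = c(16L, 32L, 32L),
                        label_dim = 2L, signal_channels = 2L, L = 128L,
                        spade = NULL, n_local_layers = 1L) {
  if (length(diff_embed_dims) != 3L) stop("diff_embed_dims must have exactly three entries")
  if (any(c(n_residual_layers, residual_channels, skip_channels, diff_embed_dims,
            label_dim, signal_channels, L) < 1))
    stop("all dsat_config dimensions must be >= 1")
  if (is.null(spade)) spade <- spade_config(d_model = residual_channels)
  stopifnot(inherits(spade, "spade_config"))
  if (spade$d_model != residual_channels)
    stop("spade$d_model must equal residual_channels")
  if (skip_channels != residual_channels)
    stop("skip_channels must equal residual_channels in this implementation")
  structure(list(n_residual_layers = as.integer(n_residual_layers),
                 residual_channels = as.integer(residual_channels),
                 skip_channels = as.integer(skip_channels),
                 diff_embed_dims = as.integer(diff_embed_dims),
                 label_dim = as.integer(label_dim),
                 signal_channels = as.integer(signal_channels),
                 L = as.integer(L), spade = spade,
                 n_local_layers = as.integer(n_local_layers)),
            class = "dsat_config")
}

#' Reference-scale model configuration
#'
#' The full-scale training configuration: 4 residual layers, 256/256
#' channels, embedding dims (128, 256, 256), 12 labels, 8 leads, 1000
#' samples. Training it requires GPU-scale compute; shipped for
#' completeness, not exercised by the test suite.
#' @return a [dsat_config()]
#' @export
dsat_config_reference <- function() {
  dsat_config(n_residual_layers = 4L, residual_channels = 256L,
              skip_channels = 256L, diff_embed_dims = c(128L, 256L, 256L),
              label_dim = 12L, signal_channels = 8L, L = 1000L,
              spade = spade_config(d_model = 256L, window = 16L, n_heads = 8L,
                                   d_ffn = 512L, ssm_state_dim = 64L))
}

.sinusoid <- function(t, d0) {
  half <- max(1L, d0 %/% 2L)
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(1L, half - 1L))
  e <- c(sin(t * freq), cos(t * freq))
  e[seq_len(d0)]
}

#' Three-level diffusion-step embedding
#'
#' A sinusoidal code of width `dims[1]` passed through two affine + swish
#' stages to widths `dims[2]` and `dims[3]`. Deterministic in `t` for fixed
#' parameters.
#'
#' @param t integer diffusion step (>= 1)
#' @param dims the three embedding widths
#' @param params optional named list of nodes `W1, b1, W2, b2`; a seeded set
#'   is created when omitted
#' @param seed seed used when `params` is omitted
#' @return numeric vector of width `dims[3]`
#' @export
diffusion_embedding <- function(t, dims = c(128L, 256L, 256L), params = NULL, seed = 1L) {
  if (t < 1 || t != round(t)) stop("t must be a positive integer")
  if (length(dims) != 3L) stop("dims must have three entries")
  if (is.null(params)) {
    set.seed(seed)
    params <- list(W1 = ad_param(.init_mat(dims[1], dims[2])),
                   b1 = ad_param(rep(0, dims[2])),
                   W2 = ad_param(.init_mat(dims[2], dims[3])),
                   b2 = ad_param(rep(0, dims[3])))
  }
  ad_no_grad(as.numeric(ad_val(.embed_node(t, dims, params))))
}

.embed_node <- function(t, dims, params) {
  e <- ad_const(matrix(.sinusoid(t, dims[1]), 1L))
  h <- ad_swish(ad_linear(e, params$W1, params$b1))
  ad_swish(ad_linear(h, params$W2, params$b2))
}

#' Initialize a denoiser model
#'
#' @param cfg a [dsat_config()]
#' @param seed parameter-draw seed
#' @return object of class `dsat_model`: `cfg`, flat named `params` list of
#'   autodiff nodes, and the per-layer fixed structures (S4 kernel bases,
#'   attention masks)
#' @export
dsat_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "dsat_config"))
  set.seed(seed)
  C <- cfg$residual_channels
  Csig <- cfg$signal_channels
  de <- cfg$diff_embed_dims
  params <- list()
  layers <- list()
  params[["in.W"]] <- ad_param(.init_mat(Csig, C))
  params[["in.b"]] <- ad_param(rep(0, C))
  params[["emb.W1"]] <- ad_param(.init_mat(de[1], de[2]))
  params[["emb.b1"]] <- ad_param(rep(0, de[2]))
  params[["emb.W2"]] <- ad_param(.init_mat(de[2], de[3]))
  params[["emb.b2"]] <- ad_param(rep(0, de[3]))
  for (b in seq_len(cfg$n_residual_layers)) {
    pre <- sprintf("b%d.", b)
    params[[paste0(pre, "emb.W")]] <- ad_param(.init_mat(de[3], C))
    params[[paste0(pre, "emb.b")]] <- ad_param(rep(0, C))
    sp <- list(spade_init(cfg$spade, cfg$L, global = TRUE,
                          seed = derive_seed(seed, 100L * b)))
    for (j in seq_len(cfg$n_local_layers))
      sp[[j + 1L]] <- spade_init(cfg$spade, cfg$L, global = FALSE,
                                 seed = derive_seed(seed, 100L * b + j))
    for (j in seq_along(sp)) {
      for (nm in names(sp[[j]]$params))
        params[[sprintf("%ssp%d.%s", pre, j, nm)]] <- sp[[j]]$params[[nm]]
    }
    layers[[b]] <- sp
    params[[paste0(pre, "cond.W")]] <- ad_param(.init_mat(cfg$label_dim, 2L * C))
    params[[paste0(pre, "cond.b")]] <- ad_param(rep(0, 2L * C))
    params[[paste0(pre, "gate.W")]] <- ad_param(.init_mat(C, 2L * C))
    params[[paste0(pre, "gate.b")]] <- ad_param(rep(0, 2L * C))
    if (b < cfg$n_residual_layers) {
      # the final block's residual stream is never consumed, so its
      # projection would be untrainable dead weight; omit it
      params[[paste0(pre, "res.W")]] <- ad_param(.init_mat(C, C))
      params[[paste0(pre, "res.b")]] <- ad_param(rep(0, C))
    }
    params[[paste0(pre, "skip.W")]] <- ad_param(.init_mat(C, cfg$skip_channels))
    params[[paste0(pre, "skip.b")]] <- ad_param(rep(0, cfg$skip_channels))
  }
  post <- spade_init(cfg$spade, cfg$L, global = TRUE, seed = derive_seed(seed, 999L))
  for (nm in names(post$params)) params[[paste0("post.sp.", nm)]] <- post$params[[nm]]
  params[["post.cond.W"]] <- ad_param(.init_mat(cfg$label_dim, cfg$skip_channels))
  params[["post.cond.b"]] <- ad_param(rep(0, cfg$skip_channels))
  params[["out.W1"]] <- ad_param(.init_mat(cfg$skip_channels, cfg$skip_channels))
  params[["out.b1"]] <- ad_param(rep(0, cfg$skip_channels))
  params[["out.W2"]] <- ad_param(.init_mat(cfg$skip_channels, Csig, scale = 0.01))
  params[["out.b2"]] <- ad_param(rep(0, Csig))
  structure(list(cfg = cfg, params = params, layers = layers, post = post),
            class = "dsat_model")
}

#' Total trainable parameter count of a model
#' @param model a [dsat_init()] model
#' @return integer
#' @export
dsat_n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

# forward pass on autodiff nodes; X is an L x signal_channels node
dsat_forward_node <- function(model, X, t, cvec) {
  cfg <- model$cfg
  p <- model$params
  if (length(cvec) != cfg$label_dim)
    stop(sprintf("label vector length %d does not match label_dim %d",
                 length(cvec), cfg$label_dim))
  C <- cfg$residual_channels
  cn <- ad_const(matrix(as.numeric(cvec), 1L))
  emb <- .embed_node(t, cfg$diff_embed_dims,
                     list(W1 = p[["emb.W1"]], b1 = p[["emb.b1"]],
                          W2 = p[["emb.W2"]], b2 = p[["emb.b2"]]))
  h <- ad_relu(ad_linear(X, p[["in.W"]], p[["in.b"]]))
  skip <- NULL
  for (b in seq_len(cfg$n_residual_layers)) {
    pre <- sprintf("b%d.", b)
    eb <- ad_linear(emb, p[[paste0(pre, "emb.W")]], p[[paste0(pre, "emb.b")]])
    hb <- ad_add_rowvec(h, eb)
    for (layer in model$layers[[b]]) hb <- spade_forward_node(hb, layer)
    g <- ad_linear(hb, p[[paste0(pre, "gate.W")]], p[[paste0(pre, "gate.b")]])
    cb <- ad_linear(cn, p[[paste0(pre, "cond.W")]], p[[paste0(pre, "cond.b")]])
    g <- ad_add_rowvec(g, cb)
    z <- ad_mul(ad_tanh(ad_cols(g, seq_len(C))),
                ad_sigmoid(ad_cols(g, C + seq_len(C))))
    sk <- ad_linear(z, p[[paste0(pre, "skip.W")]], p[[paste0(pre, "skip.b")]])
    if (b < cfg$n_residual_layers) {
      res <- ad_linear(z, p[[paste0(pre, "res.W")]], p[[paste0(pre, "res.b")]])
      h <- ad_scale(ad_add(h, res), 1 / sqrt(2))
    }
    skip <- if (is.null(skip)) sk else ad_add(skip, sk)
  }
  s <- ad_scale(skip, 1 / sqrt(cfg$n_residual_layers))
  cpost <- ad_linear(cn, p[["post.cond.W"]], p[["post.cond.b"]])
  s <- ad_add_rowvec(s, cpost)
  s <- spade_forward_node(s, model$post)
  out <- ad_relu(ad_linear(s, p[["out.W1"]], p[["out.b1"]]))
  ad_linear(out, p[["out.W2"]], p[["out.b2"]])
}

# plain-numeric forward (no tape); mirrors dsat_forward_node. X holds B
# records stacked record-major as a (B*L) x signal_channels matrix; cmat is
# one label row per record (or a single row shared by all).
.dsat_forward_num <- function(model, X, t, cmat, B = 1L) {
  cfg <- model$cfg
  p <- model$params
  C <- cfg$residual_channels
  n <- nrow(X)
  L <- n %/% B
  cmat <- if (is.null(dim(cmat))) matrix(as.numeric(cmat), 1L) else as.matrix(cmat)
  shared_c <- nrow(cmat) == 1L
  # broadcast a per-record row matrix (B x d) over each record's L rows
  bc <- function(M) if (nrow(M) == 1L) rep(as.vector(M), each = n) else
    M[rep(seq_len(B), each = L), , drop = FALSE]
  e <- matrix(.sinusoid(t, cfg$diff_embed_dims[1]), 1L)
  sw <- function(x) x / (1 + exp(-x))
  emb <- sw(sw(e %*% p[["emb.W1"]]$val + p[["emb.b1"]]$val) %*% p[["emb.W2"]]$val +
              p[["emb.b2"]]$val)
  h <- pmax(X %*% p[["in.W"]]$val + rep(p[["in.b"]]$val, each = n), 0)
  skip <- NULL
  for (b in seq_len(cfg$n_residual_layers)) {
    pre <- sprintf("b%d.", b)
    eb <- as.vector(emb %*% p[[paste0(pre, "emb.W")]]$val) + p[[paste0(pre, "emb.b")]]$val
    hb <- h + rep(eb, each = n)
    for (layer in model$layers[[b]]) hb <- .spade_forward_num(hb, layer, B)
    g <- hb %*% p[[paste0(pre, "gate.W")]]$val + rep(p[[paste0(pre, "gate.b")]]$val, each = n)
    cb <- cmat %*% p[[paste0(pre, "cond.W")]]$val +
      rep(p[[paste0(pre, "cond.b")]]$val, each = nrow(cmat))
    g <- g + bc(cb)
    z <- tanh(g[, seq_len(C), drop = FALSE]) / (1 + exp(-g[, C + seq_len(C), drop = FALSE]))
    sk <- z %*% p[[paste0(pre, "skip.W")]]$val + rep(p[[paste0(pre, "skip.b")]]$val, each = n)
    if (b < cfg$n_residual_layers) {
      res <- z %*% p[[paste0(pre, "res.W")]]$val + rep(p[[paste0(pre, "res.b")]]$val, each = n)
      h <- (h + res) / sqrt(2)
    }
    skip <- if (is.null(skip)) sk else skip + sk
  }
  s <- skip / sqrt(cfg$n_residual_layers)
  cpost <- cmat %*% p[["post.cond.W"]]$val +
    rep(p[["post.cond.b"]]$val, each = nrow(cmat))
  s <- .spade_forward_num(s + bc(cpost), model$post, B)
  out <- pmax(s %*% p[["out.W1"]]$val + rep(p[["out.b1"]]$val, each = n), 0)
  out %*% p[["out.W2"]]$val + rep(p[["out.b2"]]$val, each = n)
}

# pack a model into plain matrices for the compiled forward pass; the S4
# kernel FFTs are precomputed here since they are fixed during sampling
.pack_model <- function(model) {
  cfg <- model$cfg
  pack_layer <- function(layer) {
    p <- lapply(layer$params, function(x) x$val)
    sp <- list(global = layer$global,
               banded = !is.null(layer$fixed$band))
    if (sp$banded) {
      sp$cells <- layer$fixed$band$cells - 1L
      sp$slots <- layer$fixed$band$slots - 1L
      sp$nb <- layer$fixed$band$nb
    }
    if (layer$global) {
      Mt <- layer$fixed$Mt
      Kmat <- vapply(seq_along(Mt), function(ch) as.numeric(Mt[[ch]] %*% p$C_ssm[ch, ]),
                     numeric(nrow(Mt[[1]])))
      sp$fk <- stats::mvfft(.fft_pad(Kmat, 2L * nrow(Kmat)))
    }
    c(sp, p)
  }
  d0 <- cfg$diff_embed_dims[1]
  half <- max(1L, d0 %/% 2L)
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(1L, half - 1L))
  list(params = lapply(model$params, function(x) x$val),
       blocks = lapply(model$layers, function(sp) list(layers = lapply(sp, pack_layer))),
       post = pack_layer(model$post),
       n_heads = cfg$spade$n_heads,
       residual_channels = cfg$residual_channels,
       sinusoid_base = c(freq, freq)[seq_len(d0)])
}

#' Denoiser forward pass
#'
#' Maps a noised record, a diffusion step and a label vector to the
#' predicted noise. Input and output are channels x timesteps matrices.
#' Inference runs on a plain-numeric path (no autodiff tape); training uses
#' the equivalent tracked path, and the two are asserted equal in the test
#' suite.
#'
#' @param model a [dsat_init()] model
#' @param xt numeric signal_channels x L matrix
#' @param t integer diffusion step
#' @param cvec binary label vector of length `label_dim`
#' @return numeric matrix, same shape as `xt`
#' @export
model_forward <- function(model, xt, t, cvec) {
  xt <- as.matrix(xt)
  cfg <- model$cfg
  if (nrow(xt) != cfg$signal_channels || ncol(xt) != cfg$L)
    stop(sprintf("xt must be %d x %d (got %d x %d)",
                 cfg$signal_channels, cfg$L, nrow(xt), ncol(xt)))
  if (length(cvec) != cfg$label_dim)
    stop(sprintf("label vector length %d does not match label_dim %d",
                 length(cvec), cfg$label_dim))
  t(.dsat_forward_num(model, t(xt), t, cvec))
}

#' Noise predictor closure for use with the diffusion API
#'
#' Wraps a model as the `predictor(xt, t, c)` function expected by
#' [training_loss()] and [reverse_sample()]; works on channels x L arrays.
#' @param model a [dsat_init()] model
#' @return function (xt, t, c) -> eps_hat
#' @export
dsat_predictor <- function(model) {
  function(xt, t, cvec) model_forward(model, xt, t, cvec)
}
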