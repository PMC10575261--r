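# SPADE layers: a global layer combining an S4 state-space branch with
# sliding-window local attention, and plain local layers (the same block
# with the SSM branch disabled). Layer composition:
#   X_local  = Local(LN(X))
#   X_global = SSM(LN(X))            (global layers only)
#   X_a      = W [LN(X_local), LN(X_global)] + X
#   Y        = FFN(LN(X_a)) + X_a
# Sequences are L x d_model matrices (time in rows).

#' SPADE layer configuration
#'
#' @param d_model feature width (must be divisible by `n_heads`)
#' @param window local-attention half-window: position i attends to j with
#'   |i - j| <= window (plus itself); `Inf` gives full attention
#' @param n_heads number of attention heads
#' @param d_ffn hidden width of the two-layer feed-forward network
#' @param ssm_state_dim state dimension N of the S4 branch
#' @return object of class `spade_config`
#' @export
spade_config <- function(d_model = 32L, window = 8L, n_heads = 2L,
                         d_ffn = 64L, ssm_state_dim = 8L) {
  stopifnot(d_model >= 1, n_heads >= 1, d_ffn >= 1, ssm_state_dim >= 1,
            window >= 0)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), window = window,
                 n_heads = as.integer(n_heads), d_ffn = as.integer(d_ffn),
                 ssm_state_dim = as.integer(ssm_state_dim)),
            class = "spade_config")
}

.init_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

#' Per-channel S4 kernel basis for a SPADE global layer
#'
#' Each of the `d_model` channels gets its own fixed stable HiPPO system
#' (standard normal form) with a log-uniform step size in `[1e-3, 1e-1]`;
#' only the output map C is trained, so the channel kernel is the linear
#' combination K_c = Mt_c C_c of N fixed basis kernels.
#' @keywords internal
ssm_basis <- function(d_model, N, L) {
  i <- 0:(N - 1)
  P <- sqrt(i + 0.5)
  S <- -sqrt(outer(i + 0.5, i + 0.5))
  S[upper.tri(S)] <- -S[upper.tri(S)]
  diag(S) <- -0.5
  A <- S - outer(P, P)
  B <- sqrt(2 * i + 1)
  deltas <- exp(stats::runif(d_model, log(1e-3), log(1e-1)))
  Mt <- vector("list", d_model)
  for (ch in seq_len(d_model)) {
    d <- deltas[ch]
    Minv <- solve(diag(N) - (d / 2) * A)
    Ab <- Minv %*% (diag(N) + (d / 2) * A)
    x <- as.numeric(Minv %*% (d * B))
    M <- matrix(0, L, N)
    for (k in seq_len(L)) {
      M[k, ] <- x
      if (k < L) x <- as.numeric(Ab %*% x)
    }
    Mt[[ch]] <- M  # L x N, kernel = M %*% C_ch
  }
  list(Mt = Mt, deltas = deltas)
}

# kernel matrix node (L x d_model) from the trainable C map (d_model x N)
ad_ssm_kernels <- function(Cmat, Mt) {
  Cmat <- ad_const(Cmat)
  d_model <- nrow(Cmat$val)
  K <- vapply(seq_len(d_model), function(ch) as.numeric(Mt[[ch]] %*% Cmat$val[ch, ]),
              numeric(nrow(Mt[[1]])))
  n <- ad_node(K, list(Cmat), function(n) {
    Mt <- n$aux
    dK <- n$grad
    dC <- t(vapply(seq_along(Mt), function(ch) as.numeric(crossprod(Mt[[ch]], dK[, ch])),
                   numeric(ncol(Mt[[1]]))))
    list(dC)
  })
  n$aux <- Mt
  n
}

.band_mask <- function(L, window) {
  if (!is.finite(window) || window >= L - 1) return(matrix(0, L, L))
  idx <- abs(outer(seq_len(L), seq_len(L), "-")) > window
  m <- matrix(0, L, L)
  m[idx] <- -1e9
  m
}

#' Initialize the parameters of one SPADE (or local) layer
#'
#' @param cfg a [spade_config()]
#' @param L sequence length (fixes the S4 kernel basis and attention mask)
#' @param global if TRUE include the S4 branch; if FALSE build a plain local
#'   layer (`X_a = W LN(X_local) + X`)
#' @param seed RNG seed for the parameter draw
#' @return list with `cfg`, `global`, named `params` (autodiff nodes) and
#'   `fixed` (kernel basis, attention mask)
#' @export
spade_init <- function(cfg, L, global = TRUE, seed = 1L) {
  stopifnot(inherits(cfg, "spade_config"))
  set.seed(seed)
  d <- cfg$d_model
  p <- list(
    ln0_g = ad_param(rep(1, d)), ln0_b = ad_param(rep(0, d)),
    Wq = ad_param(.init_mat(d, d)), Wk = ad_param(.init_mat(d, d)),
    Wv = ad_param(.init_mat(d, d)),
    Wo = ad_param(.init_mat(d, d)), bo = ad_param(rep(0, d)),
    lnl_g = ad_param(rep(1, d)), lnl_b = ad_param(rep(0, d)),
    ln2_g = ad_param(rep(1, d)), ln2_b = ad_param(rep(0, d)),
    W1 = ad_param(.init_mat(d, cfg$d_ffn)), b1 = ad_param(rep(0, cfg$d_ffn)),
    W2 = ad_param(.init_mat(cfg$d_ffn, d, scale = 0.02)), b2 = ad_param(rep(0, d))
  )
  fixed <- list(L = L, band = if (is.finite(cfg$window) && cfg$window < L - 1)
    band_index(L, as.integer(cfg$window)) else NULL)
  if (global) {
    basis <- ssm_basis(d, cfg$ssm_state_dim, L)
    fixed$Mt <- basis$Mt
    fixed$deltas <- basis$deltas
    p$lng_g <- ad_param(rep(1, d)); p$lng_b <- ad_param(rep(0, d))
    p$C_ssm <- ad_param(.init_mat(d, cfg$ssm_state_dim))
    p$Wcat <- ad_param(.init_mat(2 * d, d))
  } else {
    p$Wcat <- ad_param(.init_mat(d, d))
  }
  p$bcat <- ad_param(rep(0, d))
  list(cfg = cfg, global = global, params = p, fixed = fixed)
}

# band for a layer at runtime length L (cached for the configured length)
.layer_band <- function(layer, L) {
  if (L == layer$fixed$L) return(layer$fixed$band)
  if (is.finite(layer$cfg$window) && layer$cfg$window < L - 1)
    band_index(L, as.integer(layer$cfg$window)) else NULL
}

# multi-head sliding-window attention on an autodiff node (L x d)
.attention_node <- function(Xn, layer) {
  cfg <- layer$cfg; p <- layer$params
  L <- nrow(ad_val(Xn))
  bi <- .layer_band(layer, L)
  Q <- ad_linear(Xn, p$Wq); K <- ad_linear(Xn, p$Wk); V <- ad_linear(Xn, p$Wv)
  dh <- cfg$d_model %/% cfg$n_heads
  heads <- vector("list", cfg$n_heads)
  for (h in seq_len(cfg$n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- ad_tcrossprod(ad_cols(Q, idx), ad_cols(K, idx), scale = 1 / sqrt(dh))
    P <- if (is.null(bi)) ad_softmax_rows(S) else ad_softmax_band(S, bi)
    heads[[h]] <- ad_matmul(P, ad_cols(V, idx))
  }
  O <- heads[[1]]
  if (cfg$n_heads > 1L) for (h in 2:cfg$n_heads) O <- ad_cbind2(O, heads[[h]])
  ad_linear(O, p$Wo, p$bo)
}

# full layer on an autodiff node; used by both the public API and the model
spade_forward_node <- function(X, layer) {
  p <- layer$params
  Xn <- ad_layernorm(X, p$ln0_g, p$ln0_b)
  Xl <- .attention_node(Xn, layer)
  branch <- ad_layernorm(Xl, p$lnl_g, p$lnl_b)
  if (layer$global) {
    K <- ad_ssm_kernels(p$C_ssm, layer$fixed$Mt)
    Xg <- ad_causal_conv(Xn, K)
    branch <- ad_cbind2(branch, ad_layernorm(Xg, p$lng_g, p$lng_b))
  }
  Xa <- ad_add(ad_linear(branch, p$Wcat, p$bcat), X)
  H <- ad_layernorm(Xa, p$ln2_g, p$ln2_b)
  ffn <- ad_linear(ad_gelu(ad_linear(H, p$W1, p$b1)), p$W2, p$b2)
  ad_add(ffn, Xa)
}

# --- plain-numeric inference path -------------------------------------------
# Mirrors spade_forward_node on raw matrices (no tape, no node allocation);
# used for sampling, where no gradients are needed. Equality with the
# autodiff path is asserted in the test suite.

.ln_num <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  xhat <- xc / sqrt(rowMeans(xc^2) + eps)
  xhat * rep(as.vector(g), each = nrow(x)) + rep(as.vector(b), each = nrow(x))
}

.softmax_rows_num <- function(x) {
  e <- exp(x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))])
  e / rowSums(e)
}

.gelu_num <- function(x) x / (1 + exp(-1.702 * x))

# B records stacked as a (B*L) x d matrix (record-major row blocks);
# attention runs per record, everything else is batched
.attention_num <- function(Xn, layer, B = 1L) {
  cfg <- layer$cfg; p <- layer$params
  L <- nrow(Xn) %/% B
  bi <- .layer_band(layer, L)
  Q <- Xn %*% p$Wq$val; K <- Xn %*% p$Wk$val; V <- Xn %*% p$Wv$val
  dh <- cfg$d_model %/% cfg$n_heads
  O <- matrix(0, nrow(Xn), cfg$d_model)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, idx, drop = FALSE], K[rows, idx, drop = FALSE]) / sqrt(dh)
      P <- if (is.null(bi)) .softmax_rows_num(S) else .softmax_band_val(S, bi)
      O[rows, idx] <- P %*% V[rows, idx, drop = FALSE]
    }
  }
  O %*% p$Wo$val + rep(p$bo$val, each = nrow(Xn))
}

# batched causal convolution: reshape (B*L) x d -> L x (d*B), one FFT pass
.causal_conv_num <- function(Xn, Kmat, B) {
  L <- nrow(Kmat); d <- ncol(Kmat); m <- 2L * L
  if (B == 1L) {
    return(Re(stats::mvfft(stats::mvfft(.fft_pad(Xn, m)) * stats::mvfft(.fft_pad(Kmat, m)),
                           inverse = TRUE))[seq_len(L), , drop = FALSE] / m)
  }
  Xw <- Xn
  dim(Xw) <- c(L, B * d)              # columns ordered channel-major, record fastest
  fk <- stats::mvfft(.fft_pad(Kmat, m))[, rep(seq_len(d), each = B), drop = FALSE]
  Yw <- Re(stats::mvfft(stats::mvfft(.fft_pad(Xw, m)) * fk,
                        inverse = TRUE))[seq_len(L), , drop = FALSE] / m
  dim(Yw) <- c(L * B, d)
  Yw
}

.spade_forward_num <- function(X, layer, B = 1L) {
  p <- layer$params
  n <- nrow(X)
  Xn <- .ln_num(X, p$ln0_g$val, p$ln0_b$val)
  branch <- .ln_num(.attention_num(Xn, layer, B), p$lnl_g$val, p$lnl_b$val)
  if (layer$global) {
    Mt <- layer$fixed$Mt
    Kmat <- vapply(seq_len(ncol(Xn)), function(ch) as.numeric(Mt[[ch]] %*% p$C_ssm$val[ch, ]),
                   numeric(nrow(Mt[[1]])))
    Xg <- .causal_conv_num(Xn, Kmat, B)
    branch <- cbind(branch, .ln_num(Xg, p$lng_g$val, p$lng_b$val))
  }
  Xa <- branch %*% p$Wcat$val + rep(p$bcat$val, each = n) + X
  H <- .ln_num(Xa, p$ln2_g$val, p$ln2_b$val)
  ffn <- .gelu_num(H %*% p$W1$val + rep(p$b1$val, each = n)) %*% p$W2$val +
    rep(p$b2$val, each = n)
  ffn + Xa
}

#' Sliding-window multi-head self-attention
#'
#' Scaled dot-product attention in which position i attends only to
#' positions j with |i - j| <= `cfg$window` (softmax over the visible
#' window). With `window >= L - 1` this reduces to full self-attention.
#'
#' @param X numeric L x d_model matrix
#' @param cfg a [spade_config()]
#' @param layer optional layer from [spade_init()] supplying the projection
#'   weights; a fresh seeded layer is created when omitted
#' @param seed seed used when `layer` is omitted
#' @return numeric L x d_model matrix
#' @export
local_attention <- function(X, cfg, layer = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("local_attention: input must be finite")
  if (is.null(layer)) layer <- spade_init(cfg, nrow(X), global = FALSE, seed = seed)
  ad_no_grad(ad_val(.attention_node(ad_const(X), layer)))
}

#' Apply one SPADE (or local) layer
#'
#' @param X numeric L x d_model matrix
#' @param layer a layer built by [spade_init()]
#' @return numeric L x d_model matrix, same shape as the input
#' @export
spade_forward <- function(X, layer) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("spade_forward: input must be finite")
  if (ncol(X) != layer$cfg$d_model)
    stop(sprintf("input width %d does not match d_model %d", ncol(X), layer$cfg$d_model))
  ad_no_grad(ad_val(spade_forward_node(ad_const(X), layer)))
}
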