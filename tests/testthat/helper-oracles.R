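# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (enumeration, direct summation, dense linear
# algebra) and never call the implementation paths they check.

# HiPPO construction, re-evaluated entry by entry from the printed formulas
oracle_hippo_A <- function(N, form = "printed") {
  A <- matrix(0, N, N)
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    base <- if (i == j) {
      if (form == "printed") 0.5 else -0.5
    } else if (i > j) {
      -sqrt((i + 0.5) * (j + 0.5))
    } else {
      if (form == "printed") -sqrt((i + 0.5) * (j + 0.5)) else sqrt((i + 0.5) * (j + 0.5))
    }
    A[i + 1, j + 1] <- base - sqrt(i + 0.5) * sqrt(j + 0.5)
  }
  A
}

# y_k from the expanded recurrence sum, term by term (one matrix power each)
oracle_ssm_expanded <- function(A_bar, B_bar, C, u) {
  L <- length(u)
  N <- nrow(A_bar)
  y <- numeric(L)
  for (k in seq_len(L)) {
    acc <- 0
    Ap <- diag(N)
    for (j in k:1) {          # term C A^(k-j) B u_j
      acc <- acc + sum(C * (Ap %*% B_bar)) * u[j]
      Ap <- A_bar %*% Ap
    }
    y[k] <- acc
  }
  y
}

# a random stable discrete system via the package-independent route:
# draw continuous A with negative-definite symmetric part
oracle_random_ssm <- function(N, L, seed) {
  set.seed(seed)
  A <- matrix(rnorm(N * N), N, N)
  A <- A - t(A) - diag(N) * (1 + runif(1))
  delta <- runif(1, 0.05, 0.5)
  list(params = ssm_params(A, rnorm(N), rnorm(N), D = 0, delta = delta), L = L)
}

# DTW by exhaustive enumeration of all monotone warping paths (memoized on
# the grid); exact for short integer series
oracle_dtw <- function(x, y) {
  N <- length(x); M <- length(y)
  memo <- matrix(NA_real_, N, M)
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- (x[i] - y[j])^2
    v <- if (i == 1 && j == 1) cost else
      cost + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(N, M)
}

# MMD by explicit double sums
oracle_mmd <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  s1 <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) s1 <- s1 + k(X[i, ], X[j, ])
  s2 <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) s2 <- s2 + k(Y[i, ], Y[j, ])
  s3 <- 0
  for (i in 1:n) for (j in 1:m) s3 <- s3 + k(X[i, ], Y[j, ])
  s1 / (n * (n - 1)) + s2 / (m * (m - 1)) - 2 * s3 / (n * m)
}

# macro AUROC by brute-force pair counting with ties worth 1/2
oracle_auroc <- function(scores, truth) {
  per <- c()
  for (j in seq_len(ncol(truth))) {
    pos <- scores[truth[, j] == 1, j]
    neg <- scores[truth[, j] == 0, j]
    if (length(pos) == 0 || length(neg) == 0) next
    s <- 0
    for (p in pos) for (q in neg) s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    per <- c(per, s / (length(pos) * length(neg)))
  }
  mean(per)
}

# dense self-attention with an explicit additive -Inf window mask
oracle_masked_attention <- function(X, layer, window) {
  p <- lapply(layer$params, function(x) x$val)
  L <- nrow(X)
  d <- ncol(X)
  nh <- layer$cfg$n_heads
  dh <- d / nh
  mask <- matrix(0, L, L)
  mask[abs(outer(seq_len(L), seq_len(L), "-")) > window] <- -Inf
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  O <- matrix(0, L, d)
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh) + mask
    P <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    O[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  sweep(O %*% p$Wo, 2, p$bo, "+")
}

# attention weights of one head under the same masking, for exact-zero checks
oracle_attention_weights <- function(X, layer, window, head = 1) {
  p <- lapply(layer$params, function(x) x$val)
  L <- nrow(X); d <- ncol(X)
  dh <- d / layer$cfg$n_heads
  idx <- ((head - 1) * dh + 1):(head * dh)
  Q <- (X %*% p$Wq)[, idx, drop = FALSE]
  K <- (X %*% p$Wk)[, idx, drop = FALSE]
  S <- Q %*% t(K) / sqrt(dh)
  S[abs(outer(seq_len(L), seq_len(L), "-")) > window] <- -Inf
  t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

# tiny desk fixtures shared across tests
tiny_spade_cfg <- function(d_model = 4L, window = 1L, n_heads = 2L)
  spade_config(d_model = d_model, window = window, n_heads = n_heads,
               d_ffn = 6L, ssm_state_dim = 3L)

tiny_model_cfg <- function(L = 32L)
  dsat_config(n_residual_layers = 2L, residual_channels = 8L,
              skip_channels = 8L, diff_embed_dims = c(6L, 8L, 8L),
              label_dim = 2L, signal_channels = 2L, L = L,
              spade = spade_config(d_model = 8L, window = 3L, n_heads = 2L,
                                   d_ffn = 12L, ssm_state_dim = 4L))
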