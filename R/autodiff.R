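# Minimal tape-based reverse-mode automatic differentiation.
#
# Nodes are environments carrying $val (numeric vector/matrix), $grad
# (accumulated, same shape), $parents and a backward closure $bw that maps
# the node's gradient to a list of parent gradients. Every op executed while
# gradients are enabled appends its node to a global tape; ad_backward()
# walks the tape in reverse creation order. Constants are not tracked, so
# inference with ad_no_grad() pays no tape cost.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$k <- 0L
.ad$enabled <- TRUE

ad_reset_tape <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$k <- 0L
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
ad_no_grad <- function(expr) {
  old <- .ad$enabled
  .ad$enabled <- FALSE
  on.exit(.ad$enabled <- old)
  expr
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$ad_node)

ad_node <- function(val, parents = NULL, bw = NULL, track = TRUE) {
  n <- new.env(parent = emptyenv())
  n$ad_node <- TRUE
  n$val <- val
  n$grad <- NULL
  if (!is.null(bw) && isTRUE(.ad$enabled)) {
    n$parents <- parents
    n$bw <- bw
    n$track <- track
    k <- .ad$k + 1L
    if (k > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[k]] <- n
    .ad$k <- k
  } else {
    n$parents <- NULL
    n$bw <- NULL
    n$track <- track && !is.null(bw)  # leaf params stay tracked
  }
  n
}

#' Create a trainable parameter node
#' @param val initial numeric value (vector or matrix)
#' @keywords internal
ad_param <- function(val) {
  n <- ad_node(val, track = TRUE)
  n$track <- TRUE
  n$is_param <- TRUE
  n
}

ad_const <- function(val) {
  if (ad_is_node(val)) return(val)
  n <- ad_node(val, track = FALSE)
  n$track <- FALSE
  n
}

ad_val <- function(x) if (ad_is_node(x)) x$val else x

.ad_acc <- function(p, g) {
  if (is.null(p) || !isTRUE(p$track)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar output node
#' @param out node produced by tracked ops; its gradient seed is 1
#' @keywords internal
ad_backward <- function(out) {
  stopifnot(ad_is_node(out))
  if (is.null(out$bw)) stop("ad_backward: output node is not on the tape (gradients disabled?)")
  out$grad <- if (is.null(out$grad)) array(1, dim = if (is.null(dim(out$val))) length(out$val) else dim(out$val)) else out$grad
  if (length(out$val) == 1L) out$grad <- 1
  for (i in rev(seq_len(.ad$k))) {
    n <- .ad$tape[[i]]
    if (is.null(n$grad)) next
    gs <- n$bw(n)
    ps <- n$parents
    for (j in seq_along(ps)) .ad_acc(ps[[j]], gs[[j]])
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- shape helpers -----------------------------------------------------------

.reduce_like <- function(g, ref) {
  # collapse a gradient to the shape of ref (handles scalar parents)
  if (length(ref) == 1L) return(sum(g))
  g
}

# --- elementwise ops ---------------------------------------------------------

ad_add <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$val + b$val, list(a, b), function(n) {
    list(.reduce_like(n$grad, n$parents[[1]]$val),
         .reduce_like(n$grad, n$parents[[2]]$val))
  })
}

ad_sub <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$val - b$val, list(a, b), function(n) {
    list(.reduce_like(n$grad, n$parents[[1]]$val),
         .reduce_like(-n$grad, n$parents[[2]]$val))
  })
}

ad_mul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$val * b$val, list(a, b), function(n) {
    av <- n$parents[[1]]$val; bv <- n$parents[[2]]$val
    list(.reduce_like(n$grad * bv, av), .reduce_like(n$grad * av, bv))
  })
}

ad_scale <- function(a, s) {  # s plain numeric scalar
  a <- ad_const(a)
  ad_node(a$val * s, list(a), function(n) list(n$grad * s))
}

ad_tanh <- function(a) {
  a <- ad_const(a)
  v <- tanh(a$val)
  ad_node(v, list(a), function(n) list(n$grad * (1 - n$val^2)))
}

ad_sigmoid <- function(a) {
  a <- ad_const(a)
  v <- 1 / (1 + exp(-a$val))
  ad_node(v, list(a), function(n) list(n$grad * n$val * (1 - n$val)))
}

ad_relu <- function(a) {
  a <- ad_const(a)
  ad_node(pmax(a$val, 0), list(a), function(n) list(n$grad * (n$parents[[1]]$val > 0)))
}

ad_swish <- function(a) {  # x * sigmoid(x)
  a <- ad_const(a)
  s <- 1 / (1 + exp(-a$val))
  n <- ad_node(a$val * s, list(a), function(n) {
    x <- n$parents[[1]]$val
    s <- n$aux
    list(n$grad * (s + x * s * (1 - s)))
  })
  n$aux <- s
  n
}

ad_gelu <- function(a) {  # sigmoid form: x * sigmoid(1.702 x)
  a <- ad_const(a)
  x <- a$val
  s <- 1 / (1 + exp(-1.702 * x))
  n <- ad_node(x * s, list(a), function(n) {
    x <- n$parents[[1]]$val
    s <- n$aux
    list(n$grad * (s + 1.702 * x * s * (1 - s)))
  })
  n$aux <- s
  n
}

# --- linear algebra ----------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$val %*% b$val, list(a, b), function(n) {
    list(tcrossprod(n$grad, n$parents[[2]]$val),
         crossprod(n$parents[[1]]$val, n$grad))
  })
}

ad_transpose <- function(a) {
  a <- ad_const(a)
  ad_node(t(a$val), list(a), function(n) list(t(n$grad)))
}

#' Affine map X W + b with the bias broadcast over rows
#' @keywords internal
ad_linear <- function(x, w, b = NULL) {
  x <- ad_const(x); w <- ad_const(w)
  v <- x$val %*% w$val
  if (!is.null(b)) {
    b <- ad_const(b)
    v <- v + rep(as.vector(b$val), each = nrow(v))
    ad_node(v, list(x, w, b), function(n) {
      g <- n$grad
      list(tcrossprod(g, n$parents[[2]]$val),
           crossprod(n$parents[[1]]$val, g), colSums(g))
    })
  } else {
    ad_node(v, list(x, w), function(n) {
      g <- n$grad
      list(tcrossprod(g, n$parents[[2]]$val),
           crossprod(n$parents[[1]]$val, g))
    })
  }
}

#' Add a length-d (or 1 x d) vector to every row of an L x d matrix
#' @keywords internal
ad_add_rowvec <- function(x, v) {
  x <- ad_const(x); v <- ad_const(v)
  vv <- as.vector(v$val)
  ad_node(x$val + rep(vv, each = nrow(x$val)), list(x, v), function(n) {
    g2 <- colSums(n$grad)
    if (is.matrix(n$parents[[2]]$val)) g2 <- matrix(g2, 1L)
    list(n$grad, g2)
  })
}

#' A %*% t(B), fused (avoids a transpose node); optional scalar scale
#' @keywords internal
ad_tcrossprod <- function(a, b, scale = 1) {
  a <- ad_const(a); b <- ad_const(b)
  n <- ad_node(tcrossprod(a$val, b$val) * scale, list(a, b), function(n) {
    s <- n$aux
    list((n$grad %*% n$parents[[2]]$val) * s,
         crossprod(n$grad, n$parents[[1]]$val) * s)
  })
  n$aux <- scale
  n
}

ad_cols <- function(x, idx) {
  x <- ad_const(x)
  n <- ad_node(x$val[, idx, drop = FALSE], list(x), function(n) {
    g0 <- array(0, dim = dim(n$parents[[1]]$val))
    g0[, n$aux] <- g0[, n$aux] + n$grad
    list(g0)
  })
  n$aux <- idx
  n
}

ad_cbind2 <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  na <- ncol(a$val)
  n <- ad_node(cbind(a$val, b$val), list(a, b), function(n) {
    na <- n$aux
    list(n$grad[, seq_len(na), drop = FALSE],
         n$grad[, -seq_len(na), drop = FALSE])
  })
  n$aux <- na
  n
}

#' Banded-support index for sliding-window attention
#'
#' Precomputes the column-major cell indices of the |i - j| <= w band of an
#' L x L matrix and the matching slots of its L x (2w+1) packed layout.
#' @keywords internal
band_index <- function(L, w) {
  nb <- 2L * w + 1L
  off <- rep(-w:w, each = L)
  i <- rep(seq_len(L), nb)
  j <- i + off
  ok <- j >= 1L & j <= L
  list(L = L, nb = nb,
       cells = (i + (j - 1L) * L)[ok],
       slots = (i + (off + w) * L)[ok])
}

# packed-band softmax: rows normalized over the visible window only,
# out-of-window weights exactly 0; returns the full (mostly zero) L x L map
.softmax_band_val <- function(S, bi) {
  L <- bi$L
  Sb <- matrix(-Inf, L, bi$nb)
  Sb[bi$slots] <- S[bi$cells]
  rm <- Sb[cbind(seq_len(L), max.col(Sb, ties.method = "first"))]
  E <- exp(Sb - rm)
  Pb <- E / rowSums(E)
  P <- matrix(0, L, L)
  P[bi$cells] <- Pb[bi$slots]
  P
}

#' Row-wise softmax restricted to a band of visible positions
#' @keywords internal
ad_softmax_band <- function(x, bi) {
  x <- ad_const(x)
  ad_node(.softmax_band_val(x$val, bi), list(x), function(n) {
    p <- n$val; g <- n$grad
    list(p * (g - rowSums(g * p)))
  })
}

#' Row-wise softmax
#' @keywords internal
ad_softmax_rows <- function(x) {
  x <- ad_const(x)
  xv <- x$val
  rowmax <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - rowmax)
  p <- e / rowSums(e)
  ad_node(p, list(x), function(n) {
    p <- n$val; g <- n$grad
    list(p * (g - rowSums(g * p)))
  })
}

#' Row-wise layer normalization with learnable scale/shift
#' @keywords internal
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ad_const(x); gamma <- ad_const(gamma); beta <- ad_const(beta)
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  L <- nrow(xv)
  y <- xhat * rep(as.vector(gamma$val), each = L) + rep(as.vector(beta$val), each = L)
  n <- ad_node(y, list(x, gamma, beta), function(n) {
    a <- n$aux
    g <- n$grad
    dxhat <- g * rep(as.vector(n$parents[[2]]$val), each = nrow(g))
    dx <- (dxhat - rowMeans(dxhat) - a$xhat * rowMeans(dxhat * a$xhat)) * a$inv
    list(dx, colSums(g * a$xhat), colSums(g))
  })
  n$aux <- list(xhat = xhat, inv = inv)
  n
}

# --- convolution -------------------------------------------------------------

.fft_pad <- function(m, len) rbind(m, matrix(0, len - nrow(m), ncol(m)))

#' Causal (one-sided) convolution of each column of u with each column of K
#'
#' u and K are L x C; output `y[i,c] = sum_d K[d+1,c] * u[i-d,c]` over d >= 0.
#' Computed via length-2L FFTs, batched over channels.
#' @keywords internal
ad_causal_conv <- function(u, K) {
  u <- ad_const(u); K <- ad_const(K)
  L <- nrow(u$val); m <- 2L * L
  fu <- stats::mvfft(.fft_pad(u$val, m))
  fk <- stats::mvfft(.fft_pad(K$val, m))
  y <- Re(stats::mvfft(fu * fk, inverse = TRUE))[seq_len(L), , drop = FALSE] / m
  n <- ad_node(y, list(u, K), function(n) {
    a <- n$aux
    L <- nrow(n$val); m <- 2L * L
    fg <- stats::mvfft(.fft_pad(n$grad, m))
    du <- Re(stats::mvfft(Conj(a$fk) * fg, inverse = TRUE))[seq_len(L), , drop = FALSE] / m
    dK <- Re(stats::mvfft(Conj(a$fu) * fg, inverse = TRUE))[seq_len(L), , drop = FALSE] / m
    list(du, dK)
  })
  n$aux <- list(fu = fu, fk = fk)
  n
}

#' Shift rows of a matrix down by `o` (zero fill), o may be negative
#' @keywords internal
ad_shift_rows <- function(x, o) {
  x <- ad_const(x)
  L <- nrow(x$val)
  shift <- function(m, o) {
    if (o == 0L) return(m)
    out <- matrix(0, nrow(m), ncol(m))
    if (o > 0L && o < L) out[(o + 1L):L, ] <- m[1L:(L - o), ]
    if (o < 0L && -o < L) out[1L:(L + o), ] <- m[(1L - o):L, ]
    out
  }
  n <- ad_node(shift(x$val, o), list(x), function(n) list(n$aux$shift(n$grad, -n$aux$o)))
  n$aux <- list(o = o, shift = shift)
  n
}

# --- reductions and losses ---------------------------------------------------

ad_colmeans <- function(x) {
  x <- ad_const(x)
  L <- nrow(x$val)
  ad_node(matrix(colMeans(x$val), 1L), list(x), function(n) {
    L <- nrow(n$parents[[1]]$val)
    list(matrix(rep(n$grad / L, each = L), L))
  })
}

ad_mean <- function(x) {
  x <- ad_const(x)
  ad_node(mean(x$val), list(x), function(n) {
    v <- n$parents[[1]]$val
    g <- array(n$grad / length(v), dim = if (is.null(dim(v))) length(v) else dim(v))
    list(g)
  })
}

#' Mean squared error against a constant target
#' @keywords internal
ad_mse <- function(pred, target) {
  pred <- ad_const(pred)
  tv <- ad_val(target)
  d <- pred$val - tv
  n <- ad_node(mean(d^2), list(pred), function(n) list(2 * n$aux / length(n$aux) * n$grad))
  n$aux <- d
  n
}

#' Mean of a list of scalar nodes
#' @keywords internal
ad_mean_list <- function(nodes) {
  vals <- vapply(nodes, function(n) as.numeric(n$val), numeric(1))
  ad_node(mean(vals), nodes, function(n) {
    as.list(rep(n$grad / length(n$parents), length(n$parents)))
  })
}

#' Numerically stable binary cross-entropy from logits
#' @param z logits node (any shape), y constant 0/1 targets, same shape
#' @keywords internal
ad_bce_logits <- function(z, y) {
  z <- ad_const(z)
  yv <- ad_val(y)
  zv <- z$val
  # log(1 + exp(z)) - y z, stable form
  loss <- mean(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv))))
  n <- ad_node(loss, list(z), function(n) {
    zv <- n$parents[[1]]$val
    s <- 1 / (1 + exp(-zv))
    list((s - n$aux) / length(zv) * n$grad)
  })
  n$aux <- yv
  n
}

# --- optimizer ---------------------------------------------------------------

#' Create an Adam optimizer over a flat named list of parameter nodes
#' @param params named list of `ad_param` nodes
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @return optimizer state environment; advance with [adam_step()]
#' @keywords internal
adam_init <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = if (is.null(dim(p$val))) length(p$val) else dim(p$val)))
  st$v <- lapply(params, function(p) array(0, dim = if (is.null(dim(p$val))) length(p$val) else dim(p$val)))
  st
}

#' One Adam update from the gradients accumulated in the parameter nodes
#' @keywords internal
adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * as.vector(g)
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * as.vector(g)^2
    upd <- st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
    dim(upd) <- dim(p$val)
    p$val <- p$val - upd
  }
  invisible(st)
}

# serialize / restore parameter values and optimizer state (RDS-safe lists)

ad_params_values <- function(params) lapply(params, function(p) p$val)

ad_params_restore <- function(params, values) {
  stopifnot(identical(names(params), names(values)))
  for (i in seq_along(params)) params[[i]]$val <- values[[i]]
  invisible(params)
}

adam_state_save <- function(st) list(t = st$t, m = st$m, v = st$v, lr = st$lr,
                                     beta1 = st$beta1, beta2 = st$beta2, eps = st$eps)

adam_state_restore <- function(st, saved) {
  st$t <- saved$t; st$m <- saved$m; st$v <- saved$v
  st$lr <- saved$lr; st$beta1 <- saved$beta1; st$beta2 <- saved$beta2; st$eps <- saved$eps
  invisible(st)
}
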