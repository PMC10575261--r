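# Structured state-space (S4) core: construction, discretization, application.

#' Continuous-time state-space parameters
#'
#' Bundles the continuous system x'(t) = A x(t) + B u(t), y(t) = C x(t) + D u(t)
#' together with the discretization step size.
#'
#' @param A real N x N state matrix
#' @param B real length-N input map
#' @param C real length-N output map
#' @param D optional scalar feedthrough (default 0)
#' @param delta positive step size used by [discretize()]
#' @return an object of class `ssm_params`
#' @export
ssm_params <- function(A, B, C, D = 0, delta) {
  A <- as.matrix(A)
  B <- as.numeric(B); C <- as.numeric(C); D <- as.numeric(D)
  N <- nrow(A)
  if (ncol(A) != N) stop("A must be square")
  if (length(B) != N || length(C) != N) stop("B and C must have length nrow(A)")
  if (length(D) != 1) stop("D must be a scalar")
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) || delta <= 0)
    stop("delta must be a positive finite scalar")
  if (!all(is.finite(A)) || !all(is.finite(B)) || !all(is.finite(C)) || !is.finite(D))
    stop("ssm_params: all entries must be finite")
  structure(list(A = A, B = B, C = C, D = D, delta = delta, N = N),
            class = "ssm_params")
}

#' HiPPO initialization of a state-space model
#'
#' Builds the transition matrix as a diagonal-plus-low-rank correction
#' A = A_base - P P^T with P_i = sqrt(i + 1/2) and B_i = sqrt(2 i + 1)
#' (0-based indices). Two variants of `A_base` are offered:
#'
#' * `form = "printed"`: entries -sqrt((i+1/2)(j+1/2)) on *both* triangles
#'   with +1/2 on the diagonal. This yields a symmetric A with positive
#'   eigenvalues, i.e. an unstable continuous system; it is retained because
#'   it is one circulating reading of the construction.
#' * `form = "s4"`: the standard normal form, -sqrt((i+1/2)(j+1/2)) below the
#'   diagonal, +sqrt((i+1/2)(j+1/2)) above, -1/2 on the diagonal. All
#'   eigenvalues of A then have negative real part and the discretized
#'   kernel is stable for any delta in (0, 2).
#'
#' The output map C is drawn from a seeded standard normal; D is 0.
#'
#' @param N state dimension (>= 1)
#' @param delta step size stored for later discretization
#' @param form which reading of the base matrix to use (see Details)
#' @param seed seed for the random C draw
#' @return an `ssm_params` object
#' @export
build_hippo <- function(N, delta = 0.01, form = c("printed", "s4"), seed = 1L) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("N must be a positive integer")
  form <- match.arg(form)
  N <- as.integer(N)
  i <- 0:(N - 1)
  P <- sqrt(i + 0.5)
  S <- -sqrt(outer(i + 0.5, i + 0.5))
  if (form == "printed") {
    diag(S) <- 0.5
  } else {
    S[upper.tri(S)] <- -S[upper.tri(S)]
    diag(S) <- -0.5
  }
  A <- S - outer(P, P)
  B <- sqrt(2 * i + 1)
  set.seed(seed)
  C <- stats::rnorm(N)
  ssm_params(A, B, C, D = 0, delta = delta)
}

#' Discretize a state-space model by the bilinear (Tustin) transform
#'
#' Computes Abar = (I - delta/2 A)^{-1} (I + delta/2 A),
#' Bbar = (I - delta/2 A)^{-1} delta B, Cbar = C, and the length-L
#' convolution kernel Kbar with Kbar[k] = Cbar Abar^(k-1) Bbar.
#'
#' @param params an [ssm_params()] object
#' @param L kernel length (>= 1)
#' @return an object of class `discrete_ssm` with fields `A_bar`, `B_bar`,
#'   `C_bar`, `D`, `L` and `K_bar`
#' @export
discretize <- function(params, L) {
  stopifnot(inherits(params, "ssm_params"))
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L))
    stop("L must be a positive integer")
  L <- as.integer(L)
  d <- params$delta
  N <- params$N
  M <- diag(N) - (d / 2) * params$A
  Minv <- tryCatch(solve(M), error = function(e)
    stop(sprintf("discretize: (I - delta/2 A) is singular for delta = %g", d)))
  A_bar <- Minv %*% (diag(N) + (d / 2) * params$A)
  B_bar <- as.numeric(Minv %*% (d * params$B))
  K_bar <- ssm_kernel(A_bar, B_bar, params$C, L)
  structure(list(A_bar = A_bar, B_bar = B_bar, C_bar = params$C, D = params$D,
                 L = L, K_bar = K_bar, N = N),
            class = "discrete_ssm")
}

#' Materialize the SSM convolution kernel `K[k] = C Abar^(k-1) Bbar`
#'
#' Direct O(N^2 L) iteration of matrix-vector products; adequate at desk
#' scale. (The O(L) Cauchy-kernel algorithm is deliberately out of scope.)
#' @keywords internal
ssm_kernel <- function(A_bar, B_bar, C, L) {
  K <- numeric(L)
  x <- B_bar
  for (k in seq_len(L)) {
    K[k] <- sum(C * x)
    if (k < L) x <- as.numeric(A_bar %*% x)
  }
  K
}

.check_ssm_input <- function(ssm, u) {
  stopifnot(inherits(ssm, "discrete_ssm"))
  if (length(u) != ssm$L)
    stop(sprintf("input length %d does not match kernel length %d", length(u), ssm$L))
  if (!all(is.finite(u))) stop("input sequence must be finite")
  invisible(NULL)
}

#' Apply a discretized SSM by exact state recurrence
#'
#' Steps x_k = Abar x_{k-1} + Bbar u_k, y_k = Cbar x_k (+ D u_k) from a zero
#' initial state. This is the exactness oracle for [ssm_apply_conv()].
#'
#' @param ssm a [discretize()]d system
#' @param u numeric input sequence of length `ssm$L`
#' @return numeric output sequence, same length
#' @export
ssm_apply_recurrent <- function(ssm, u) {
  .check_ssm_input(ssm, u)
  N <- ssm$N
  x <- numeric(N)
  y <- numeric(ssm$L)
  for (k in seq_along(u)) {
    x <- as.numeric(ssm$A_bar %*% x) + ssm$B_bar * u[k]
    y[k] <- sum(ssm$C_bar * x) + ssm$D * u[k]
  }
  y
}

#' Apply a discretized SSM by causal convolution with its kernel
#'
#' y = Kbar * u (one-sided, truncated to length L), computed with an FFT.
#' Agrees with [ssm_apply_recurrent()] to high precision.
#'
#' @inheritParams ssm_apply_recurrent
#' @return numeric output sequence, same length
#' @export
ssm_apply_conv <- function(ssm, u) {
  .check_ssm_input(ssm, u)
  L <- ssm$L
  m <- 2L * L
  y <- Re(stats::fft(stats::fft(c(u, numeric(m - L))) *
                     stats::fft(c(ssm$K_bar, numeric(m - L))), inverse = TRUE))[seq_len(L)] / m
  y + ssm$D * u
}
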