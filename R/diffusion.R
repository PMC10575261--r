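# DDPM machinery: linear noise schedule, forward noising, eps-prediction
# loss, and ancestral reverse sampling with class conditioning.

#' Linear variance schedule for a denoising diffusion process
#'
#' beta is linearly interpolated from `beta_start` to `beta_end` inclusive
#' over `T_steps` steps; alpha_t = 1 - beta_t and
#' alpha_bar_t = prod_{i<=t} alpha_i. Defaults are the reference
#' configuration: 200 steps from 1e-4 to 0.02.
#'
#' @param T_steps number of diffusion steps (>= 1)
#' @param beta_start,beta_end endpoints, 0 < beta_start <= beta_end < 1
#' @return object of class `noise_schedule` with fields `T`, `beta`, `alpha`,
#'   `alpha_bar`
#' @export
make_schedule <- function(T_steps = 200L, beta_start = 1e-4, beta_end = 0.02) {
  if (!is.numeric(T_steps) || length(T_steps) != 1 || T_steps < 1 || T_steps != round(T_steps))
    stop("T_steps must be a positive integer")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("require 0 < beta_start <= beta_end < 1")
  T_steps <- as.integer(T_steps)
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "noise_schedule")
}

.check_t <- function(t, schedule) {
  if (any(t < 1) || any(t > schedule$T) || any(t != round(t)))
    stop(sprintf("diffusion step t must be an integer in [1, %d]", schedule$T))
  invisible(NULL)
}

#' Forward (noising) diffusion at step t
#'
#' x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) eps. The alternative
#' reading without the square root on the noise weight (which does not give
#' unit-variance marginals) is available for audit via `no_root_noise`.
#'
#' @param x0 clean signal (any numeric array)
#' @param t integer step in `[1, schedule$T]`
#' @param eps standard-normal noise, same shape as `x0`
#' @param schedule a [make_schedule()] object
#' @param no_root_noise if TRUE weight the noise by (1 - alpha_bar_t) instead
#'   of its square root
#' @return noised signal, same shape as `x0`
#' @export
forward_diffuse <- function(x0, t, eps, schedule, no_root_noise = FALSE) {
  .check_t(t, schedule)
  if (!identical(dim(x0), dim(eps)) || length(x0) != length(eps))
    stop("x0 and eps must have identical shapes")
  ab <- schedule$alpha_bar[t]
  w <- if (no_root_noise) (1 - ab) else sqrt(1 - ab)
  sqrt(ab) * x0 + w * eps
}

#' eps-prediction training loss on a diffusion batch
#'
#' Mean squared error between the injected noise and the predictor's
#' estimate, averaged over all batch elements. `predictor(xt, t, c)` must
#' return an object shaped like `eps` (a plain array, or an autodiff node
#' when called inside a training step).
#'
#' @param predictor function of (xt, t, c)
#' @param batch list with fields `x0` (list of arrays), `t` (integer vector),
#'   `c` (list of label vectors), `eps` (list of arrays)
#' @param schedule a [make_schedule()] object
#' @return non-negative scalar (numeric, or scalar autodiff node if the
#'   predictor returned nodes)
#' @export
training_loss <- function(predictor, batch, schedule) {
  stopifnot(length(batch$x0) == length(batch$eps),
            length(batch$x0) == length(batch$t))
  losses <- vector("list", length(batch$x0))
  for (i in seq_along(batch$x0)) {
    x0 <- batch$x0[[i]]; eps <- batch$eps[[i]]; t <- batch$t[i]
    if (!identical(dim(x0), dim(eps))) stop("x0/eps shape mismatch in batch")
    xt <- forward_diffuse(x0, t, eps, schedule)
    pred <- predictor(xt, t, batch$c[[i]])
    if (ad_is_node(pred)) {
      if (!identical(dim(pred$val), dim(eps)) && length(pred$val) != length(eps))
        stop("prediction/eps shape mismatch")
      losses[[i]] <- ad_mse(pred, eps)
    } else {
      if (length(pred) != length(eps)) stop("prediction/eps shape mismatch")
      losses[[i]] <- mean((eps - pred)^2)
    }
  }
  if (ad_is_node(losses[[1]])) ad_mean_list(losses) else mean(unlist(losses))
}

#' Derive a child RNG seed from a base seed and a stream index
#'
#' Simple counter scheme modulo a Mersenne prime so every (seed, stream)
#' pair maps to a distinct 31-bit seed, keeping draws reproducible
#' independently of batch layout.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 11) %% 2147483647)
}

#' Ancestral reverse-diffusion sampling
#'
#' Starting from x_T ~ N(0, 1), iterates
#' x_{t-1} = (x_t - (1 - alpha_t)/sqrt(1 - alpha_bar_t) eps_hat) / sqrt(alpha_t)
#'           + sigma_t z
#' down to t = 1, with z ~ N(0,1) for t > 1 and z = 0 at t = 1.
#' sigma_t^2 = beta_t by default ("fixed" variance); the posterior variance
#' beta_tilde_t = (1 - alpha_bar_{t-1})/(1 - alpha_bar_t) beta_t is available
#' via `variance = "posterior"`.
#'
#' All randomness is derived from `seed` with a counter scheme (one stream
#' for x_T, one per step), so results are bit-reproducible.
#'
#' @param predictor function of (xt, t, c) returning the predicted noise
#' @param c label vector passed through to the predictor
#' @param schedule a [make_schedule()] object
#' @param shape integer vector, shape of the generated sample
#' @param seed integer seed
#' @param variance "fixed" (sigma_t^2 = beta_t) or "posterior"
#' @return array of dimension `shape` (vector if length-1 shape)
#' @export
reverse_sample <- function(predictor, c, schedule, shape, seed,
                           variance = c("fixed", "posterior")) {
  variance <- match.arg(variance)
  n <- prod(shape)
  set.seed(derive_seed(seed, 0L))
  x <- array(stats::rnorm(n), dim = shape)
  ab <- schedule$alpha_bar
  for (t in seq(schedule$T, 1L)) {
    eps_hat <- predictor(x, t, c)
    if (ad_is_node(eps_hat)) eps_hat <- eps_hat$val
    eps_hat <- array(eps_hat, dim = shape)
    mu <- (x - (schedule$beta[t] / sqrt(1 - ab[t])) * eps_hat) / sqrt(schedule$alpha[t])
    if (!all(is.finite(mu)))
      stop(sprintf("reverse_sample: non-finite values at step t = %d", t))
    if (t > 1L) {
      s2 <- if (variance == "fixed") schedule$beta[t] else
        (1 - ab[t - 1]) / (1 - ab[t]) * schedule$beta[t]
      set.seed(derive_seed(seed, t))
      x <- mu + sqrt(s2) * array(stats::rnorm(n), dim = shape)
    } else {
      x <- mu
    }
  }
  x
}
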