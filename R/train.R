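# Training loop for the denoiser: Adam on the eps-prediction MSE, with
# resumable RDS checkpoints and a per-step loss log.

#' Train a denoiser model on a dataset
#'
#' Each step draws a batch of records, a uniform diffusion step t per record
#' and fresh standard-normal noise, then takes one Adam step on the mean
#' squared eps-prediction error. Fully deterministic given `seed`.
#'
#' @param model a [dsat_init()] model (updated in place)
#' @param records n x channels x L array or list of channels x L matrices
#' @param labels n x label_dim binary matrix
#' @param schedule a [make_schedule()]
#' @param steps number of optimization steps
#' @param batch_size records per step
#' @param lr Adam learning rate
#' @param seed seed controlling batch, t and noise draws
#' @param checkpoint_path optional RDS path written every
#'   `checkpoint_every` steps and at the end
#' @param checkpoint_every steps between checkpoints
#' @param resume_from optional checkpoint to restore (parameters, optimizer
#'   state and step counter) before training continues
#' @param verbose print a running loss every 100 steps
#' @return list with `model`, `loss` (per-step vector including any resumed
#'   history), and `checkpoint_path`
#' @export
dsat_train <- function(model, records, labels, schedule,
                       steps = 500L, batch_size = 8L, lr = 1e-3, seed = 1L,
                       checkpoint_path = NULL, checkpoint_every = 250L,
                       resume_from = NULL, verbose = FALSE) {
  records <- .as_record_list(records)
  labels <- as.matrix(labels)
  stopifnot(length(records) == nrow(labels),
            ncol(labels) == model$cfg$label_dim)
  opt <- adam_init(model$params, lr = lr)
  loss_hist <- numeric(0)
  step0 <- 0L
  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    ad_params_restore(model$params, ck$params)
    adam_state_restore(opt, ck$optimizer)
    loss_hist <- ck$loss
    step0 <- ck$step
  }
  n <- length(records)
  for (s in seq_len(steps)) {
    gstep <- step0 + s
    set.seed(derive_seed(seed, gstep))
    idx <- sample.int(n, min(batch_size, n))
    t <- sample.int(schedule$T, length(idx), replace = TRUE)
    batch <- list(
      x0 = lapply(idx, function(i) records[[i]]),
      t = t,
      c = lapply(idx, function(i) labels[i, ]),
      eps = lapply(idx, function(i)
        array(stats::rnorm(length(records[[i]])), dim = dim(records[[i]]))))
    ad_reset_tape()
    ad_zero_grads(model$params)
    predictor <- function(xt, tt, cvec)
      dsat_forward_node(model, ad_const(t(xt)), tt, cvec)
    # forward_diffuse works on plain arrays; predictions come back as nodes
    # shaped L x channels, so transpose targets to match
    losses <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      x0 <- batch$x0[[i]]; eps <- batch$eps[[i]]
      xt <- forward_diffuse(x0, batch$t[i], eps, schedule)
      pred <- predictor(xt, batch$t[i], batch$c[[i]])
      losses[[i]] <- ad_mse(pred, t(eps))
    }
    loss <- ad_mean_list(losses)
    ad_backward(loss)
    adam_step(opt)
    loss_hist <- c(loss_hist, as.numeric(loss$val))
    if (verbose && gstep %% 100L == 0L)
      message(sprintf("step %d  loss %.4f", gstep,
                      mean(utils::tail(loss_hist, 100))))
    if (!is.null(checkpoint_path) &&
        (s == steps || gstep %% checkpoint_every == 0L)) {
      save_checkpoint(checkpoint_path, model, opt, schedule, gstep, loss_hist)
    }
  }
  ad_reset_tape()
  list(model = model, loss = loss_hist, checkpoint_path = checkpoint_path)
}

#' Write a resumable training checkpoint
#' @keywords internal
save_checkpoint <- function(path, model, opt, schedule, step, loss) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(version = 1L, cfg = model$cfg, params = ad_params_values(model$params),
               optimizer = adam_state_save(opt),
               schedule = list(T = schedule$T, beta_start = schedule$beta[1],
                               beta_end = schedule$beta[schedule$T]),
               step = step, loss = loss, model_seed = attr(model, "seed")),
          path)
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#' @param path RDS checkpoint path
#' @return list with `model`, `schedule`, `step`, `loss`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- dsat_init(ck$cfg, seed = 1L)
  ad_params_restore(model$params, ck$params)
  list(model = model,
       schedule = make_schedule(ck$schedule$T, ck$schedule$beta_start,
                                ck$schedule$beta_end),
       step = ck$step, loss = ck$loss)
}

#' Generate records from a trained model by ancestral sampling
#'
#' Runs the reverse-diffusion chains of up to `chunk` records concurrently
#' through the batched numeric forward pass. Record i draws its noise from
#' the stream `derive_seed(seed, i)` exactly as [reverse_sample()] would, so
#' the output is bit-identical to sampling records one at a time and is
#' independent of `chunk`.
#'
#' @param model a trained [dsat_init()] model
#' @param labels n x label_dim matrix: one generated record per row
#' @param schedule a [make_schedule()]
#' @param seed base seed; record i uses stream `derive_seed(seed, i)`
#' @param chunk number of chains advanced together
#' @return n x channels x L array
#' @export
dsat_sample <- function(model, labels, schedule, seed = 1L, chunk = 25L) {
  labels <- as.matrix(labels)
  cfg <- model$cfg
  stopifnot(ncol(labels) == cfg$label_dim)
  n <- nrow(labels)
  Cs <- cfg$signal_channels; L <- cfg$L
  out <- array(0, dim = c(n, Cs, L))
  draw <- function(i, stream) {
    set.seed(derive_seed(derive_seed(seed, i), stream))
    t(matrix(stats::rnorm(Cs * L), Cs, L))
  }
  ab <- schedule$alpha_bar
  packed <- .pack_model(model)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    B <- length(idx)
    x <- do.call(rbind, lapply(idx, draw, stream = 0L))
    cmat <- labels[idx, , drop = FALSE]
    if (B > 1L && all(cmat == rep(cmat[1, ], each = B)))
      cmat <- cmat[1, , drop = FALSE]
    for (t in seq(schedule$T, 1L)) {
      eps_hat <- .dsat_forward_cpp(packed, x, t, cmat, B)
      mu <- (x - (schedule$beta[t] / sqrt(1 - ab[t])) * eps_hat) /
        sqrt(schedule$alpha[t])
      if (!all(is.finite(mu)))
        stop(sprintf("dsat_sample: non-finite values at step t = %d", t))
      x <- if (t > 1L) {
        mu + sqrt(schedule$beta[t]) * do.call(rbind, lapply(idx, draw, stream = t))
      } else mu
    }
    for (k in seq_along(idx)) {
      rows <- ((k - 1L) * L + 1L):(k * L)
      out[idx[k], , ] <- t(x[rows, , drop = FALSE])
    }
  }
  out
}
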