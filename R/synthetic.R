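# Class-conditional synthetic ECG fixture generator. Records are
# quasi-periodic trains of Gaussian-bump beats (P/Q/R/S/T surrogates) whose
# rate and amplitudes depend on a binary label vector, mixed linearly into
# leads so that 12-lead records satisfy the Einthoven/Goldberger identities
# when noise-free. Not a physiological simulator: it exists so training,
# sampling, lead logic and evaluation are all testable without any download.

#' Default P/Q/R/S/T bump parameters (beat-fraction units)
#'
#' Centers and widths are fractions of one beat period; amplitudes are in
#' arbitrary millivolt-like units. Morphology is deliberately smooth so the
#' spectral fundamental of a beat train dominates its harmonics, which keeps
#' the dominant-frequency class detector trivial.
#' @return list with numeric vectors `amp`, `center`, `width` named P,Q,R,S,T
#' @export
default_beat_params <- function() {
  list(amp    = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.18, T = 0.45),
       center = c(P = 0.15, Q = 0.245, R = 0.28, S = 0.315, T = 0.55),
       width  = c(P = 0.045, Q = 0.018, R = 0.045, S = 0.020, T = 0.110))
}

#' Single-beat waveform as a sum of Gaussian bumps
#'
#' waveform(tau) = sum_b amp_b exp(-(tau - center_b)^2 / (2 width_b^2)) with
#' tau on a [0, 1) beat-fraction grid of `length` samples.
#'
#' @param params list with `amp`, `center`, `width` vectors of equal length
#' @param length samples per beat
#' @return numeric vector of length `length`
#' @export
beat_template <- function(params = default_beat_params(), length = 64L) {
  stopifnot(length >= 1)
  if (any(params$width <= 0)) stop("beat_template: widths must be positive")
  if (length(params$amp) != length(params$center) ||
      length(params$amp) != length(params$width))
    stop("beat_template: amp/center/width lengths differ")
  tau <- (seq_len(length) - 1) / length
  w <- numeric(length)
  for (b in seq_along(params$amp))
    w <- w + params$amp[b] * exp(-(tau - params$center[b])^2 / (2 * params$width[b]^2))
  w
}

#' Synthetic dataset configuration
#'
#' `class_effects` is a list with one element per label, each a list with
#' `rate_mult` (multiplicative on beat rate, i.e. additive on log-rate so
#' multilabel combinations compose), `r_amp` and `t_amp` (multiplicative on
#' the R and T bump amplitudes). The desk-scale default is 2 leads, 2
#' one-hot classes at 1.25 Hz and 2.5 Hz, L = 128 at 64 Hz.
#'
#' @param n_records number of records
#' @param fs sampling rate (Hz)
#' @param duration_s record duration; `fs * duration_s` must be integral
#' @param n_leads 2 (desk), 8, or 12
#' @param label_dim number of labels C
#' @param base_rate_hz beat rate with all labels off
#' @param class_effects per-label modifiers (see Details)
#' @param prevalence per-label Bernoulli prevalence (ignored when
#'   `one_hot = TRUE`)
#' @param one_hot draw exactly one active label per record, uniformly
#' @param noise_sd additive Gaussian noise level
#' @param seed RNG seed
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_records = 100L, fs = 64, duration_s = 2,
                         n_leads = 2L, label_dim = 2L, base_rate_hz = 1.25,
                         class_effects = NULL, prevalence = NULL,
                         one_hot = TRUE, noise_sd = 0.05, seed = 1L) {
  L <- fs * duration_s
  if (abs(L - round(L)) > 1e-9) stop("fs * duration_s must be integral")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!n_leads %in% c(2L, 8L, 12L)) stop("n_leads must be 2, 8 or 12")
  if (is.null(class_effects)) {
    class_effects <- rep(list(list(rate_mult = 1, r_amp = 1, t_amp = 1)), label_dim)
    if (label_dim >= 2L) class_effects[[2L]] <- list(rate_mult = 2, r_amp = 0.9, t_amp = 1.2)
  }
  if (length(class_effects) != label_dim) stop("one class_effects entry per label required")
  if (is.null(prevalence)) prevalence <- rep(0.5, label_dim)
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence values must lie in [0, 1]")
  structure(list(n_records = as.integer(n_records), fs = fs,
                 duration_s = duration_s, L = as.integer(round(L)),
                 n_leads = as.integer(n_leads), label_dim = as.integer(label_dim),
                 base_rate_hz = base_rate_hz, class_effects = class_effects,
                 prevalence = prevalence, one_hot = isTRUE(one_hot),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# label-dependent beat rate and amplitude modifiers
.label_effects <- function(cfg, label) {
  log_rate <- log(cfg$base_rate_hz)
  r_amp <- 1; t_amp <- 1
  for (j in seq_len(cfg$label_dim)) {
    if (label[j] == 1) {
      e <- cfg$class_effects[[j]]
      log_rate <- log_rate + log(e$rate_mult)
      r_amp <- r_amp * e$r_amp
      t_amp <- t_amp * e$t_amp
    }
  }
  list(rate = exp(log_rate), r_amp = r_amp, t_amp = t_amp)
}

# beat train at a given rate (Hz): phase-sampled template, deterministic
.beat_train <- function(cfg, rate, r_amp, t_amp, phase = 0) {
  bp <- default_beat_params()
  bp$amp["R"] <- bp$amp["R"] * r_amp
  bp$amp["T"] <- bp$amp["T"] * t_amp
  tt <- (seq_len(cfg$L) - 1) / cfg$fs
  tau <- (tt * rate + phase) %% 1
  w <- numeric(cfg$L)
  for (b in seq_along(bp$amp))
    w <- w + bp$amp[b] * exp(-(tau - bp$center[b])^2 / (2 * bp$width[b]^2))
  w - mean(w)
}

# lead mixing coefficients for the cardiac source; chosen so a 12-lead
# record built from (I, aVF) via the identities is internally consistent
.lead_mix <- function(n_leads) {
  if (n_leads == 2L) return(c(1.0, 0.6))
  c(I = 1.0, aVF = 0.6, V1 = -0.4, V2 = -0.2, V3 = 0.35,
    V4 = 0.8, V5 = 0.95, V6 = 0.85)
}

#' Generate a class-conditional synthetic dataset
#'
#' @param cfg a [synth_config()]
#' @param labels optional n x C binary matrix overriding label sampling
#' @return list with `records` (n x leads x L array), `labels` (n x C),
#'   `cfg`, and `lead_names`
#' @export
generate_dataset <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$L < 1 || cfg$n_records < 1) stop("generate_dataset: empty configuration")
  set.seed(cfg$seed)
  n <- cfg$n_records; C <- cfg$label_dim
  if (is.null(labels)) {
    if (cfg$one_hot) {
      k <- sample.int(C, n, replace = TRUE)
      labels <- matrix(0, n, C)
      labels[cbind(seq_len(n), k)] <- 1
    } else {
      labels <- matrix(stats::rbinom(n * C, 1, rep(cfg$prevalence, each = n)), n, C)
    }
  } else {
    labels <- as.matrix(labels)
    stopifnot(nrow(labels) == n, ncol(labels) == C)
  }
  lead_names <- if (cfg$n_leads == 12L) LEADS_12 else
    if (cfg$n_leads == 8L) LEADS_8 else c("I", "aVF")
  records <- array(0, dim = c(n, cfg$n_leads, cfg$L),
                   dimnames = list(NULL, lead_names, NULL))
  mix <- .lead_mix(cfg$n_leads)
  for (i in seq_len(n)) {
    ef <- .label_effects(cfg, labels[i, ])
    phase <- stats::runif(1)
    src <- .beat_train(cfg, ef$rate, ef$r_amp, ef$t_amp, phase)
    if (cfg$n_leads == 12L) {
      I <- mix[["I"]] * src; aVF <- mix[["aVF"]] * src
      lim <- derive_four_leads(I, aVF)
      base <- rbind(I, lim$II, lim$III, lim$aVR, lim$aVL, aVF,
                    t(vapply(paste0("V", 1:6), function(v) mix[[v]] * src,
                             numeric(cfg$L))))
    } else {
      base <- t(vapply(seq_len(cfg$n_leads), function(l) mix[l] * src,
                       numeric(cfg$L)))
    }
    if (cfg$noise_sd > 0)
      base <- base + matrix(stats::rnorm(length(base), sd = cfg$noise_sd),
                            nrow(base))
    records[i, , ] <- base
  }
  list(records = records, labels = labels, cfg = cfg, lead_names = lead_names)
}

#' Dominant-frequency estimate of a record
#'
#' Picks the peak of the mean power spectrum (across leads) inside `band`
#' Hz. Deliberately trivial: it is the fixture's class detector.
#'
#' @param record channels x L matrix
#' @param fs sampling rate
#' @param band numeric length-2 search band in Hz
#' @return dominant frequency in Hz
#' @export
dominant_frequency <- function(record, fs, band = c(0.8, 3.2)) {
  record <- as.matrix(record)
  L <- ncol(record)
  freqs <- (0:(L - 1)) * fs / L
  spec <- rep(0, L)
  for (l in seq_len(nrow(record))) {
    v <- record[l, ] - mean(record[l, ])
    spec <- spec + Mod(stats::fft(v))^2
  }
  keep <- which(freqs >= band[1] & freqs <= band[2])
  freqs[keep[which.max(spec[keep])]]
}

#' Classify records by nearest class beat rate
#'
#' @param records list or n x channels x L array
#' @param cfg the [synth_config()] that defines the class rates
#' @return integer vector of one-hot class indices
#' @export
classify_by_rate <- function(records, cfg) {
  records <- .as_record_list(records)
  rates <- vapply(seq_len(cfg$label_dim), function(j) {
    lab <- rep(0, cfg$label_dim); lab[j] <- 1
    .label_effects(cfg, lab)$rate
  }, numeric(1))
  vapply(records, function(r) {
    f <- dominant_frequency(r, cfg$fs)
    which.min(abs(rates - f))
  }, integer(1))
}

#' Group-wise train/test/validation split by patient identifier
#'
#' Assigns each distinct `person_id` to exactly one subset so no person
#' spans two subsets.
#'
#' @param person_id vector of identifiers, one per record
#' @param fractions length-3 non-negative weights for train/test/validation
#' @param seed shuffling seed
#' @return factor of subset assignments (`train`, `test`, `validation`)
#' @export
split_by_patient <- function(person_id, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0), sum(fractions) > 0)
  ids <- unique(person_id)
  set.seed(seed)
  ids <- sample(ids)
  cum <- cumsum(fractions / sum(fractions))
  nid <- length(ids)
  cuts <- c(0, round(cum[1:2] * nid), nid)
  grp <- rep(c("train", "test", "validation"),
             times = pmax(diff(cuts), 0))[seq_len(nid)]
  names(grp) <- as.character(ids)
  factor(grp[as.character(person_id)], levels = c("train", "test", "validation"))
}

# --- minimal WFDB (format 16) I/O -------------------------------------------
# Single-segment records, one interleaved .dat per record, 16-bit
# little-endian samples, physical = (digital - baseline) / gain. Covers the
# subset this package writes; not a general WFDB implementation.

#' Write a multi-lead record as a WFDB format-16 record
#' @param sig a [multilead_signal()]
#' @param dir output directory
#' @param name record name (basename of the .hea/.dat pair)
#' @param gain ADC gain (units per physical unit)
#' @return invisibly, the header path
#' @export
write_wfdb <- function(sig, dir, name, gain = 1000) {
  stopifnot(inherits(sig, "multilead_signal"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsig <- nrow(sig$values); nsamp <- ncol(sig$values)
  dig <- round(sig$values * gain)
  if (any(abs(dig) > 32767)) stop("write_wfdb: signal exceeds 16-bit range at this gain")
  hea <- c(sprintf("%s %d %g %d", name, nsig, sig$fs, nsamp),
           sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 %s",
                   name, gain, as.integer(dig[, 1]), sig$lead_names))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(dig)), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Read a WFDB format-16 record written by [write_wfdb()]
#' @param dir record directory
#' @param name record name
#' @return a [multilead_signal()]
#' @export
read_wfdb <- function(dir, name) {
  hea_path <- file.path(dir, paste0(name, ".hea"))
  if (!file.exists(hea_path)) stop(sprintf("read_wfdb: missing header for record '%s'", name))
  hea <- readLines(hea_path)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  leads <- character(nsig); gains <- numeric(nsig)
  for (s in seq_len(nsig)) {
    f <- strsplit(trimws(hea[s + 1]), "\\s+")[[1]]
    if (f[2] != "16") stop("read_wfdb: only format 16 is supported")
    gains[s] <- as.numeric(sub("/.*$", "", f[3]))
    leads[s] <- f[length(f)]
  }
  dat_path <- file.path(dir, paste0(name, ".dat"))
  if (!file.exists(dat_path)) stop(sprintf("read_wfdb: missing signal file for record '%s'", name))
  raw <- readBin(dat_path, integer(), n = nsig * nsamp, size = 2L,
                 endian = "little", signed = TRUE)
  dig <- matrix(raw, nrow = nsig)  # column-major interleaving as written
  multilead_signal(dig / gains, fs, leads)
}

#' Load a directory of WFDB records with a CSV label manifest
#'
#' The manifest `labels.csv` must have columns `record_id`, optionally
#' `person_id`, and one 0/1 column per label.
#'
#' @param path directory containing `<id>.hea` / `<id>.dat` pairs and
#'   `labels.csv`
#' @param ids record identifiers to load (may be empty)
#' @return list with `records` (list of [multilead_signal()]), `labels`
#'   (matrix) and `person_id` (or NULL)
#' @export
load_wfdb_records <- function(path, ids) {
  if (length(ids) == 0L)
    return(list(records = list(), labels = matrix(0, 0, 0), person_id = NULL))
  man_path <- file.path(path, "labels.csv")
  if (!file.exists(man_path)) stop("load_wfdb_records: labels.csv not found")
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  rownames(man) <- as.character(man$record_id)
  missing <- setdiff(as.character(ids), rownames(man))
  if (length(missing))
    stop(sprintf("load_wfdb_records: no manifest entry for record(s): %s",
                 paste(missing, collapse = ", ")))
  label_cols <- setdiff(names(man), c("record_id", "person_id"))
  records <- lapply(as.character(ids), function(id) read_wfdb(path, id))
  labels <- as.matrix(man[as.character(ids), label_cols, drop = FALSE])
  list(records = records, labels = labels,
       person_id = if ("person_id" %in% names(man)) man[as.character(ids), "person_id"] else NULL)
}
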