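# 12-lead reconstruction from the 8 generated leads (I, aVF, V1-V6) via
# Einthoven's law and Goldberger's equations:
#   III = II - I,  aVL = (I - III)/2,  aVF = (II + III)/2,  -aVR = (I + II)/2
# The generator produces I and aVF, so the system is first inverted to
# II = aVF + I/2 (the unique solution consistent with all identities).

#' Ordered lead names
#' @keywords internal
LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")
LEADS_8 <- c("I", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")

#' Multi-lead signal container
#'
#' @param values channels x timesteps numeric matrix
#' @param fs sampling rate in Hz
#' @param lead_names character vector, one per channel
#' @return object of class `multilead_signal`
#' @export
multilead_signal <- function(values, fs, lead_names) {
  values <- as.matrix(values)
  if (length(lead_names) != nrow(values))
    stop("length(lead_names) must equal the number of channels")
  if (!all(is.finite(values))) stop("signal values must be finite")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(values = values, fs = fs, lead_names = as.character(lead_names)),
            class = "multilead_signal")
}

#' @export
print.multilead_signal <- function(x, ...) {
  cat(sprintf("multilead_signal: %d leads x %d samples @ %g Hz [%s]\n",
              nrow(x$values), ncol(x$values), x$fs,
              paste(x$lead_names, collapse = ", ")))
  invisible(x)
}

#' Derive leads II, III, aVL, aVR from leads I and aVF
#'
#' Inverts the Goldberger relation to II = aVF + I/2, then applies
#' Einthoven's law and the remaining Goldberger equations. All four limb
#' identities hold on the output by construction.
#'
#' @param leadI,leadAVF numeric vectors of equal length
#' @return list with components `II`, `III`, `aVL`, `aVR`
#' @export
derive_four_leads <- function(leadI, leadAVF) {
  if (length(leadI) != length(leadAVF))
    stop("leadI and leadAVF must have equal length")
  if (!all(is.finite(leadI)) || !all(is.finite(leadAVF)))
    stop("lead inputs must be finite")
  II <- leadAVF + leadI / 2
  III <- II - leadI
  list(II = II, III = III,
       aVL = (leadI - III) / 2,
       aVR = -(leadI + II) / 2)
}

#' Assemble a full 12-lead record from the 8 generated leads
#'
#' @param eight a [multilead_signal()] with leads `I, aVF, V1..V6` in that
#'   order
#' @return a [multilead_signal()] with the 12 standard leads in the order
#'   `I, II, III, aVR, aVL, aVF, V1..V6`; precordials are passed through
#'   unchanged
#' @export
assemble_12_lead <- function(eight) {
  stopifnot(inherits(eight, "multilead_signal"))
  if (nrow(eight$values) != 8L || !identical(eight$lead_names, LEADS_8))
    stop(sprintf("expected 8 leads named [%s], got [%s]",
                 paste(LEADS_8, collapse = ", "),
                 paste(eight$lead_names, collapse = ", ")))
  v <- eight$values
  lim <- derive_four_leads(v["I" == eight$lead_names, ], v["aVF" == eight$lead_names, ])
  out <- rbind(v[1, ], lim$II, lim$III, lim$aVR, lim$aVL, v[2, ],
               v[3:8, ])
  rownames(out) <- NULL
  multilead_signal(out, eight$fs, LEADS_12)
}

#' Reduce a 12-lead record to the 8 generated leads
#'
#' @param twelve a [multilead_signal()] with the standard 12 leads
#' @return a [multilead_signal()] with leads `I, aVF, V1..V6`
#' @export
reduce_to_8_lead <- function(twelve) {
  stopifnot(inherits(twelve, "multilead_signal"))
  if (!identical(twelve$lead_names, LEADS_12))
    stop("expected the standard 12-lead order")
  idx <- match(LEADS_8, twelve$lead_names)
  multilead_signal(twelve$values[idx, , drop = FALSE], twelve$fs, LEADS_8)
}

#' Check the Einthoven/Goldberger identities on a 12-lead record
#'
#' @param twelve a 12-lead [multilead_signal()]
#' @return maximum absolute residual over the four identities
#' @export
lead_identity_residual <- function(twelve) {
  stopifnot(inherits(twelve, "multilead_signal"),
            identical(twelve$lead_names, LEADS_12))
  v <- twelve$values
  g <- function(nm) v[match(nm, twelve$lead_names), ]
  max(abs(g("III") - (g("II") - g("I"))),
      abs(g("aVL") - (g("I") - g("III")) / 2),
      abs(g("aVF") - (g("II") + g("III")) / 2),
      abs(-g("aVR") - (g("I") + g("II")) / 2))
}
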