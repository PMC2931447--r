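#' Sequence parameters for a PSIR / IR-TFE / Look-Locker kernel
#'
#' Bundles the timing and RF parameters that define one repeating kernel of
#' an inversion-prepared spoiled gradient-echo acquisition. A PSIR kernel
#' spans two cardiac RR intervals and contains two identical readout trains;
#' an IR-TFE or Look-Locker kernel spans a single RR interval.
#'
#' @param rr_ms RR interval duration in ms (one cardiac cycle).
#' @param t_inv_ms Inversion delay in ms, from the inversion pulse to the
#'   start of the first readout train.
#' @param tr_ms Repetition time of the readout train in ms.
#' @param flip_deg Readout flip angle alpha in degrees, in (0, 90).
#' @param tfe_factor Number of readout pulses per acquisition block
#'   (turbo-field-echo factor n); the acquisition duration is
#'   \code{t_acq_ms = tfe_factor * tr_ms}.
#' @param inversion_deg Inversion pulse angle in degrees, in (90, 180].
#'   180 is a perfect inversion.
#' @param kernel_rr Number of RR intervals per kernel: 2 for PSIR,
#'   1 for IR-TFE / Look-Locker.
#'
#' @return An object of class \code{"seq_params"}: a list with the fields
#'   above plus the derived \code{t_acq_ms}.
#'
#' @details The readout train must fit inside its RR interval:
#'   \code{t_inv_ms + t_acq_ms <= rr_ms}, and for a two-RR kernel the second
#'   train (starting at \code{rr_ms + t_inv_ms}) must end before the next
#'   inversion. \code{t_inv_ms = 0} with \code{t_acq_ms = rr_ms} is the
#'   degenerate continuous-acquisition (Look-Locker) configuration and is
#'   allowed.
#'
#' @examples
#' seq_params(rr_ms = 1000, t_inv_ms = 300, tr_ms = 9.4, flip_deg = 18,
#'            tfe_factor = 23)
#' @export
seq_params <- function(rr_ms = 1000, t_inv_ms = 300, tr_ms = 9.4,
                       flip_deg = 18, tfe_factor = 23,
                       inversion_deg = 180, kernel_rr = 2) {
  stopifnot(length(rr_ms) == 1, length(t_inv_ms) == 1, length(tr_ms) == 1,
            length(flip_deg) == 1, length(tfe_factor) == 1,
            length(inversion_deg) == 1, length(kernel_rr) == 1)
  if (!is.finite(rr_ms) || rr_ms <= 0)
    stop("rr_ms must be a positive duration (ms)")
  if (!is.finite(t_inv_ms) || t_inv_ms < 0)
    stop("t_inv_ms must be a non-negative duration (ms)")
  if (!is.finite(tr_ms) || tr_ms <= 0)
    stop("tr_ms must be a positive duration (ms)")
  if (!is.finite(flip_deg) || flip_deg <= 0 || flip_deg >= 90)
    stop("flip_deg must lie in (0, 90) degrees")
  if (!is.finite(tfe_factor) || tfe_factor < 1 ||
      tfe_factor != round(tfe_factor))
    stop("tfe_factor must be a positive integer")
  if (!is.finite(inversion_deg) || inversion_deg <= 90 || inversion_deg > 180)
    stop("inversion_deg must lie in (90, 180] degrees")
  if (!kernel_rr %in% c(1, 2))
    stop("kernel_rr must be 1 (IR-TFE/LL) or 2 (PSIR)")
  t_acq_ms <- tfe_factor * tr_ms
  if (t_inv_ms + t_acq_ms > rr_ms + 1e-9)
    stop("readout train must end within the RR interval: ",
         "t_inv_ms + tfe_factor*tr_ms = ", t_inv_ms + t_acq_ms,
         " > rr_ms = ", rr_ms)
  structure(list(rr_ms = rr_ms, t_inv_ms = t_inv_ms, tr_ms = tr_ms,
                 flip_deg = flip_deg, tfe_factor = tfe_factor,
                 inversion_deg = inversion_deg, kernel_rr = kernel_rr,
                 t_acq_ms = t_acq_ms),
            class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  kind <- if (x$kernel_rr == 2) "PSIR (2 RR)" else "IR-TFE/LL (1 RR)"
  cat(sprintf("<seq_params> %s\n", kind))
  cat(sprintf("  RR %.1f ms | T_inv %.1f ms | TR %.2f ms | flip %.1f deg\n",
              x$rr_ms, x$t_inv_ms, x$tr_ms, x$flip_deg))
  cat(sprintf("  TFE factor %d (T_acq %.1f ms) | inversion %.1f deg\n",
              x$tfe_factor, x$t_acq_ms, x$inversion_deg))
  invisible(x)
}

#' Tissue relaxation state
#'
#' Ground-truth or fitted (T1, M0) pair. Both fields may be vectors of
#' matching length, so a tissue_state can describe a whole set of voxels.
#'
#' @param t1_ms Longitudinal relaxation time(s) in ms, > 0.
#' @param m0 Equilibrium magnetization(s) in arbitrary units, > 0
#'   (normalized to 1 in simulations).
#' @return An object of class \code{"tissue_state"}.
#' @examples
#' tissue_state(400)                 # T1 = 400 ms, M0 = 1
#' tissue_state(c(228, 298, 411))    # three tissues
#' @export
tissue_state <- function(t1_ms, m0 = 1) {
  if (length(m0) == 1) m0 <- rep(m0, length(t1_ms))
  if (length(m0) != length(t1_ms))
    stop("t1_ms and m0 must have matching length")
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0))
    stop("t1_ms must be positive and finite")
  if (any(!is.finite(m0)) || any(m0 <= 0))
    stop("m0 must be positive and finite")
  structure(list(t1_ms = as.numeric(t1_ms), m0 = as.numeric(m0)),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  n <- length(x$t1_ms)
  if (n == 1) {
    cat(sprintf("<tissue_state> T1 = %.1f ms, M0 = %.4g\n", x$t1_ms, x$m0))
  } else {
    cat(sprintf("<tissue_state> %d tissues, T1 in [%.1f, %.1f] ms\n",
                n, min(x$t1_ms), max(x$t1_ms)))
  }
  invisible(x)
}

.as_tissue <- function(x) {
  if (inherits(x, "tissue_state")) x else tissue_state(x)
}

#' Fit options for the iterative two-point T1 fit
#'
#' @param tolerance_ms Convergence criterion: iteration stops when the change
#'   in T1 between successive iterates falls below this (ms).
#' @param max_iterations Iteration cap.
#' @param t1_bounds_ms Length-2 vector of admissible T1 (ms); estimates
#'   outside are clamped and flagged.
#' @return A list of class \code{"fit_options"}.
#' @export
fit_options <- function(tolerance_ms = 0.01, max_iterations = 100,
                        t1_bounds_ms = c(1, 5000)) {
  stopifnot(tolerance_ms > 0, max_iterations >= 1,
            length(t1_bounds_ms) == 2, t1_bounds_ms[1] > 0,
            t1_bounds_ms[2] > t1_bounds_ms[1])
  structure(list(tolerance_ms = tolerance_ms,
                 max_iterations = as.integer(max_iterations),
                 t1_bounds_ms = as.numeric(t1_bounds_ms)),
            class = "fit_options")
}
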