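#' Exponential approach of longitudinal magnetization toward a target
#'
#' Shared primitive for every free-relaxation or saturated-readout segment of
#' the kernel: \code{m(t) = m_target + (m_start - m_target) * exp(-t / tau)}.
#'
#' @param m_start Magnetization at the start of the segment.
#' @param m_target Asymptote the magnetization relaxes toward (M0 for free
#'   relaxation, M0* during a readout train).
#' @param duration_ms Segment duration in ms, >= 0.
#' @param tau_ms Time constant in ms (T1 or T1*), > 0.
#' @return Magnetization at the end of the segment. Vectorized in all
#'   arguments.
#' @export
relax_toward <- function(m_start, m_target, duration_ms, tau_ms) {
  if (any(tau_ms <= 0)) stop("tau_ms must be > 0")
  if (any(duration_ms < 0)) stop("duration_ms must be >= 0")
  m_target + (m_start - m_target) * exp(-duration_ms / tau_ms)
}

#' Apparent relaxation during a spoiled readout train
#'
#' During a train of flip-angle-alpha pulses repeated every TR with perfect
#' spoiling, the longitudinal magnetization sampled just before each pulse
#' follows a mono-exponential with a shortened apparent time constant T1* and
#' a saturated asymptote M0*:
#' \deqn{1/T1^* = 1/T1 - \ln(\cos\alpha)/TR}
#' \deqn{M0^* = M0 (1 - E) / (1 - E \cos\alpha), \quad E = e^{-TR/T1}.}
#'
#' The rate relation is exact: \eqn{\cos\alpha \cdot e^{-TR/T1}} is the
#' per-TR decay factor of the discrete pulse train and its logarithm is
#' \eqn{-TR/T1^*}. The asymptote is the exact fixed point of the discrete
#' train, so the exponential envelope through the pre-pulse samples matches a
#' pulse-by-pulse simulation to machine precision (see
#' \code{\link{pulse_by_pulse_trajectory}}). The familiar continuous-limit
#' approximation \eqn{M0^* \approx M0\, T1^*/T1} agrees with it to first
#' order in \eqn{TR/T1} and is available via \code{form = "continuous"}.
#'
#' @param tissue A \code{\link{tissue_state}} (T1 may be a vector).
#' @param seq A \code{\link{seq_params}}.
#' @param form \code{"discrete"} (exact fixed point, default) or
#'   \code{"continuous"} (M0* = M0 T1*/T1).
#' @return A list of class \code{"apparent_relaxation"} with vectors
#'   \code{t1_star_ms} and \code{m0_star}.
#' @examples
#' ar <- apparent_relaxation(tissue_state(400), seq_params(tr_ms = 10,
#'   flip_deg = 15, tfe_factor = 19, t_inv_ms = 300))
#' ar$t1_star_ms  # ~167.6 ms
#' @export
apparent_relaxation <- function(tissue, seq,
                                form = c("discrete", "continuous")) {
  tissue <- .as_tissue(tissue)
  form <- match.arg(form)
  stopifnot(inherits(seq, "seq_params"))
  ca <- cos(seq$flip_deg * pi / 180)
  t1 <- tissue$t1_ms
  t1_star <- 1 / (1 / t1 - log(ca) / seq$tr_ms)
  m0_star <- if (form == "discrete") {
    e <- exp(-seq$tr_ms / t1)
    tissue$m0 * (1 - e) / (1 - ca * e)
  } else {
    tissue$m0 * t1_star / t1
  }
  structure(list(t1_star_ms = t1_star, m0_star = m0_star),
            class = "apparent_relaxation")
}

# Segment durations of the two-RR PSIR kernel, given possibly jittered
# RR intervals rr1 (containing both readouts' start) and rr2.
.kernel_durations <- function(seq, rr1 = seq$rr_ms, rr2 = seq$rr_ms) {
  d <- list(inv_to_b = seq$t_inv_ms,
            b_to_c   = seq$t_acq_ms,
            c_to_d   = rr1 - seq$t_acq_ms,
            d_to_e   = seq$t_acq_ms,
            e_to_f   = rr2 - seq$t_inv_ms - seq$t_acq_ms)
  if (any(unlist(d) < -1e-9))
    stop("kernel timing invalid: readout trains do not fit in the RR intervals")
  lapply(d, function(x) pmax(x, 0))
}

#' Propagate magnetization through one two-RR PSIR kernel
#'
#' Chains the five closed-form segments of the kernel starting from a given
#' post-inversion magnetization \code{m_a}: free T1 relaxation toward M0
#' during the inversion delay (A to B), saturated relaxation toward M0* with
#' T1* during the first readout train (B to C), free relaxation until the
#' second readout one RR later (C to D, duration RR - T_acq), the second
#' readout train (D to E), and free relaxation until just before the next
#' inversion at 2 RR (E to F).
#'
#' @param tissue A \code{\link{tissue_state}}.
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 2}.
#' @param m_a Magnetization just after the inversion pulse (vectorized,
#'   recycled against \code{tissue}).
#' @return A list of class \code{"magnetization_kernel"} with fields
#'   \code{m_a} ... \code{m_f}.
#' @seealso \code{\link{steady_state_kernel}} for the self-consistent steady
#'   state, \code{\link{pulse_by_pulse_trajectory}} for the discrete oracle.
#' @export
propagate_kernel <- function(tissue, seq, m_a) {
  tissue <- .as_tissue(tissue)
  stopifnot(inherits(seq, "seq_params"))
  if (seq$kernel_rr != 2)
    stop("propagate_kernel requires a two-RR (PSIR) kernel")
  ar <- apparent_relaxation(tissue, seq)
  d <- .kernel_durations(seq)
  t1 <- tissue$t1_ms; m0 <- tissue$m0
  m_b <- relax_toward(m_a, m0, d$inv_to_b, t1)
  m_c <- relax_toward(m_b, ar$m0_star, d$b_to_c, ar$t1_star_ms)
  m_d <- relax_toward(m_c, m0, d$c_to_d, t1)
  m_e <- relax_toward(m_d, ar$m0_star, d$d_to_e, ar$t1_star_ms)
  m_f <- relax_toward(m_e, m0, d$e_to_f, t1)
  structure(list(m_a = m_a, m_b = m_b, m_c = m_c,
                 m_d = m_d, m_e = m_e, m_f = m_f),
            class = "magnetization_kernel")
}

#' Steady-state magnetization checkpoints of the PSIR kernel
#'
#' In a multi-shot acquisition the kernel repeats every 2 RR and the
#' magnetization settles into a steady state in which the value just after
#' each inversion reproduces itself: \code{m_a = cos(inv) * m_f} (with a
#' perfect 180-degree inversion, \code{m_a = -m_f}), and \code{|m_a| < m0}.
#'
#' Each kernel segment is an affine map of \code{m_a}, so
#' \code{m_f = a * m_a + b} with \code{0 < a < 1} and the fixed point is
#' available in closed form: \code{m_a = b cos(inv) / (1 - a cos(inv))}.
#' The iterative route (repeated \code{\link{propagate_kernel}}) is retained
#' for testing.
#'
#' @inheritParams propagate_kernel
#' @param method \code{"closed"} (affine fixed point, default) or
#'   \code{"iterate"}.
#' @param tol,max_iter Convergence controls for \code{method = "iterate"}.
#' @return A \code{"magnetization_kernel"} at steady state.
#' @examples
#' ss <- steady_state_kernel(tissue_state(400),
#'   seq_params(rr_ms = 1000, t_inv_ms = 300, tr_ms = 10,
#'              flip_deg = 15, tfe_factor = 19))
#' c(ss$m_b, ss$m_d)   # the two measured checkpoints
#' @export
steady_state_kernel <- function(tissue, seq, method = c("closed", "iterate"),
                                tol = 1e-12, max_iter = 10000) {
  tissue <- .as_tissue(tissue)
  method <- match.arg(method)
  ci <- cos(seq$inversion_deg * pi / 180)
  if (method == "closed") {
    # m_f is affine in m_a: evaluate at m_a = 0 and m_a = 1 to get (a, b).
    k0 <- propagate_kernel(tissue, seq, m_a = rep(0, length(tissue$t1_ms)))
    k1 <- propagate_kernel(tissue, seq, m_a = rep(1, length(tissue$t1_ms)))
    a <- k1$m_f - k0$m_f
    b <- k0$m_f
    m_a <- b * ci / (1 - a * ci)
    propagate_kernel(tissue, seq, m_a)
  } else {
    m_a <- -tissue$m0
    for (i in seq_len(max_iter)) {
      k <- propagate_kernel(tissue, seq, m_a)
      m_a_new <- ci * k$m_f
      if (max(abs(m_a_new - m_a)) < tol) {
        return(propagate_kernel(tissue, seq, m_a_new))
      }
      m_a <- m_a_new
    }
    warning("steady_state_kernel: iteration did not reach tol")
    propagate_kernel(tissue, seq, m_a)
  }
}

#' Steady-state Look-Locker signal
#'
#' For a continuous readout with the inversion repeated every RR interval
#' (one-RR kernel, acquisition filling the whole interval), the steady-state
#' longitudinal magnetization a time \code{t} after the inversion is
#' \deqn{M(t) = M0^* \left(1 - \frac{2}{1+e} e^{-t/T1^*}\right), \quad
#'       e = e^{-RR/T1^*}}
#' for a perfect inversion; the general inversion angle replaces the factor
#' 2/(1+e) accordingly. The signal crosses zero at
#' \eqn{t_{null} = T1^* \ln(2/(1+e))}, which in general differs from the
#' zero-crossing time of a PSIR acquisition of the same tissue
#' (\code{\link{psir_zero_crossing}}).
#'
#' @param t_ms Time(s) after the inversion pulse, in \code{[0, rr_ms)}.
#' @param tissue A \code{\link{tissue_state}} (scalar T1).
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 1}; only
#'   \code{rr_ms}, \code{tr_ms} and \code{flip_deg} matter (the readout is
#'   continuous).
#' @return Signed magnetization at each \code{t_ms}.
#' @export
look_locker_signal <- function(t_ms, tissue, seq) {
  tissue <- .as_tissue(tissue)
  stopifnot(inherits(seq, "seq_params"))
  if (seq$kernel_rr != 1)
    stop("look_locker_signal requires a one-RR kernel (kernel_rr = 1)")
  if (any(t_ms < 0) || any(t_ms >= seq$rr_ms))
    stop("t_ms must lie in [0, rr_ms)")
  ar <- apparent_relaxation(tissue, seq)
  ci <- cos(seq$inversion_deg * pi / 180)
  e <- exp(-seq$rr_ms / ar$t1_star_ms)
  # fixed point of m_a = ci * relax(m_a, m0*, RR, T1*)
  m_a <- ci * ar$m0_star * (1 - e) / (1 - ci * e)
  relax_toward(m_a, ar$m0_star, t_ms, ar$t1_star_ms)
}

#' Zero-crossing time of the steady-state Look-Locker signal
#'
#' @inheritParams look_locker_signal
#' @return Time after inversion (ms) at which \code{\link{look_locker_signal}}
#'   crosses zero.
#' @export
ll_zero_crossing <- function(tissue, seq) {
  tissue <- .as_tissue(tissue)
  ar <- apparent_relaxation(tissue, seq)
  ci <- cos(seq$inversion_deg * pi / 180)
  e <- exp(-seq$rr_ms / ar$t1_star_ms)
  m_a <- ci * ar$m0_star * (1 - e) / (1 - ci * e)
  if (m_a >= 0) stop("signal does not start negative; no zero crossing")
  ar$t1_star_ms * log((ar$m0_star - m_a) / ar$m0_star)
}
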