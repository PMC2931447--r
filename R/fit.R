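#' A measured PSIR sample pair
#'
#' The signed image intensities at the start of the two readout trains of a
#' PSIR kernel, on an arbitrary common scale. A physical steady-state voxel
#' has \code{m_d > m_b} (more recovery at RR + T_inv than at T_inv) and
#' \code{m_d > 0}; violations mark the voxel invalid rather than raising.
#'
#' @param m_b,m_d Signed intensities (vectors of equal length).
#' @return A list of class \code{"psir_sample"}.
#' @export
psir_sample <- function(m_b, m_d) {
  stopifnot(length(m_b) == length(m_d))
  structure(list(m_b = as.numeric(m_b), m_d = as.numeric(m_d)),
            class = "psir_sample")
}

.as_sample <- function(x) {
  if (inherits(x, "psir_sample")) return(x)
  if (inherits(x, "magnetization_kernel")) return(psir_sample(x$m_b, x$m_d))
  if (is.list(x) && all(c("m_b", "m_d") %in% names(x)))
    return(psir_sample(x$m_b, x$m_d))
  stop("cannot interpret input as a PSIR sample (need m_b and m_d)")
}

.fit_result <- function(t1, m0, iter, converged, residual, valid) {
  structure(list(t1_ms = t1, m0 = m0, n_iterations = iter,
                 converged = converged, residual = residual, valid = valid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  n <- length(x$t1_ms)
  cat(sprintf("<fit_result> %d voxel(s), %d converged, %d valid\n",
              n, sum(x$converged), sum(x$valid)))
  if (n <= 6) {
    cat(sprintf("  T1 = %s ms\n",
                paste(sprintf("%.2f", x$t1_ms), collapse = ", ")))
  }
  invisible(x)
}

#' Iterative two-point PSIR fit of (T1, M0)
#'
#' Recovers T1 and M0 from the measured pair (M_B, M_D) of a steady-state
#' PSIR kernel. The six magnetization checkpoints are coupled, so T1 has no
#' explicit solution; the estimate is refined iteratively:
#' \enumerate{
#'   \item Initialize \code{m0 = -m_a = m_d}.
#'   \item Coarse T1 from the inversion-delay segment:
#'     \code{t1 = t_inv / log((m0 - m_a) / (m0 - m_b))}.
#'   \item M_C from M_B through the readout-train segment using the apparent
#'     relaxation (T1*, M0*).
#'   \item New M0 from the free-relaxation segment between the readouts:
#'     \code{m0 = (m_d - m_c * E) / (1 - E)},
#'     \code{E = exp(-(rr - t_acq) / t1)}.
#'   \item M_E and M_F through the remaining segments; new \code{m_a = -m_f}.
#'   \item Repeat from step 2 until |Delta T1| < tolerance.
#' }
#' The fit assumes a perfect (180 degree) inversion and is invariant to the
#' global intensity scale. Vectorized over voxels; voxels that hit an invalid
#' logarithm, violate \code{m_d > m_b}, \code{m_d > 0}, or leave the T1
#' bounds are flagged, never raised.
#'
#' @param sample A \code{\link{psir_sample}} (or anything with \code{m_b},
#'   \code{m_d}, e.g. a \code{\link{steady_state_kernel}} result).
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 2}. The fit
#'   always assumes a perfect inversion regardless of \code{inversion_deg}.
#' @param opts A \code{\link{fit_options}}.
#' @return A \code{"fit_result"} with vectors \code{t1_ms}, \code{m0},
#'   \code{n_iterations}, \code{converged}, \code{residual} (last |Delta T1|
#'   in ms) and \code{valid}.
#' @examples
#' sq <- seq_params(rr_ms = 1000, t_inv_ms = 300, tr_ms = 10,
#'                  flip_deg = 15, tfe_factor = 19)
#' ss <- steady_state_kernel(tissue_state(411), sq)
#' fit_two_point(ss, sq)$t1_ms   # recovers 411 ms
#' @export
fit_two_point <- function(sample, seq, opts = fit_options()) {
  sample <- .as_sample(sample)
  stopifnot(inherits(seq, "seq_params"), inherits(opts, "fit_options"))
  if (seq$kernel_rr != 2)
    stop("fit_two_point requires a two-RR (PSIR) kernel")
  b <- sample$m_b; d <- sample$m_d
  n <- length(b)
  ca <- cos(seq$flip_deg * pi / 180)
  d_seg <- .kernel_durations(seq)
  lo <- opts$t1_bounds_ms[1]; hi <- opts$t1_bounds_ms[2]

  valid <- is.finite(b) & is.finite(d) & (d > b) & (d > 0)
  t1 <- rep(NA_real_, n); m0 <- rep(NA_real_, n)
  iter <- integer(n); converged <- logical(n)
  residual <- rep(NA_real_, n)

  act <- which(valid)
  if (length(act)) {
    m0a <- d[act]; maa <- -d[act]; ba <- b[act]; da <- d[act]
    t1a <- rep(NA_real_, length(act)); prev <- rep(Inf, length(act))
    oka <- rep(TRUE, length(act)); conva <- rep(FALSE, length(act))
    live <- rep(TRUE, length(act)); ita <- integer(length(act))
    resa <- rep(NA_real_, length(act))
    for (k in seq_len(opts$max_iterations)) {
      i <- which(live)
      if (!length(i)) break
      ita[i] <- k
      ratio <- (m0a[i] - maa[i]) / (m0a[i] - ba[i])
      bad <- !is.finite(ratio) | ratio <= 0
      # ratio in (0, 1] means the current m0 estimate is too small to
      # explain the recovery (true T1 beyond the upper bound): clamp to the
      # bound and keep iterating -- the m0 update usually rescues it.
      t1i <- ifelse(ratio > 1, seq$t_inv_ms / log(ratio), hi)
      clamped <- !bad & (t1i < lo | t1i > hi | ratio <= 1)
      t1i <- pmin(pmax(t1i, lo), hi)
      t1i[bad] <- hi   # placeholder; voxel is already marked invalid
      # apparent relaxation at the current T1 estimate
      t1s <- 1 / (1 / t1i - log(ca) / seq$tr_ms)
      etr <- exp(-seq$tr_ms / t1i)
      sat <- (1 - etr) / (1 - ca * etr)   # m0* per unit m0
      mc <- sat * m0a[i] + (ba[i] - sat * m0a[i]) * exp(-d_seg$b_to_c / t1s)
      E <- exp(-d_seg$c_to_d / t1i)
      m0n <- (da[i] - mc * E) / (1 - E)
      bad <- bad | !is.finite(m0n) | m0n <= 0
      me <- sat * m0n + (da[i] - sat * m0n) * exp(-d_seg$d_to_e / t1s)
      mf <- m0n + (me - m0n) * exp(-d_seg$e_to_f / t1i)
      res <- abs(t1i - prev[i])
      t1a[i] <- t1i; m0a[i] <- m0n; maa[i] <- -mf
      resa[i] <- res; prev[i] <- t1i
      oka[i][bad] <- FALSE
      settled <- !bad & res < opts$tolerance_ms
      # voxels that settle at a clamped bound stop but stay flagged
      # (converged = FALSE); they remain valid per the clamp-and-flag policy
      conva[i][settled & !clamped] <- TRUE
      live[i] <- !bad & !settled
    }
    t1[act] <- t1a; m0[act] <- m0a
    iter[act] <- ita; residual[act] <- resa
    converged[act] <- conva & oka
    valid[act] <- oka
  }
  t1[!valid] <- NA_real_; m0[!valid] <- NA_real_
  .fit_result(t1, m0, iter, converged, residual, valid)
}

#' Naive two-point inversion-recovery fit (no saturation model)
#'
#' Fits the same (M_B, M_D) pair while neglecting the readout saturation and
#' the multi-shot steady state: full recovery is assumed
#' (\code{m_a = -m0}, flip angle treated as 0), so
#' \code{m_b = m0 (1 - 2 exp(-t_inv/t1))} and
#' \code{m_d = m0 (1 - 2 exp(-(rr + t_inv)/t1))}. T1 is found by 1-D root
#' finding on the intensity ratio. This reproduces the systematic
#' underestimation of T1 that appears whenever the RR interval is not much
#' longer (4-5x) than T1.
#'
#' @inheritParams fit_two_point
#' @return A \code{"fit_result"}.
#' @export
fit_naive <- function(sample, seq, opts = fit_options()) {
  sample <- .as_sample(sample)
  stopifnot(inherits(seq, "seq_params"))
  if (seq$kernel_rr != 2)
    stop("fit_naive requires a two-RR (PSIR) kernel")
  b <- sample$m_b; d <- sample$m_d
  n <- length(b)
  lo <- opts$t1_bounds_ms[1]; hi <- opts$t1_bounds_ms[2]
  tb <- seq$t_inv_ms; td <- seq$rr_ms + seq$t_inv_ms
  t1 <- rep(NA_real_, n); m0 <- rep(NA_real_, n)
  valid <- is.finite(b) & is.finite(d) & (d > b) & (d > 0)
  g <- function(t1v, bi, di) {
    di * (1 - 2 * exp(-tb / t1v)) - bi * (1 - 2 * exp(-td / t1v))
  }
  for (i in which(valid)) {
    glo <- g(lo, b[i], d[i]); ghi <- g(hi, b[i], d[i])
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
      valid[i] <- FALSE
      next
    }
    r <- stats::uniroot(g, c(lo, hi), bi = b[i], di = d[i], tol = 1e-6)
    t1[i] <- r$root
    m0[i] <- d[i] / (1 - 2 * exp(-td / r$root))
    if (!is.finite(m0[i]) || m0[i] <= 0) valid[i] <- FALSE
  }
  t1[!valid] <- NA_real_; m0[!valid] <- NA_real_
  .fit_result(t1, m0, ifelse(valid, 1L, 0L), valid,
              rep(0, n), valid)
}

#' A sampled Look-Locker inversion-recovery series
#'
#' @param sample_times_ms Times after the inversion pulse (ms), strictly
#'   increasing, all below the RR interval.
#' @param signals Signed intensities at those times (arbitrary scale).
#' @return A list of class \code{"ll_series"}.
#' @export
ll_series <- function(sample_times_ms, signals) {
  stopifnot(length(sample_times_ms) == length(signals),
            length(signals) >= 3)
  if (any(diff(sample_times_ms) <= 0))
    stop("sample_times_ms must be strictly increasing")
  structure(list(sample_times_ms = as.numeric(sample_times_ms),
                 signals = as.numeric(signals)),
            class = "ll_series")
}

#' Fit a Look-Locker series for T1
#'
#' Least-squares fit of the steady-state Look-Locker signal shape (see
#' \code{\link{look_locker_signal}}) to a sampled inversion-recovery series.
#' The model has exactly two free parameters, the amplitude M0* and the
#' apparent time constant T1*; the intercept is coupled through
#' \code{e = exp(-rr/t1_star)}, not fit freely. Because the model is linear
#' in M0*, the amplitude is profiled out and the residual sum of squares is
#' minimized over T1* alone (1-D, bounded). The true T1 is then recovered by
#' undoing the readout saturation:
#' \code{1/t1 = 1/t1_star + log(cos(flip)) / tr}.
#'
#' @param series A \code{\link{ll_series}}.
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 1}; its
#'   \code{rr_ms} is the inversion repetition interval and \code{tr_ms},
#'   \code{flip_deg} describe the continuous readout.
#' @param t1_star_bounds_ms Search interval for T1* (ms).
#' @return A \code{"fit_result"} (scalar) whose \code{m0} is the fitted
#'   equilibrium magnetization in the series' intensity units.
#' @export
fit_look_locker <- function(series, seq, t1_star_bounds_ms = c(5, 5000)) {
  stopifnot(inherits(series, "ll_series"), inherits(seq, "seq_params"))
  if (seq$kernel_rr != 1)
    stop("fit_look_locker requires a one-RR kernel")
  t <- series$sample_times_ms; y <- series$signals
  shape <- function(t1s) {
    e <- exp(-seq$rr_ms / t1s)
    1 - (2 / (1 + e)) * exp(-t / t1s)
  }
  rss <- function(t1s) {
    s <- shape(t1s)
    amp <- sum(y * s) / sum(s * s)
    sum((y - amp * s)^2)
  }
  opt <- stats::optimize(rss, t1_star_bounds_ms, tol = 1e-6)
  t1s <- opt$minimum
  # refine: optimize() can stall on flat regions; polish with a local search
  for (w in c(0.1, 0.01)) {
    iv <- c(max(t1_star_bounds_ms[1], t1s * (1 - w)),
            min(t1_star_bounds_ms[2], t1s * (1 + w)))
    t1s <- stats::optimize(rss, iv, tol = 1e-9)$minimum
  }
  s <- shape(t1s)
  amp <- sum(y * s) / sum(s * s)   # = M0* in intensity units
  ca <- cos(seq$flip_deg * pi / 180)
  inv_t1 <- 1 / t1s + log(ca) / seq$tr_ms
  ok <- is.finite(inv_t1) && inv_t1 > 0 && amp > 0
  t1 <- if (ok) 1 / inv_t1 else NA_real_
  # invert m0* = m0 (1 - e) / (1 - cos(a) e) at the recovered T1
  m0 <- if (ok) {
    e1 <- exp(-seq$tr_ms / t1)
    amp * (1 - ca * e1) / (1 - e1)
  } else NA_real_
  hit_bound <- min(abs(t1s - t1_star_bounds_ms)) < 1e-3
  .fit_result(t1, m0, 1L, ok && !hit_bound, 0, ok)
}

#' Voxelwise parameter map from a PSIR volume pair
#'
#' Applies \code{\link{fit_two_point}} to every masked voxel of two
#' co-registered signed volumes (first and second readout of the PSIR
#' kernel) and assembles T1, R1 and M0 maps.
#'
#' @param volume_b,volume_d Numeric arrays of identical dimensions (2-D
#'   treated as single-slice 3-D).
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 2}.
#' @param mask Optional logical/0-1 array of the same shape; default all
#'   voxels.
#' @param opts A \code{\link{fit_options}}.
#' @param spacing_mm Voxel spacing carried through to the output (length 3).
#' @return A \code{"parameter_map"}: list of arrays \code{t1}, \code{r1}
#'   (s^-1, = 1000/t1), \code{m0}, logical \code{mask} (valid fitted voxels),
#'   integer \code{convergence} (1 converged, 0 not, NA outside input mask),
#'   and \code{spacing_mm}. Invalid voxels hold \code{NA}.
#' @export
fit_map <- function(volume_b, volume_d, seq, mask = NULL,
                    opts = fit_options(), spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(volume_b), dim(volume_d)) ||
      length(volume_b) != length(volume_d))
    stop("volume_b and volume_d must have identical dimensions")
  dm <- dim(volume_b)
  if (is.null(dm)) dm <- length(volume_b)
  if (length(dm) == 2) dm <- c(dm, 1L)
  if (length(dm) != 3) stop("volumes must be 2-D or 3-D")
  if (is.null(mask)) {
    mask <- rep(TRUE, prod(dm))
  } else {
    if (length(mask) != prod(dm)) stop("mask shape mismatch")
    mask <- as.logical(mask)
  }
  if (!any(mask)) warning("empty mask: returning an empty map")
  nab <- rep(NA_real_, prod(dm))
  t1 <- nab; m0 <- nab; conv <- rep(NA_integer_, prod(dm))
  idx <- which(mask)
  if (length(idx)) {
    fr <- fit_two_point(psir_sample(as.numeric(volume_b)[idx],
                                    as.numeric(volume_d)[idx]), seq, opts)
    t1[idx] <- fr$t1_ms
    m0[idx] <- fr$m0
    conv[idx] <- as.integer(fr$converged)
  }
  ok <- !is.na(t1)
  structure(list(t1 = array(t1, dm),
                 r1 = array(1000 / t1, dm),
                 m0 = array(m0, dm),
                 mask = array(ok, dm),
                 convergence = array(conv, dm),
                 spacing_mm = spacing_mm),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s voxels, %d valid, %d converged\n",
              paste(dim(x$t1), collapse = "x"),
              sum(x$mask), sum(x$convergence == 1, na.rm = TRUE)))
  if (any(x$mask))
    cat(sprintf("  T1 range %.1f - %.1f ms\n",
                min(x$t1[x$mask]), max(x$t1[x$mask])))
  invisible(x)
}
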