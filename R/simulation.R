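#' @keywords internal
#' Rebuild a seq_params with some fields replaced.
.seq_with <- function(seq, ...) {
  f <- utils::modifyList(unclass(seq)[c("rr_ms", "t_inv_ms", "tr_ms",
                                        "flip_deg", "tfe_factor",
                                        "inversion_deg", "kernel_rr")],
                         list(...))
  do.call(seq_params, f)
}

# Vectorized discrete pulse train across replicates. t1, m0 scalars;
# rr_mat: n_replicates x n_intervals matrix of (possibly jittered) RR
# durations. Never uses the aggregate (T1*, M0*) closed form: every readout
# pulse is applied individually as m -> m*cos(alpha) followed by free T1
# relaxation over TR. Returns checkpoints of the LAST kernel.
.pulse_train_last <- function(t1, m0, seq, rr_mat) {
  ca <- cos(seq$flip_deg * pi / 180)
  ci <- cos(seq$inversion_deg * pi / 180)
  n_int <- ncol(rr_mat)
  krr <- seq$kernel_rr
  n_kern <- n_int %/% krr
  m <- rep(m0, nrow(rr_mat))
  e_tr <- exp(-seq$tr_ms / t1)
  g_tr <- m0 * (1 - e_tr)
  out <- NULL
  for (k in seq_len(n_kern)) {
    rr1 <- rr_mat[, krr * (k - 1) + 1]
    m <- m * ci
    m_a <- m
    m <- relax_toward(m, m0, seq$t_inv_ms, t1)
    m_b <- m
    for (p in seq_len(seq$tfe_factor)) m <- (m * ca) * e_tr + g_tr
    m_c <- m
    if (krr == 2) {
      rr2 <- rr_mat[, krr * k]
      m <- relax_toward(m, m0, rr1 - seq$t_acq_ms, t1)
      m_d <- m
      for (p in seq_len(seq$tfe_factor)) m <- (m * ca) * e_tr + g_tr
      m_e <- m
      m <- relax_toward(m, m0, rr2 - seq$t_inv_ms - seq$t_acq_ms, t1)
      m_f <- m
      out <- list(m_a = m_a, m_b = m_b, m_c = m_c,
                  m_d = m_d, m_e = m_e, m_f = m_f)
    } else {
      m <- relax_toward(m, m0, rr1 - seq$t_inv_ms - seq$t_acq_ms, t1)
      m_f <- m
      out <- list(m_a = m_a, m_b = m_b, m_c = m_c, m_f = m_f)
    }
  }
  out
}

#' Discrete pulse-by-pulse magnetization trajectory
#'
#' Brute-force oracle for the closed-form kernel model: simulates the
#' longitudinal magnetization event by event -- inversion (cosine scaling of
#' Mz), free T1 relaxation between events, and every one of the n readout
#' pulses individually (\code{m -> m cos(alpha)} then free relaxation over
#' one TR). The aggregate apparent-relaxation closed form is never used, so
#' agreement with \code{\link{steady_state_kernel}} is a genuine
#' cross-check of the model algebra. Checkpoints are sampled at the segment
#' boundaries (acquisition start = just before the first pulse, acquisition
#' end = after the last pulse's TR).
#'
#' @param tissue A \code{\link{tissue_state}} (scalar).
#' @param seq A \code{\link{seq_params}}.
#' @param rr_sequence Vector of RR-interval durations (ms); each kernel
#'   consumes \code{seq$kernel_rr} of them. Magnetization starts fully
#'   relaxed at +M0 before the first inversion.
#' @return A data.frame with one row per completed kernel and the checkpoint
#'   magnetizations as columns (\code{m_a ... m_f} for a PSIR kernel;
#'   \code{m_a, m_b, m_c, m_f} for a one-RR kernel).
#' @export
pulse_by_pulse_trajectory <- function(tissue, seq, rr_sequence) {
  tissue <- .as_tissue(tissue)
  stopifnot(length(tissue$t1_ms) == 1)
  krr <- seq$kernel_rr
  n_kern <- length(rr_sequence) %/% krr
  if (n_kern < 1) stop("rr_sequence shorter than one kernel")
  rows <- vector("list", n_kern)
  # run kernel-by-kernel, carrying the magnetization forward
  ca <- cos(seq$flip_deg * pi / 180)
  ci <- cos(seq$inversion_deg * pi / 180)
  t1 <- tissue$t1_ms; m0 <- tissue$m0
  e_tr <- exp(-seq$tr_ms / t1)
  g_tr <- m0 * (1 - e_tr)
  m <- m0
  for (k in seq_len(n_kern)) {
    rr1 <- rr_sequence[krr * (k - 1) + 1]
    if (rr1 < seq$t_inv_ms + seq$t_acq_ms - 1e-9)
      stop("RR interval ", k, " too short for the readout train")
    m <- m * ci; m_a <- m
    m <- relax_toward(m, m0, seq$t_inv_ms, t1); m_b <- m
    for (p in seq_len(seq$tfe_factor)) m <- (m * ca) * e_tr + g_tr
    m_c <- m
    if (krr == 2) {
      rr2 <- rr_sequence[krr * k]
      if (rr2 < seq$t_inv_ms + seq$t_acq_ms - 1e-9)
        stop("RR interval ", krr * k, " too short for the readout train")
      m <- relax_toward(m, m0, rr1 - seq$t_acq_ms, t1); m_d <- m
      for (p in seq_len(seq$tfe_factor)) m <- (m * ca) * e_tr + g_tr
      m_e <- m
      m <- relax_toward(m, m0, rr2 - seq$t_inv_ms - seq$t_acq_ms, t1)
      m_f <- m
      rows[[k]] <- data.frame(kernel = k, m_a = m_a, m_b = m_b, m_c = m_c,
                              m_d = m_d, m_e = m_e, m_f = m_f)
    } else {
      m <- relax_toward(m, m0, rr1 - seq$t_inv_ms - seq$t_acq_ms, t1)
      m_f <- m
      rows[[k]] <- data.frame(kernel = k, m_a = m_a, m_b = m_b, m_c = m_c,
                              m_f = m_f)
    }
  }
  do.call(rbind, rows)
}

#' Digital phantom specification
#'
#' Describes an in-silico phantom: a voxel grid with geometric regions of
#' known (T1, M0) on an empty background. The default regions are six discs
#' matching the agarose/gadolinium phantom set with T1 = 228, 298, 411, 539,
#' 638 and 754 ms. Overlapping regions follow a last-wins rule.
#'
#' @param shape Grid dimensions (length 2 or 3).
#' @param regions List of regions; each a list with \code{type}
#'   ("disc" or "rect"), geometry (\code{center}+\code{radius} in voxels for
#'   a disc, \code{xlim}+\code{ylim} for a rect; applied to every slice),
#'   \code{t1_ms} and optional \code{m0} (default 1).
#' @param noise_sigma Gaussian noise standard deviation added independently
#'   to both signed volumes, in units of M0.
#' @param seed Integer seed for the noise; NULL leaves the RNG state alone.
#' @return A list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(72, 48, 1), regions = NULL,
                         noise_sigma = 0.005, seed = NULL) {
  if (length(shape) == 2) shape <- c(shape, 1L)
  stopifnot(length(shape) == 3, all(shape >= 1), noise_sigma >= 0)
  if (is.null(regions)) {
    t1s <- c(228, 298, 411, 539, 638, 754)
    centers <- expand.grid(x = c(12, 36, 60), y = c(12, 36))
    regions <- lapply(seq_along(t1s), function(i) {
      list(type = "disc", center = c(centers$x[i], centers$y[i]),
           radius = 8, t1_ms = t1s[i], m0 = 1)
    })
  }
  for (r in regions) {
    stopifnot(r$type %in% c("disc", "rect"), r$t1_ms > 0)
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

# Rasterize the region list into label / t1 / m0 arrays (last wins).
.phantom_truth <- function(spec) {
  dm <- spec$shape
  t1 <- array(NA_real_, dm); m0 <- array(NA_real_, dm)
  lab <- array(0L, dm)
  xs <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2])
  ys <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2])
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    inside <- if (r$type == "disc") {
      (xs - r$center[1])^2 + (ys - r$center[2])^2 <= r$radius^2
    } else {
      xs >= r$xlim[1] & xs <= r$xlim[2] & ys >= r$ylim[1] & ys <= r$ylim[2]
    }
    m0i <- if (is.null(r$m0)) 1 else r$m0
    for (z in seq_len(dm[3])) {
      sl <- which(inside)
      off <- (z - 1) * dm[1] * dm[2]
      t1[off + sl] <- r$t1_ms
      m0[off + sl] <- m0i
      lab[off + sl] <- i
    }
  }
  list(t1 = t1, m0 = m0, label = lab)
}

#' Generate a PSIR volume pair from a digital phantom
#'
#' For every tissue voxel the steady-state (M_B, M_D) pair is computed from
#' the closed-form kernel model; independent Gaussian noise is then added to
#' both signed volumes (phase-corrected real-channel reconstruction, so the
#' noise is additive Gaussian, not Rician). Background voxels carry pure
#' noise. Reproducible under a fixed seed.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param seq A \code{\link{seq_params}} with \code{kernel_rr = 2}.
#' @return A list with \code{volume_b}, \code{volume_d} (numeric arrays),
#'   \code{truth} (a \code{"parameter_map"} holding the ground-truth T1/R1/M0
#'   with the tissue mask) and \code{label} (integer region-label array).
#' @export
generate_phantom_volumes <- function(spec, seq) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(seq, "seq_params"))
  tr <- .phantom_truth(spec)
  dm <- spec$shape
  vb <- array(0, dm); vd <- array(0, dm)
  idx <- which(!is.na(tr$t1))
  if (length(idx)) {
    ss <- steady_state_kernel(tissue_state(tr$t1[idx], tr$m0[idx]), seq)
    vb[idx] <- ss$m_b
    vd[idx] <- ss$m_d
  }
  if (spec$noise_sigma > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    vb <- vb + array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
    vd <- vd + array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
  }
  truth <- structure(list(t1 = tr$t1, r1 = 1000 / tr$t1, m0 = tr$m0,
                          mask = !is.na(tr$t1),
                          convergence = array(ifelse(is.na(tr$t1), NA_integer_,
                                                     1L), dm),
                          spacing_mm = c(1, 1, 1)),
                     class = "parameter_map")
  list(volume_b = vb, volume_d = vd, truth = truth, label = tr$label)
}

#' Arrhythmia Monte-Carlo configuration
#'
#' @param jitter_fraction Half-width of the uniform relative RR variation
#'   (default 0.05, i.e. +/- 5 percent per interval).
#' @param n_replicates Replicates per (T1, heart-rate) cell.
#' @param n_kernels_burnin Kernels simulated before the sampled kernel, to
#'   reach the (jittered) steady state.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @return A list of class \code{"arrhythmia_config"}.
#' @export
arrhythmia_config <- function(jitter_fraction = 0.05, n_replicates = 1000,
                              n_kernels_burnin = 20, seed = NULL) {
  stopifnot(jitter_fraction >= 0, jitter_fraction < 0.5,
            n_replicates >= 1, n_kernels_burnin >= 1)
  structure(list(jitter_fraction = jitter_fraction,
                 n_replicates = as.integer(n_replicates),
                 n_kernels_burnin = as.integer(n_kernels_burnin),
                 seed = seed),
            class = "arrhythmia_config")
}

#' Monte-Carlo estimate of the T1 error caused by cardiac arrhythmia
#'
#' For each (true T1, nominal heart rate) cell: the PSIR kernel train is
#' simulated pulse by pulse with every RR interval independently jittered
#' uniformly within +/- \code{jitter_fraction}; after burn-in the (M_B, M_D)
#' pair of one kernel is sampled and fitted assuming the NOMINAL RR. The
#' spread of the fitted T1 over replicates measures the arrhythmia-induced
#' error.
#'
#' @param t1_list True T1 values (ms).
#' @param hr_list Nominal heart rates (bpm).
#' @param cfg An \code{\link{arrhythmia_config}}.
#' @param seq A \code{\link{seq_params}} (kernel_rr = 2); its \code{rr_ms} is
#'   replaced by the nominal RR of each heart rate.
#' @param fitter \code{"two_point"} (the saturation-corrected fit) or
#'   \code{"naive"} (pure inversion recovery, for the comparison of the two).
#' @return A data.frame with one row per cell: \code{t1_true_ms},
#'   \code{hr_bpm}, \code{n_fitted}, \code{n_invalid}, \code{mean_t1_ms},
#'   \code{sd_t1_ms}, \code{pct_sd} (= 100 sd/true, the reported error) and
#'   \code{pct_bias} (= 100 |mean - true|/true).
#' @export
arrhythmia_monte_carlo <- function(t1_list, hr_list,
                                   cfg = arrhythmia_config(),
                                   seq = seq_params(),
                                   fitter = c("two_point", "naive")) {
  fitter <- match.arg(fitter)
  stopifnot(inherits(cfg, "arrhythmia_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_int <- (cfg$n_kernels_burnin + 1) * 2
  rows <- list()
  for (t1 in t1_list) for (hr in hr_list) {
    rr_nom <- 60000 / hr
    sq <- .seq_with(seq, rr_ms = rr_nom, kernel_rr = 2)
    jit <- matrix(stats::runif(cfg$n_replicates * n_int,
                               -cfg$jitter_fraction, cfg$jitter_fraction),
                  cfg$n_replicates, n_int)
    rr_mat <- rr_nom * (1 + jit)
    ck <- .pulse_train_last(t1, 1, sq, rr_mat)
    smp <- psir_sample(ck$m_b, ck$m_d)
    fr <- if (fitter == "two_point") fit_two_point(smp, sq)
          else fit_naive(smp, sq)
    keep <- fr$valid & (fitter == "naive" | fr$converged)
    t1f <- fr$t1_ms[keep]
    rows[[length(rows) + 1]] <- data.frame(
      t1_true_ms = t1, hr_bpm = hr,
      n_fitted = length(t1f),
      n_invalid = cfg$n_replicates - length(t1f),
      mean_t1_ms = mean(t1f),
      sd_t1_ms = stats::sd(t1f),
      pct_sd = 100 * stats::sd(t1f) / t1,
      pct_bias = 100 * abs(mean(t1f) - t1) / t1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bias from fitting imperfect-inversion data with the perfect-180 model
#'
#' Noiseless steady-state (M_B, M_D) pairs are generated with a reduced
#' inversion angle and fitted with \code{\link{fit_two_point}}, which assumes
#' a perfect 180-degree inversion. An incomplete inversion leaves less
#' negated magnetization, which the perfect-inversion model can only explain
#' with a longer T1 -- an overestimation, about 2-3 percent for a 10 percent
#' angle reduction (162 degrees) over T1 in 200-800 ms.
#'
#' @param t1_grid True T1 values (ms).
#' @param seq A \code{\link{seq_params}} (kernel_rr = 2).
#' @param actual_inversion_deg The true inversion angle in (90, 180].
#' @return data.frame with \code{t1_true_ms}, \code{t1_fitted_ms},
#'   \code{pct_bias} (signed, positive = overestimation).
#' @export
inversion_imperfection_sweep <- function(t1_grid, seq = seq_params(),
                                         actual_inversion_deg = 162) {
  stopifnot(actual_inversion_deg > 90, actual_inversion_deg <= 180)
  sq_gen <- .seq_with(seq, inversion_deg = actual_inversion_deg,
                      kernel_rr = 2)
  ss <- steady_state_kernel(tissue_state(t1_grid), sq_gen)
  fr <- fit_two_point(psir_sample(ss$m_b, ss$m_d),
                      .seq_with(seq, inversion_deg = 180, kernel_rr = 2))
  data.frame(t1_true_ms = t1_grid,
             t1_fitted_ms = fr$t1_ms,
             pct_bias = 100 * (fr$t1_ms - t1_grid) / t1_grid)
}

#' Noiseless robustness sweeps over flip angle or inversion delay
#'
#' Forward-simulates the steady-state sample and refits it across a grid of
#' acquisition settings, reproducing in silico the flatness of the fitted T1
#' against the applied flip angle and inversion delay.
#'
#' @param t1_grid True T1 values (ms).
#' @param flip_grid Flip angles (deg) to sweep, or NULL.
#' @param tinv_grid Inversion delays (ms) to sweep, or NULL. Exactly one of
#'   \code{flip_grid}/\code{tinv_grid} must be given unless both are empty.
#' @param seq Base \code{\link{seq_params}}.
#' @return data.frame with \code{t1_true_ms}, the swept setting
#'   (\code{flip_deg} or \code{t_inv_ms}), \code{t1_fitted_ms} and
#'   \code{pct_error}. Empty grids give an empty table.
#' @export
parameter_sweeps <- function(t1_grid, flip_grid = NULL, tinv_grid = NULL,
                             seq = seq_params()) {
  if (!is.null(flip_grid) && !is.null(tinv_grid))
    stop("sweep one parameter at a time")
  swept <- if (!is.null(flip_grid)) "flip_deg" else "t_inv_ms"
  grid <- if (!is.null(flip_grid)) flip_grid else tinv_grid
  if (length(t1_grid) == 0 || length(grid) == 0) {
    out <- data.frame(t1_true_ms = numeric(0), swept = numeric(0),
                      t1_fitted_ms = numeric(0), pct_error = numeric(0))
    names(out)[2] <- swept
    return(out)
  }
  rows <- list()
  for (g in grid) {
    sq <- if (swept == "flip_deg") .seq_with(seq, flip_deg = g)
          else .seq_with(seq, t_inv_ms = g)
    ss <- steady_state_kernel(tissue_state(t1_grid), sq)
    fr <- fit_two_point(psir_sample(ss$m_b, ss$m_d), sq)
    rows[[length(rows) + 1]] <- data.frame(
      t1_true_ms = t1_grid, swept = g,
      t1_fitted_ms = fr$t1_ms,
      pct_error = 100 * (fr$t1_ms - t1_grid) / t1_grid)
  }
  out <- do.call(rbind, rows)
  names(out)[2] <- swept
  rownames(out) <- NULL
  out
}
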