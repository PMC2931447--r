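test_that("seq_params validates timing and RF parameters", {
  expect_s3_class(fig_seq(), "seq_params")
  expect_equal(fig_seq()$t_acq_ms, 190)
  expect_error(seq_params(rr_ms = -1), "positive")
  expect_error(seq_params(flip_deg = 95), "flip_deg")
  expect_error(seq_params(inversion_deg = 80), "inversion_deg")
  # readout train must fit in the RR interval
  expect_error(seq_params(rr_ms = 500, t_inv_ms = 300, tr_ms = 10,
                          tfe_factor = 25), "within the RR")
  # the degenerate continuous-acquisition configuration is allowed
  expect_s3_class(seq_params(rr_ms = 500, t_inv_ms = 0, tr_ms = 25,
                             tfe_factor = 20, kernel_rr = 2), "seq_params")
  expect_error(tissue_state(-5), "positive")
})

test_that("relax_toward is the exponential-approach primitive", {
  expect_equal(relax_toward(0.3, 1, 0, 400), 0.3)       # zero duration
  expect_equal(relax_toward(0.3, 1, 1e9, 400), 1)       # long-time limit
  expect_equal(relax_toward(-1, 1, 400, 400), 1 - 2 * exp(-1),
               tolerance = 1e-12)                        # hand arithmetic
  expect_error(relax_toward(0, 1, 10, -1), "tau_ms")
  expect_error(relax_toward(0, 1, -1, 10), "duration")
})

test_that("apparent relaxation matches the closed form and the pulse train", {
  sq <- fig_seq()
  ar <- apparent_relaxation(tissue_state(400), sq)
  # 1/T1* = 1/T1 - ln(cos a)/TR: 167.6 ms for T1 400, TR 10, flip 15
  expect_equal(ar$t1_star_ms, 167.6, tolerance = 5e-4)
  # the decay rate is exactly the log of the discrete per-TR factor
  expect_equal(exp(-sq$tr_ms / ar$t1_star_ms),
               cos(15 * pi / 180) * exp(-10 / 400), tolerance = 1e-12)
  # exact discrete asymptote; continuous Eq-1 form agrees to ~2 percent
  e <- exp(-10 / 400)
  expect_equal(ar$m0_star, (1 - e) / (1 - cos(15 * pi / 180) * e),
               tolerance = 1e-12)
  arc <- apparent_relaxation(tissue_state(400), sq, form = "continuous")
  expect_equal(arc$m0_star, 0.419, tolerance = 1e-3)
  expect_equal(ar$m0_star / arc$m0_star, 1, tolerance = 0.02)
  # in-vivo protocol: T1 300 ms -> T1* ~ 115 ms
  ar2 <- apparent_relaxation(tissue_state(300), protocol_seq())
  expect_equal(ar2$t1_star_ms, 115, tolerance = 5e-3)
  # m0* cross-check against the discrete oracle: drive the pulse train to
  # its saturated plateau with a very long acquisition
  sq_long <- seq_params(rr_ms = 20000, t_inv_ms = 1, tr_ms = 10,
                        flip_deg = 15, tfe_factor = 1500)
  tr <- pulse_by_pulse_trajectory(tissue_state(400), sq_long,
                                  rep(20000, 10))
  expect_equal(tr$m_c[5], ar$m0_star, tolerance = 1e-10)
})

test_that("saturation is monotone in flip angle and vanishes at alpha -> 0", {
  flips <- seq(1, 89, by = 4)
  t1s <- vapply(flips, function(a)
    apparent_relaxation(tissue_state(400),
                        fig_seq(flip_deg = a))$t1_star_ms, 0)
  m0s <- vapply(flips, function(a)
    apparent_relaxation(tissue_state(400),
                        fig_seq(flip_deg = a))$m0_star, 0)
  expect_true(all(diff(t1s) < 0))
  expect_true(all(diff(m0s) < 0))
  expect_true(all(t1s < 400 & t1s > 0))
  expect_true(all(m0s < 1 & m0s > 0))
  ar0 <- apparent_relaxation(tissue_state(400), fig_seq(flip_deg = 1e-6))
  expect_equal(ar0$t1_star_ms, 400, tolerance = 1e-6)
  expect_equal(ar0$m0_star, 1, tolerance = 1e-6)
})

test_that("propagate_kernel chains the five segments correctly", {
  sq <- fig_seq()
  # near-zero flip, huge RR: pure inversion recovery, full recovery at 2RR
  sq0 <- seq_params(rr_ms = 1e5, t_inv_ms = 300, tr_ms = 10, flip_deg = 1e-6,
                    tfe_factor = 19)
  k <- propagate_kernel(tissue_state(400), sq0, m_a = -1)
  expect_equal(k$m_f, 1, tolerance = 1e-9)
  expect_equal(k$m_b, 1 - 2 * exp(-300 / 400), tolerance = 1e-9)
  # instant-recovery limit
  kf <- propagate_kernel(tissue_state(0.01), sq, m_a = -1)
  expect_equal(kf$m_b, 1); expect_equal(kf$m_d, 1)
  # segments move monotonically toward their targets
  ss <- steady_state_kernel(tissue_state(400), sq)
  expect_true(ss$m_f > ss$m_e && ss$m_e < ss$m_d)  # m_e pulled down by M0*
  expect_true(ss$m_b > ss$m_a)
  expect_error(propagate_kernel(tissue_state(400), fig_seq(kernel_rr = 1),
                                -1), "two-RR")
})

test_that("steady state: fixed point, closed form == iteration, |M_A| < M0", {
  for (t1 in c(150, 400, 900)) for (hr in c(60, 90)) {
    sq <- fig_seq(rr_ms = 60000 / hr)
    ss <- steady_state_kernel(tissue_state(t1), sq)
    # fixed-point property m_a = -m_f
    expect_equal(ss$m_a, -ss$m_f, tolerance = 1e-10)
    # multi-shot saturation
    expect_lt(abs(ss$m_a), 1)
    # the two routes agree
    it <- steady_state_kernel(tissue_state(t1), sq, method = "iterate")
    expect_equal(ss$m_a, it$m_a, tolerance = 1e-9)
  }
  # single-shot limit: full recovery between kernels, M_A = -M0
  ss1 <- steady_state_kernel(tissue_state(400), fig_seq(rr_ms = 1e6))
  expect_equal(ss1$m_a, -1, tolerance = 1e-9)
})

test_that("steady-state checkpoints scale linearly in M0", {
  sq <- protocol_seq()
  s1 <- steady_state_kernel(tissue_state(350, 1), sq)
  s3 <- steady_state_kernel(tissue_state(350, 3.7), sq)
  for (f in c("m_a", "m_b", "m_c", "m_d", "m_e", "m_f"))
    expect_equal(s3[[f]], 3.7 * s1[[f]], tolerance = 1e-12)
})

test_that("closed-form steady state matches the pulse-by-pulse oracle", {
  for (t1 in c(200, 400, 800)) for (al in c(5, 15, 25)) for (hr in c(60, 90)) {
    sq <- seq_params(rr_ms = 60000 / hr, t_inv_ms = 300, tr_ms = 10,
                     flip_deg = al, tfe_factor = 19)
    ss <- steady_state_kernel(tissue_state(t1), sq)
    or <- oracle_steady(t1, sq)
    for (f in c("m_a", "m_b", "m_c", "m_d", "m_e", "m_f"))
      expect_lt(abs(ss[[f]] - or[[f]]), 1e-4)
  }
})

test_that("Look-Locker closed form and its reduction from the kernel", {
  sq1 <- seq_params(rr_ms = 1000, t_inv_ms = 0, tr_ms = 25, flip_deg = 15,
                    tfe_factor = 40, kernel_rr = 1)
  ar <- apparent_relaxation(tissue_state(500), sq1)
  e <- exp(-1000 / ar$t1_star_ms)
  # t = 0 value is the negative steady-state inversion point
  expect_equal(look_locker_signal(0, tissue_state(500), sq1),
               ar$m0_star * (e - 1) / (1 + e), tolerance = 1e-12)
  expect_lt(look_locker_signal(0, tissue_state(500), sq1), 0)
  # single-shot limit: M(t) = M0*(1 - 2 exp(-t/T1*))
  sqs <- seq_params(rr_ms = 1e5, t_inv_ms = 0, tr_ms = 25, flip_deg = 15,
                    tfe_factor = 4000, kernel_rr = 1)
  ars <- apparent_relaxation(tissue_state(500), sqs)
  expect_equal(look_locker_signal(300, tissue_state(500), sqs),
               ars$m0_star * (1 - 2 * exp(-300 / ars$t1_star_ms)),
               tolerance = 1e-9)
  # zero crossing at T1* log(2/(1+e))
  tn <- ll_zero_crossing(tissue_state(500), sq1)
  expect_equal(tn, ar$t1_star_ms * log(2 / (1 + e)), tolerance = 1e-9)
  expect_equal(look_locker_signal(tn, tissue_state(500), sq1), 0,
               tolerance = 1e-12)
  # reduction: a two-RR kernel with the acquisition filling each RR and
  # t_inv = 0 reproduces the LL signal with twice the inversion period
  sq2 <- seq_params(rr_ms = 500, t_inv_ms = 0, tr_ms = 25, flip_deg = 15,
                    tfe_factor = 20, kernel_rr = 2)
  ss <- steady_state_kernel(tissue_state(500), sq2)
  expect_equal(ss$m_a, look_locker_signal(0, tissue_state(500), sq1),
               tolerance = 1e-8)
  expect_equal(ss$m_d, look_locker_signal(500, tissue_state(500), sq1),
               tolerance = 1e-8)
  expect_error(look_locker_signal(0, tissue_state(500), fig_seq()),
               "kernel_rr = 1")
  expect_error(look_locker_signal(1000, tissue_state(500), sq1), "rr_ms")
})
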