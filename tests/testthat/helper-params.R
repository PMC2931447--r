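# Shared fixtures: the illustrative kernel (T1 = 400 ms tissue, RR 1 s,
# TR 10 ms, flip 15 deg, TFE 19) and the in-vivo protocol kernel
# (TR 9.4 ms, TFE 23 -> T_acq ~ 216 ms, flip 18 deg, T_inv 300 ms).

fig_seq <- function(...) {
  args <- utils::modifyList(
    list(rr_ms = 1000, t_inv_ms = 300, tr_ms = 10, flip_deg = 15,
         tfe_factor = 19, kernel_rr = 2),
    list(...))
  do.call(seq_params, args)
}

protocol_seq <- function(...) {
  args <- utils::modifyList(
    list(rr_ms = 1000, t_inv_ms = 300, tr_ms = 9.4, flip_deg = 18,
         tfe_factor = 23, kernel_rr = 2),
    list(...))
  do.call(seq_params, args)
}

phantom_t1s <- c(228, 298, 411, 539, 638, 754)

# Steady-state checkpoints from the discrete pulse-by-pulse oracle
# (constant RR, enough kernels to settle).
oracle_steady <- function(t1, seq, n_kernels = 300, m0 = 1) {
  tr <- pulse_by_pulse_trajectory(tissue_state(t1, m0), seq,
                                  rep(seq$rr_ms, n_kernels * seq$kernel_rr))
  tr[nrow(tr), -1]
}
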