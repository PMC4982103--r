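# Shared fixtures: everything is built in code, no stored data.

default_params <- function(...) chela_params(...)

default_thermo <- function() thermo_context(K_eq_per_M = 1e-6, T_K = 307.15)

low_porphyrin_conditions <- function(...) {
  chela_conditions(D_total_M = 2.5e-6, ATP0_M = 5e-3, ...)
}

# Independent bisection oracle for the steady-state balance equation
# v(D) = k_loss * (D_total - D); deliberately avoids stats::uniroot so it
# can cross-check find_steady_state.
bisect_steady_state <- function(params, cond, iter = 200) {
  Dtot <- cond$D_total_M
  g <- function(D) {
    chelation_velocity(list(D_M = D, MgD_M = Dtot - D, ATP_M = cond$ATP0_M),
                       params, cond) -
      params$k_dechel_per_s * (Dtot - D)
  }
  lo <- Dtot * 1e-14
  hi <- Dtot
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
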