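# Memoized full-length protocol runs shared across test files (the model is
# deterministic, so one run per configuration is enough).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(protocol, flag_set = "none", mode = "slow",
                       dt = 1e-3, t_end = 1800) {
  key <- paste(protocol, flag_set, mode, dt, t_end, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_protocol(protocol, flag_set = flag_set,
                                           mode = mode, dt = dt,
                                           t_end = t_end)
  }
  .sim_cache[[key]]
}

# no-treatment schedule pair used by free-evolution tests
no_treatment <- function() {
  rt <- build_rt_schedule("RT1", n_fractions = 0)
  list(rt = rt, ht = build_ht_schedule("HT0", rt))
}

# single-fraction dynamic-LQ log kill for a non-dividing population,
# integrated analytically: Gamma(t) = (R/gamma)(1 - e^(-gamma t)) during
# beam-on, kill rate (alpha + 2 beta Gamma) R, no kill after beam-off.
lq_logkill_analytic <- function(dose, rate, alpha, beta, gamma) {
  tau <- dose / rate
  lin <- alpha * dose
  quad <- 2 * beta * rate^2 * (tau / gamma + (exp(-gamma * tau) - 1) / gamma^2)
  c(linear = lin, quadratic = quad, total = lin + quad)
}
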