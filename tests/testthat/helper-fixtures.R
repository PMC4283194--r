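# Shared fixtures: one schedule and one noise-free input function are
# enough for most tests; building them once keeps the suite fast.

fx_schedule <- default_frame_schedule()
fx_input <- simulate_input()

fx_tac_1tc <- function(K1 = 0.15, k2 = 0.02, bv = 0.05, noise = 0,
                       region_id = "region") {
  simulate_tac(list(K1 = K1, k2 = k2, bv = bv), fx_input, fx_schedule,
               noise_scale = noise, region_id = region_id)
}

# independent brute-force one-way ANOVA ICC via stats::aov, for oracle
# comparison with the package's closed-form implementation
oracle_icc_aov <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m)))
  )
  ms <- summary(stats::aov(y ~ subject, data = d))[[1]][["Mean Sq"]]
  msbs <- ms[1]
  msws <- ms[2]
  (msbs - msws) / (msbs + (ncol(m) - 1) * msws)
}
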