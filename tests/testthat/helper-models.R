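# Shared fixtures: classifiers and nights are expensive to build, so they are
# trained/simulated lazily once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small models for unit tests
tiny_quality_model <- function() cached("qm_tiny",
  train_quality_model(n_nights = 1, duration_s = 3600, seed = 101))

tiny_n3_model <- function() cached("nm_tiny",
  train_n3_model(tiny_quality_model(), n_nights = 2, duration_s = 5400, seed = 202))

# full-size models for the acceptance checks
shipped_quality_model <- function() cached("qm_ship", train_quality_model(seed = 100))

shipped_n3_model <- function() cached("nm_ship",
  train_n3_model(shipped_quality_model(), seed = 200))

# one clean mid-size night shared by several unit tests
unit_night <- function() cached("night_unit", {
  cfg <- sleep_sim_config(duration_s = 3600, seed = 555)
  hyp <- simulate_hypnogram(cfg)
  c(synthesize_night(hyp, cfg), list(hypnogram = hyp, config = cfg))
})

# closed-loop runs over several nights, shared between the scheduler-audit
# and detector-tuning acceptance checks
acceptance_nights <- function(n = 5) cached("acc_nights", {
  qm <- shipped_quality_model(); nm <- shipped_n3_model()
  lapply(seq_len(n), function(k) {
    cfg <- sleep_sim_config(duration_s = 6 * 3600, seed = 7000 + k)
    hyp <- simulate_hypnogram(cfg)
    sim <- synthesize_night(hyp, cfg)
    res <- run_closed_loop(sim$recording, qm, nm, seed = k)
    list(hypnogram = hyp,
         events = res$events, predicted = res$predicted,
         movements = res$movements)
  })
})

# periodogram band-power fraction, independent of the package's band-power
# implementation (used as an oracle)
oracle_band_fraction <- function(x, fs, band, total = c(0.1, 30)) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE, taper = 0)
  inb <- sp$freq >= band[1] & sp$freq < band[2]
  tot <- sp$freq >= total[1] & sp$freq < total[2]
  sum(sp$spec[inb]) / sum(sp$spec[tot])
}
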