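# Shared fixtures: small simulated pairs and tiny models, built in code.

fixture_pair <- function(duration_s = 120, rate = 30, seed = 7, ...) {
  simulate_pair(sim_config(duration_s = duration_s, apnea_event_rate = rate,
                           seed = seed, ...))
}

# a tiny conv model (2 channels, short input) for oracle tests
tiny_conv_model <- function(seed = 1L, input_len = 16L) {
  build_branch(branch_spec("SPO2", input_len = input_len,
                           conv_layers = list(c(2L, 3L, 1L))), seed = seed)
}

# independent shape-propagation oracle: plain integer arithmetic, no package
# internals
oracle_shapes <- function(input_len, conv_layers, padding) {
  len <- input_len
  for (cl in conv_layers) {
    k <- cl[2]; s <- cl[3]
    if (padding == "same") {
      len <- ceiling(len / s)
    } else {
      if (len < k) return(NA_integer_)
      len <- floor((len - k) / s) + 1
    }
    len <- len %/% 2  # pool 2/2
    if (len < 1) return(NA_integer_)
  }
  as.integer(len * conv_layers[[length(conv_layers)]][1])
}

# brute-force time-domain normalized autocorrelation
oracle_acf <- function(x, lag_max) {
  n <- length(x)
  denom <- sum(x^2)
  vapply(0:lag_max, function(l) sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / denom,
         numeric(1))
}

# build a small aligned labeled pair from simulated records
fixture_window_pair <- function(n_rec = 2, duration_s = 120, seed = 11,
                                filter_ecg = FALSE) {
  ecg_sets <- list(); spo2_sets <- list()
  for (i in seq_len(n_rec)) {
    p <- fixture_pair(duration_s, seed = seed + i)
    id <- sprintf("r%02d", i)
    ecg_sets[[id]] <- ingest_record(p$ecg, source_id = id)
    spo2_sets[[id]] <- ingest_record(p$spo2, source_id = id)
  }
  ecg <- apneafusion:::bind_window_sets(ecg_sets)
  if (filter_ecg) ecg <- bandpass(ecg)
  list(ecg = ecg, spo2 = apneafusion:::bind_window_sets(spo2_sets))
}
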