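# Small fixtures shared across test files; everything is generated in code.

small_design <- function(replicates = 2) {
  build_design(n_evoo = 4, n_adulterants = 3, levels = c(0.05, 0.1, 0.2),
               replicates = replicates)
}

small_dataset <- function(design = small_design(), modality = "UVVIS",
                          noise_sd = 0, drift_sd = 0, seed = 1) {
  simulate_dataset(design, modality, noise_sd = noise_sd,
                   drift_sd = drift_sd, seed = seed)
}

small_chain_config <- function(...) {
  args <- utils::modifyList(
    list(folds = 4, repetitions = 2, seed = 1, lv_max = 8, lv_max_reg = 8,
         baseline = FALSE, normalize = FALSE),
    list(...))
  do.call(chain_config, args)
}

# independent brute-force one-SE selection used as oracle
brute_force_one_se <- function(means, ses, maximize) {
  best <- if (maximize) max(means) else min(means)
  for (i in seq_along(means)) {
    ok <- if (maximize) means[i] + ses[i] > best else means[i] - ses[i] < best
    if (ok) return(i)
  }
  if (maximize) which.max(means) else which.min(means)
}
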