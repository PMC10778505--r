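# shared fixtures: ground-truth parameter sets and tiny generators

# bounds-interior ground truth for every registered model, chosen to give a
# positive, monotone-ish moisture curve on aw in [0.09, 0.83]
truth_params <- list(
  peleg = c(C1 = 0.40, C2 = 5.0, C3 = 0.03, C4 = 1.5),
  gab = c(Xm = 0.06, C = 13.83, K = 0.89),
  bet = c(Xm = 0.05, C = 5),
  halsey = c(A = 0.01, B = 1.8),
  oswin = c(K = 0.10, n = 0.41),
  smith = c(A = 0.04, B = 0.09),
  adam_shove = c(A = 0.02, B = 0.10, C = 0.20, D = 0.30),
  mod_oswin = c(A = 0.02, B = 0.003, C = 0.45),
  mod_halsey = c(A = -4.5, B = 0.04, C = 1.6),
  dent = c(Xm = 0.05, b = 0.05, b0 = 10)
)

# noiseless single-temperature slice on the measured aw range
noiseless_group <- function(model_id, params = truth_params[[model_id]],
                            T_K = 308.15, branch = "adsorption", n = 15,
                            aw = seq(0.09, 0.83, length.out = n)) {
  xe <- st_evaluate(model_id, params, aw, T_C = kelvin_to_celsius(T_K))
  sorption_dataset(branch, rep(T_K, length(aw)), aw, xe)
}

# noiseless multi-temperature slice (for temperature-dependent models)
noiseless_multiT_group <- function(model_id, params = truth_params[[model_id]],
                                   temps_K = c(298.15, 308.15, 318.15),
                                   branch = "adsorption", n_per_T = 5) {
  aw <- seq(0.15, 0.80, length.out = n_per_T)
  rows <- lapply(temps_K, function(Tv) {
    data.frame(branch = branch, T = Tv, aw = aw,
               xe = st_evaluate(model_id, params, aw,
                                T_C = kelvin_to_celsius(Tv)))
  })
  ds <- do.call(rbind, rows)
  class(ds) <- c("sorption_dataset", "data.frame")
  ds
}

# Dent reference curve used by the Clausius-Clapeyron constructions;
# type-III-ish shape whose image covers moisture 0.002-0.32 g/g
dent_ref_params <- c(Xm = 0.05, b = 0.85, b0 = 5)
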