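# Shared small fixtures for the suite.

# a quick subject with the standard clinical geometry
quick_subject <- function(seed = 1, group = "A",
                          cfg = synth_config(n_per_group = 2)) {
  set.seed(seed)
  generate_subject(cfg, group, paste0("fix", seed))
}

# reduced-geometry config for cheap generator tests (4 channels, 2
# modules, 100 Hz) — the model is identical, only smaller
tiny_config <- function(...) {
  synth_config(channels = c("Fz", "Cz", "Pz", "O1"),
               module_assignment = c(Fz = 1, Cz = 1, Pz = 2, O1 = 2),
               fs = 100, ...)
}

# a random long-format metrics table for stats-level tests that do not
# need real EEG behind them
fake_metrics <- function(n_subj = 20, seed = 99,
                         measures = c("degree", "strength", "radius",
                                      "diameter",
                                      "characteristic_path_length",
                                      "global_efficiency",
                                      "local_efficiency",
                                      "clustering_coefficient",
                                      "transitivity", "modularity",
                                      "assortativity",
                                      "small_worldness"),
                         bands = c("delta", "theta", "alpha", "beta",
                                   "gamma")) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_subj))
  df <- expand.grid(subject_id = ids, band = bands, measure = measures,
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df))
  cov <- data.frame(subject_id = ids,
                    group = rep(c("A", "B"), length.out = n_subj),
                    sex = rbinom(n_subj, 1, 0.5),
                    mmse = round(rnorm(n_subj, 27, 1.5)),
                    stringsAsFactors = FALSE)
  list(metrics = df, covariates = cov)
}
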