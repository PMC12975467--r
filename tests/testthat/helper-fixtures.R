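# shared fixtures: all inputs are generated in code at test time

# small method settings sized for n >= 150 test datasets
small_settings <- function() {
  taxo_settings(n_cuts = 20L, end_offset = 10L, replications = 4L,
                n_windows = 20L, overlap = 0.9, grid_points = 128L)
}

# write a small CSV fixture and return its path
write_csv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile("fixture", tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a taxonic/dimensional matched pair at the standard recovery conditions
recovery_pair <- function(seed, d = 2, n = 600L, within_r = 0.1) {
  matched_pair(synthetic_spec("taxonic", n = n, k = 3L, base_rate = 0.25,
                              separation = d, within_r = within_r,
                              seed = seed))
}

# mean CCFI of one dataset under the standard recovery harness (validity
# gate off: the harness measures CCFI behaviour, not the d >= 1.25 gate)
recovery_mean_ccfi <- function(matrix, seed, n_sets = 50L) {
  cfg <- run_config(matrix, n_sets = n_sets, enforce_validity = FALSE,
                    seed = seed)
  run_full_analysis(cfg)$ccfi$mean_ccfi
}
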