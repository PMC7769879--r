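# Shared fixtures and independent oracles used across test files.

# Independent electron-equivalents oracle: balance the oxidation
# half-reaction  CxHyOz + w H2O -> x CO2 + p H+ + n e-
# by solving the atom/charge linear system (O: z + w = 2x; H: y + 2w = p;
# charge: p = n). Deliberately does not use the 4C + H - 2O shortcut.
half_reaction_electrons <- function(c_atoms, h_atoms, o_atoms) {
  A <- matrix(c(1, 0, 0,    # w          = 2c - o
                2, -1, 0,   # 2w - p     = -h
                0, 1, -1),  # p - n      = 0
              nrow = 3, byrow = TRUE)
  b <- c(2 * c_atoms - o_atoms, -h_atoms, 0)
  solve(A, b)[3]
}

# A simple two-sample series fixture.
series_fix <- function(time_h, conc_mM, compound = "propionate",
                       chamber = "cathode", cell = "T") {
  concentration_series(cell, chamber, compound, time_h, conc_mM)
}

# Noise-free single-cycle simulation with the given per-reaction extents.
sim_fix <- function(extents, lactate_mM = 20, butyrate_mM = 0,
                    duration_h = 144, noise_sd = 0, migration = 0,
                    sample_volume_mL = 1, seed = 1, ...) {
  simulate_batch(sim_params(
    seed = seed, noise_sd = noise_sd, butyrate_migration = migration,
    sample_volume_mL = sample_volume_mL, current_baseline = 0,
    cycles = list(sim_cycle(duration_h = duration_h, lactate_mM = lactate_mM,
                            butyrate_mM = butyrate_mM, extents = extents)),
    ...))
}

# Extents recovered from a (possibly noisy) simulated experiment.
recovered_extents <- function(exp, cycle_index = 1) {
  d <- cycle_deltas(exp, cycle_index)
  get0 <- function(k) if (k %in% names(d$formed)) max(d$formed[[k]], 0) else 0
  decompose_extents(list(propionate = get0("propionate"),
                         acetate = get0("acetate"),
                         butyrate = get0("butyrate"),
                         lactate = -d$consumed))
}

# Write a minimal on-disk experiment (one series, one cycle, no current)
# and return the manifest path.
minimal_manifest <- function(dir, duration_h = 381.6, conc0 = 150,
                             sample_outside = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmax <- if (sample_outside) duration_h + 10 else duration_h
  ts <- data.frame(cell_id = "L3", chamber = "cathode",
                   time_h = c(0, duration_h / 2, tmax),
                   compound = "lactate",
                   conc_mM = c(conc0, conc0 / 2, conc0 / 4))
  utils::write.csv(ts, file.path(dir, "timeseries.csv"), row.names = FALSE)
  cfg <- list(cell_id = "L3", working_volume_L = 0.15,
              timeseries = "timeseries.csv",
              cycles = list(list(index = 1L, t_start_h = 0,
                                 t_end_h = duration_h,
                                 additions = list(list(time_h = 0,
                                                       compound = "lactate",
                                                       mmol = conc0 * 0.15)))))
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(cfg, path)
  path
}
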