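# Shared fixtures, built once per test run.

# noise-free study under default conditions (all seven presets)
nf_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(seed = 101, noise = FALSE)
    cache
  }
})

# noisy study at the instrument noise of the design (0.2 permil, 5% CV)
noisy_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(seed = 202, noise = TRUE)
    cache
  }
})

default_ends <- function() study_endmembers(sim_config())

# enriched endmembers mirroring the study: daphnia near natural abundance,
# leaves at 10 atom%
enriched_ends <- function() {
  endmembers(iso_value(-20, "delta_permil"),
             iso_value(0.10, "atom_fraction"))
}

# both endmembers within +-50 permil of V-PDB
natural_ends <- function() {
  endmembers(iso_value(-30, "delta_permil"), iso_value(20, "delta_permil"))
}
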