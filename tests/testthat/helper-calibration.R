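# Shared machinery for the simulation-calibration checks: SES values for
# the four habitat communities of replicate synthetic datasets generated
# under a given filtering strength (100 species, 20 transects, 199
# randomizations per null).
calibration_ses <- function(strength, n_datasets,
                            metrics = c("FD", "PD", "MFD", "MPD"),
                            n_iter = 199, seed_base = 1000) {
  reps <- lapply(seq_len(n_datasets), function(i) {
    cfg <- sim_config(n_species = 100,
                      n_transects = c(urban = 5, farmland = 5,
                                      forest = 5, wetland = 5),
                      filtering_strength = strength,
                      seed = seed_base + i)
    ds <- simulate_dataset(cfg)
    comm <- build_community_matrix(ds$survey, "habitat")
    st <- community_structures(ds$traits, ds$tree, rownames(comm))
    tab <- suppressMessages(ses_table(comm, st, metrics = metrics,
                                      n_iter = n_iter,
                                      seed = seed_base + i))
    tab$dataset <- i
    tab
  })
  do.call(rbind, reps)
}
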