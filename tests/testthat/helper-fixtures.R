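# One small simulated study shared across test files (built once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_assembly(sim_config(
        n_species = 3, contigs_per_species = 2, contig_length = 2e4,
        n_loci = 6, n_paralog_groups = 1, seed = 42
      ))
    }
    cache
  }
})

small_loci <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- mine_loci(sim$assembly, sim$panel)
    }
    cache
  }
})
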