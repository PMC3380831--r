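# Small shared simulation helpers.

small_config <- function(...) {
  sim_config(seed = 1L, chrom_length = 50000L, n_genes = 10L, ...)
}

# One simulated replicate's worth of fragments for both time points.
sim_replicate <- function(truth, layout, config, replicate_seed = 1L) {
  list(
    t0 = simulate_fragments(truth, layout, "t0", config,
                            replicate_seed = replicate_seed),
    t3 = simulate_fragments(truth, layout, "t3", config,
                            replicate_seed = replicate_seed)
  )
}

# Nearest-call distance from each truth dyad.
dyad_distances <- function(calls, truth, dyads = truth$dyad_t0) {
  vapply(seq_len(nrow(truth)), function(i) {
    ctr <- calls$center[calls$chrom == truth$chrom[i]]
    if (!length(ctr)) return(Inf)
    min(abs(ctr - dyads[i]))
  }, numeric(1))
}
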