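# Small shared configurations so unit tests stay fast; the full-size default
# configuration is exercised in test-acceptance.R.

tiny_config <- function(seed = 1L, ...) {
  synth_config(n_samples = 2L, cells_per_sample = 150L, n_classes = 3L,
               states_per_class = c(2L, 2L, 1L), n_peaks = 300L,
               n_genes = 200L, markers_per_state = 10L,
               n_lineage_peaks = 10L, n_snps = 40L, n_motifs = 6L,
               seed = seed, ...)
}

tiny_dataset <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$ds))
      cache$ds <- generate_multiome(tiny_config())
    cache$ds
  }
})

# pseudobulk list wrapper for simulate_pseudobulk() output
as_pb <- function(sim) {
  structure(list(counts = sim$counts, sample = sim$sample, state = sim$state,
                 n_cells = rep(100L, length(sim$sample)),
                 n_fragments = sim$n_fragments,
                 included = rep(TRUE, length(sim$sample))),
            class = "pseudobulk")
}
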