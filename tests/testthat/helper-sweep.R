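# The factorial sweep used by the acceptance tests is computed once per
# session and shared across test blocks.
.sweep_cache <- new.env(parent = emptyenv())

reference_sweep <- function() {
  if (is.null(.sweep_cache$tab)) {
    sp <- sweep_spec(display_levels = 2500, replicates = 10,
                     master_seed = 101)
    .sweep_cache$tab <- factorial_sweep(sp)
  }
  .sweep_cache$tab
}

# smaller items-only sweep crossing food with display abundance, for the
# lost-opportunity trends
lost_sweep <- function() {
  if (is.null(.sweep_cache$lost)) {
    sp <- sweep_spec(display_levels = c(250, 2500, 25000),
                     builds = list(build_flags(items_needed = TRUE)),
                     replicates = 5, master_seed = 202)
    .sweep_cache$lost <- factorial_sweep(sp)
  }
  .sweep_cache$lost
}
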