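## Shared, lazily built model sets. Calibration uses 200 decoys per model
## (the Gumbel fit is stable well below the default 1000 and keeps the
## suite fast); seeds are fixed once.
.test_cache <- new.env(parent = emptyenv())

test_family_models <- function() {
  if (is.null(.test_cache$fam)) {
    .test_cache$fam <- build_family_models(n_decoys = 200, seed = 101)
  }
  .test_cache$fam
}

test_marker_models <- function() {
  if (is.null(.test_cache$mark)) {
    .test_cache$mark <- build_family_models(marker_families(), marker = TRUE,
                                            n_decoys = 200, seed = 102)
  }
  .test_cache$mark
}

## Shared three-genome community (one degrader, two background) used by
## the end-to-end checks.
e2e_community <- function() {
  if (is.null(.test_cache$e2e)) {
    cfg <- sim_config(seed = 21, n_degraders = 1, n_background = 2,
                      genome_length = 30000,
                      gc_values = c(0.35, 0.5, 0.65))
    panel <- generate_reference_panel(cfg)
    .test_cache$e2e <- list(cfg = cfg, panel = panel,
                            fc = fragment_community(panel, cfg))
  }
  .test_cache$e2e
}

run_e2e <- function(extra_samples = NULL) {
  com <- e2e_community()
  samples <- c(list(com$fc$contigs), extra_samples)
  run_pipeline(samples, pipeline_config(seed = 3),
               family_models = test_family_models(),
               marker_models = test_marker_models(),
               ref_panel = synthetic_reference_panel())
}

## Unfragmented degrader genome plus its ORFs at a given planted-gene
## divergence (memoized per divergence).
test_degrader_orfs <- function(divergence = 0) {
  key <- sprintf("deg_%s", divergence)
  if (is.null(.test_cache[[key]])) {
    cfg <- sim_config(seed = 301 + round(100 * divergence),
                      n_degraders = 1, n_background = 0,
                      genome_length = 25000, divergence = divergence)
    panel <- generate_reference_panel(cfg)
    g <- panel$genomes[[1]]
    .test_cache[[key]] <- list(
      genome = g,
      orfs = call_orfs(g$sequence, contig_id = g$genome_id,
                       sample_id = "deg"))
  }
  .test_cache[[key]]
}
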