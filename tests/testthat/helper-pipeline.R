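# Two full pipeline runs under one seed, cached for reuse by the
# determinism and bookkeeping tests.

pipeline_cfg <- function(seed = 3L) {
  pipeline_config(species_tree = "((SpA:1,SpB:1):1,SpC:2);",
                  lambda = 0, mu = 0, subst_rate = 0.08,
                  protein_length = 200L,
                  model = list(max_intron = 2000L),
                  bootstrap = list(n_reps = 20L, collapse_cutoff = 50),
                  seed = seed)
}

pipeline_fixture <- function() {
  fixture("pipeline_runs", function() {
    d1 <- file.path(tempdir(), "famtrace_run1")
    d2 <- file.path(tempdir(), "famtrace_run2")
    r1 <- run_pipeline(pipeline_cfg(), d1)
    r2 <- run_pipeline(pipeline_cfg(), d2)
    list(d1 = d1, d2 = d2, r1 = r1, r2 = r2)
  })
}
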