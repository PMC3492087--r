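# Shared end-to-end fixture: one full synthetic run at the benchmark scale
# (10 kb target, 40 haploid samples, 50x, error 0.003), built lazily and
# reused by every test that needs a complete run.  A singleton in a
# 40-sample cohort has frequency 1/40, so the rare filter of this run uses
# case_freq_max just above that.

.e2e_cache <- new.env(parent = emptyenv())

e2eConfig <- function() {
  simulationConfig(
    target_length = 10000, n_amplicons = 2, n_samples = 40, mean_depth = 50,
    read_length = 100, fragment_mean = 300, fragment_sd = 30,
    error_rate = 0.003, n_variants = 60, rare_fraction = 0.65,
    catalog_fraction = 0.9, conserved_fraction = 0.2,
    indel_fraction = 0.15, seed = 20260925
  )
}

e2eRun <- function() {
  if (is.null(.e2e_cache$run)) {
    outdir <- file.path(tempdir(), "hemivar-e2e")
    cfg <- runConfig(e2eConfig(), case_freq_max = 1 / 40 + 0.001)
    .e2e_cache$run <- suppressMessages(runPipeline(cfg, outdir))
  }
  .e2e_cache$run
}

variantKey <- function(df) paste(df$pos, df$ref, df$alt)
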