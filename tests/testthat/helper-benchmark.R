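# The desk-scale benchmark protocol shared by the acceptance tests and
# (in script form) by scripts/acceptance.R: a ~2,000-window planted-motif
# fixture, two-stage training (motif pretrain -> anchor fine-tune) of the
# tiny-profile model in post-hoc conjoined mode. Problem sizes and
# optimizer settings are the package's desk-scale protocol, documented in
# the methods vignette. Bundles are cached per seed for the test run.

desk_train_config <- function(seed, epochs = 10L) {
  train_config(learning_rate = 1e-3, epochs = epochs, batch_size = 32L,
               seed = seed)
}

# motif-presence labels for stage 1, from the scan
motif_presence_labels <- function(manifest, genome, pwm) {
  hits <- scan_motifs(genome, pwm, 5e-5)
  intersect_any(genomic_intervals(manifest$windows$chrom,
                                  manifest$windows$start,
                                  manifest$windows$end), hits)
}

# full simulate -> build -> pretrain -> train bundle for one seed
train_benchmark_bundle <- function(seed, mode = "posthoc_conjoined",
                                   epochs = 10L) {
  spec <- fixture_spec(seed = seed)
  fx <- plant_windows(make_background_genome(spec), spec)
  fx$spec <- spec
  manifest <- build_dataset(fx$genome, fx$peaks$ctcf, fx$peaks$chiapet,
                            fx$peaks$atac, spec$primary_motif,
                            window_length = spec$window_length, seed = seed)
  motif_lab <- motif_presence_labels(manifest, fx$genome, spec$primary_motif)
  model <- build_model(tiny_model_config(dropout = 0), seed = seed,
                       mode = mode)
  pre <- pretrain_motif_classifier(manifest, motif_lab, fx$genome,
                                   desk_train_config(seed + 100L, epochs),
                                   model)
  fit <- train_anchor_classifier(manifest, fx$genome,
                                 desk_train_config(seed + 200L, epochs),
                                 model, init_from = pre$model)
  list(spec = spec, fixture = fx, manifest = manifest, model = fit$model,
       pretrain_log = pre$log, train_log = fit$log)
}

benchmark_bundle <- function(seed) {
  cache_get(paste0("bundle_", seed), function() train_benchmark_bundle(seed))
}

# the three standing benchmark seeds used by the multi-seed criteria
BENCH_SEEDS <- c(101L, 102L, 103L)
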