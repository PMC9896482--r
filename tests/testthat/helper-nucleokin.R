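# Shared helpers: reference parameters of the synthetic benchmark and a
# memoized default-conditions pipeline run reused across test files.

ref_params <- function() distribution_params(J = 0.1, tg = 10000)
ref_volume <- 0.01

.nk_test_cache <- new.env(parent = emptyenv())

cached_pipeline_run <- function(seed = 1L, band_datasets = 200L) {
  key <- sprintf("run_%d_%d", seed, band_datasets)
  if (is.null(.nk_test_cache[[key]])) {
    cfg <- run_config(seed = seed, out_dir = tempfile("nkrun_"),
                      benchmark = list(n_datasets = band_datasets))
    .nk_test_cache[[key]] <- run_pipeline(cfg, quiet = TRUE)
  }
  .nk_test_cache[[key]]
}

# A small feature tibble with canonical column names filled from a matrix,
# for reduction/PCA tests that do not need a full study.
canonical_tibble <- function(X, cols) {
  colnames(X) <- cols
  tibble::as_tibble(as.data.frame(X))
}
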