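# One shared end-to-end analysis for the pipeline tests: big enough that all
# nine predictors (15 parameters after dummy coding) are estimable from the
# surviving groups, computed once per test run.
.fbd_cache <- new.env(parent = emptyenv())

shared_analysis <- function() {
  if (is.null(.fbd_cache$res)) {
    cfg <- pipeline_config(n_compartments = 800, seed = 101)
    .fbd_cache$out_dir <- file.path(tempdir(), "fbd-shared-out")
    .fbd_cache$res <- suppressWarnings(
      run_forest_bird_analysis(cfg, out_dir = .fbd_cache$out_dir))
  }
  .fbd_cache$res
}

shared_analysis_dir <- function() {
  shared_analysis()
  .fbd_cache$out_dir
}
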