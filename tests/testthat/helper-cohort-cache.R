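# Full-size default cohorts are expensive (~30 s each); the acceptance
# criteria share them through this memoizing helper.
.cohort_cache <- new.env(parent = emptyenv())

cached_default_run <- function(seed, preset = "default") {
  key <- paste0(preset, seed)
  if (is.null(.cohort_cache[[key]])) {
    log <- touchkin::generate_cohort(30, preset, seed = seed)
    .cohort_cache[[key]] <- list(log = log, table = touchkin::featurize_cohort(log))
  }
  .cohort_cache[[key]]
}
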