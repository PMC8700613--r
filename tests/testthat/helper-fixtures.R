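# Shared fixtures, generated once per test run and memoized.

# Default-world cohort (43 + 43 subjects, 20 regions, 4 affected), ~6 s.
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(generate_cohort(sim_config(), seed = 42L))
    cache
  }
})

# Tiny cohort for I/O and CLI tests.
tiny_config <- function(...) {
  sim_config(n_per_group = 2L, grid_dim = c(6L, 6L, 6L), n_rois = 8L,
             affected_rois = c(3L, 7L), link_roi = 3L, ...)
}

group_vector <- function(cohort_tbl) {
  stats::setNames(cohort_tbl$group, cohort_tbl$subject_id)
}
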