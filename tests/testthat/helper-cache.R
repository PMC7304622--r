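# Shared experiment runs, computed once per test session. The default-
# configuration run backs the end-to-end checks; the reduced configuration
# keeps determinism and CLI tests fast.

.run_cache <- new.env(parent = emptyenv())

cached_default_report <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- run_experiment(
      default_config(seed = 1),
      out_dir = file.path(tempdir(), "otolrp-default-run"),
      quiet = TRUE
    )
  }
  .run_cache$default
}

tiny_config <- function(seed = 7) {
  cfg <- default_config(seed = seed)
  cfg$generator$ages <- 1:6
  cfg$generator$n_per_age <- 6
  cfg$generator$canvas_size <- 40
  cfg$generator$target_vertical_extent <- 24
  cfg$network$conv_filters <- c(4, 8)
  cfg$network$dense_units <- 16
  cfg$train$epochs <- 2
  cfg$spray$n_permutations <- 49
  # a 2-epoch model rarely predicts beyond the juvenile range: group the
  # descriptors by read age so both groups are always represented
  cfg$spray$group_source <- "read"
  cfg
}
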