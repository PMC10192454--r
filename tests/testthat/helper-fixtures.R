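# Shared helpers: tiny in-memory tables and a canned simulated trial.

make_poll_df <- function() {
  data.frame(
    cross_label = rep(c("JX1/90 × JX1/51", "JX1/11 × JX1/11"), each = 3),
    replicate = rep(1:3, 2),
    n_pollinated = 20L,
    n_pod = c(14L, 15L, 13L, 2L, 1L, 3L),
    n_pseudo = c(1L, 0L, 2L, 4L, 5L, 3L),
    n_dropped = c(5L, 5L, 5L, 14L, 14L, 14L),
    stringsAsFactors = FALSE
  )
}

make_trait_df <- function() {
  data.frame(
    cross_label = c("JX1/90 × JX1/51", "JX1/11 × JX1/11"),
    pod_weight = c(210.5, 80.2),
    weight_unpeeled = c(100, 50),
    weight_peeled = c(70, 30),
    outturn = c(70, 60),
    brix = c(14, 9),
    stringsAsFactors = FALSE
  )
}

write_temp_csv <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

# A small simulated trial reused across tests (built once per test run).
canned_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- sim_params(seed = 202L, n_genotypes = 12)
      pop <- make_population(params)
      design <- make_crossing_design(pop, n_singles = 12, n_doubles = 4,
                                     seed = 202L)
      cache <<- simulate_crossing_trial(pop, design, params)
    }
    cache
  }
})
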