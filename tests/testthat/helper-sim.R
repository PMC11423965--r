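# Shared fixtures for simulator-based tests: small grids keep unit tests
# fast; full-length cases are only built in the acceptance suite.

small_cfg <- function(duration_s = 10, power_preset = "P15", rng_seed = 1L,
                      ...) {
  sim_config(grid_height_px = 240L, grid_width_px = 320L, mm_per_px = 0.1,
             duration_s = duration_s, power_preset = power_preset,
             rng_seed = rng_seed, ...)
}

random_patch <- function(n = 8, Ng = 6, seed = 1) {
  with_seed <- get("with_seed", asNamespace("echotherm"))
  with_seed(seed, matrix(sample.int(Ng, n * n, replace = TRUE), n, n))
}

checkerboard <- function(n = 8, vals = c(0, 255)) {
  matrix(vals[(outer(seq_len(n), seq_len(n), "+") %% 2) + 1], n, n)
}

rotate90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

# Shared heavyweight artifacts for the acceptance suite, built once.
acceptance_env <- new.env(parent = emptyenv())

acceptance_cases <- function() {
  if (is.null(acceptance_env$cases)) {
    acceptance_env$cases <- lapply(1:4, function(i) {
      generate_case(sim_config(
        grid_height_px = 240L, grid_width_px = 320L, mm_per_px = 0.1,
        duration_s = 90, power_preset = "P15", rng_seed = 1000L + i),
        out_dir = file.path(tempdir(), sprintf("acc_case_%d", i)))
    })
  }
  acceptance_env$cases
}

acceptance_features <- function() {
  if (is.null(acceptance_env$features)) {
    samples <- do.call(c, lapply(acceptance_cases(), ingest_case))
    samples <- split_dataset(samples, seed = 7L)
    acceptance_env$features <- feature_table(samples, mm_per_px = 0.1)
  }
  acceptance_env$features
}

acceptance_model <- function() {
  if (is.null(acceptance_env$model)) {
    ft <- acceptance_features()
    fc <- feature_names()
    tr <- ft$split == "train"; va <- ft$split == "val"
    acceptance_env$model <- fit_temperature_model(
      ft[tr, fc], ft$temperature_C[tr],
      validation = list(x = ft[va, fc], y = ft$temperature_C[va]),
      config = forest_config(seed = 11L), power_label = "15W")
  }
  acceptance_env$model
}
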