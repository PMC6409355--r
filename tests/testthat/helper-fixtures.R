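# Shared fixtures: all inputs are built in code at test time.

write_fixture <- function(lines, ext, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, path)
  path
}

# A small deterministic records tibble (n_genes x 8 days).
small_records <- function(n_genes = 3, seed = 42, noise_sd = 0.01, ...) {
  generate_timecourse(
    generative_config(n_genes = n_genes, seed = seed, noise_sd = noise_sd, ...)
  )$records
}

# Random Model-4 design instances (one gene over the eight days) with an
# unstructured pure-noise response, for oracle comparisons.
random_instance <- function(seed) {
  records <- withr::with_seed(seed, tibble::tibble(
    gene_id = "g",
    day = c(0L, 1L, 3L, 5L, 7L, 11L, 15L, 18L),
    height = runif(8, 1, 10),
    distance = runif(8, 0, 1500),
    width = runif(8, 50, 500),
    expression = rnorm(8)
  ))
  dm <- design_matrix(records, model_spec(4))
  list(records = records, X = dm$X, y = dm$y)
}
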