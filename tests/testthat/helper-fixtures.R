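# Shared fixtures. The standard 2 Mb fixture and its pipeline run are
# expensive, so they are built lazily once per test session.

.fixture_cache <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- generate_fixture(fixture_spec(seed = 42L))
  }
  .fixture_cache$fx
}

std_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    fx <- std_fixture()
    out <- file.path(tempdir(), "std_pipeline")
    .fixture_cache$pipe <- run_marker_pipeline(
      fx$genome, genes = fx$genes, out_dir = out, seed = 7L, quiet = TRUE)
    .fixture_cache$pipe_dir <- out
  }
  .fixture_cache$pipe
}

std_pipeline_dir <- function() {
  std_pipeline()
  .fixture_cache$pipe_dir
}

# a small, fast fixture for unit tests
small_fixture <- function(seed = 11L) {
  key <- paste0("small", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixture(fixture_spec(
      seed = seed,
      scaffold_lengths = c(ctgA = 120000L, ctgB = 80000L),
      n_ssr_per_class = c(3L, 5L, 4L, 4L, 3L, 5L, 3L),
      n_genes = 6L, introns_per_gene = c(3L, 3L, 3L, 2L, 2L, 2L),
      n_duplications = 1L, segment_length = 20000L,
      ssr_per_duplication = 6L))
  }
  .fixture_cache[[key]]
}

ssr_key <- function(df) {
  paste(df$seq_id, df$start, df$end, df$class_k, df$motif, df$repeat_count)
}
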