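# Shared fixtures, built once per test run. The standard fixtures are
# deterministic (fixed seeds inside make_standard_fixtures), so caching them
# in an environment is safe.
.fixture_cache <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- make_standard_fixtures()
  .fixture_cache$fx
}

# a small, quick 3-type dataset for unit tests that need structure but not
# the full 600-cell fixture
small_dataset <- function(seed = 7) {
  simulate_dataset(simulation_spec(n_types = 3, cells_per_type = 50,
                                   n_genes = 60, n_batches = 1, seed = seed))
}

tiny_counts <- function(n = 5, G = 7, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * G, 3), n, G)
  count_matrix(m, gene_ids = paste0("g", seq_len(G)),
               cell_ids = paste0("c", seq_len(n)))
}
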