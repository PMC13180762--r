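# Fixtures built in code: tiny hypergraphs with known structure.

# Hypergraph from a list of (year, member-id vector) pairs over n concepts.
make_th <- function(edges, n_concepts = max(unlist(lapply(edges, `[[`, 2L)))) {
  vocab <- concept_vocabulary(sprintf("c%03d", seq_len(n_concepts)))
  records <- lapply(seq_along(edges), function(i)
    list(source = sprintf("e%d", i), year = edges[[i]][[1L]],
         members = edges[[i]][[2L]]))
  temporal_hypergraph(records, vocab)
}

# A chain fixture: one lineage, one hyperedge per year, consecutive overlap,
# so the unique full-length trail is forced.
chain_th <- function(n_years = 4L) {
  make_th(lapply(seq_len(n_years), function(i)
    list(1999L + i, c(i, i + 1L, i + 2L))), n_concepts = n_years + 2L)
}

# Random small hypergraph for property tests.
random_th <- function(n_concepts = 8L, n_edges = 6L, n_years = 3L,
                      min_size = 2L, max_size = 4L) {
  make_th(lapply(seq_len(n_edges), function(i) {
    list(2000L + sample.int(n_years, 1L) - 1L,
         sample.int(n_concepts, sample(min_size:max_size, 1L)))
  }), n_concepts = n_concepts)
}

# Tiny model configuration for fast training tests.
tiny_config <- function(epochs = 2L, ...) {
  hypertrail_config(d = 8L, d_time = 2L, walk_length_L = 3L, n_heads = 2L,
                    ffn_width = 12L, scorer_hidden = 8L, epochs = epochs,
                    batch_size = 8L, ...)
}

# Small synthetic dataset for integration tests.
tiny_sim <- function(seed = 7L) {
  simulate_hypergraph(synthetic_config(n_concepts = 120L, n_lineages = 10L,
                                       T_steps = 5L, seed = seed))
}

write_jsonl_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

# Bare hyperedge for sampler tests.
new_hyperedge_for_test <- function(members, t = 0L, id = 1L) {
  list(id = id, source = NA_character_, t = as.integer(t),
       members = sort(unique(as.integer(members))))
}

# Run expr under a seed without disturbing the suite's RNG stream.
with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
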