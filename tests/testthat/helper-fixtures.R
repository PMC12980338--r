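# Shared fixtures for the test suite. Everything is generated in code; a
# session-level cache avoids regenerating the heavier objects across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  promtok:::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, "")
  })
}

# Minimal promoter_windows table from raw sequences.
windows_from_seqs <- function(seqs, label = "positive", organism = "orgA",
                              prefix = "w") {
  promoter_windows(
    id = sprintf("%s%04d", prefix, seq_along(seqs)),
    organism = organism, sequence = seqs, label = label,
    source = if (label == "positive") "epd_like" else "fragment_negative",
    paired_positive_id = if (label == "positive") NA_character_ else
      sprintf("%s%04d", "w", seq_along(seqs)))
}

# Small two-organism genome set shared across I/O and negatives tests.
small_genome_set <- function() {
  cached("small_gs", {
    phylo <- generate_phylogeny(preset = "epd8")
    cfg <- sim_config(n_organisms = 2, promoters_per_organism = 25,
                      tss_spacing = 1500, seed = 101)
    synthesize_genome_set(cfg, phylo)
  })
}

small_positives <- function() {
  cached("small_pos", extract_positive_windows(small_genome_set()))
}

# Stub "classifier": a probability function keyed to one decisive token id.
stub_keyed_model <- function(key_id, hit = 0.95, miss = 0.10) {
  function(ids) if (key_id %in% ids) hit else miss
}

# Deterministic tiny tokenized dataset where positives carry a reserved
# token ("GGGGGG") absent from negatives: linearly separable.
separable_toy <- function(n_per_class = 40, seed = 1) {
  cached(sprintf("toy_%d_%d", n_per_class, seed), {
    promtok:::with_seed(seed, {
      mkseq <- function(pos) {
        toks <- replicate(10, paste(sample(c("A", "C", "T"), 6,
                                           replace = TRUE), collapse = ""))
        if (pos) toks[sample(10, 1)] <- "GGGGGG"
        paste0(paste(toks, collapse = ""), "A")  # 61 nt: odd window length
      }
      seqs <- c(vapply(seq_len(n_per_class), function(i) mkseq(TRUE), ""),
                vapply(seq_len(n_per_class), function(i) mkseq(FALSE), ""))
      vocab <- build_kmer_vocab(seqs, 6, FALSE)
      win <- data.frame(
        id = sprintf("t%04d", seq_along(seqs)),
        organism = "toy", sequence = seqs,
        label = rep(c("positive", "negative"), each = n_per_class),
        source = rep(c("epd_like", "fragment_negative"), each = n_per_class),
        paired_positive_id = c(rep(NA_character_, n_per_class),
                               sprintf("t%04d", seq_len(n_per_class))),
        mask = NA_character_, stringsAsFactors = FALSE)
      list(windows = win, vocab = vocab,
           tokenized = promtok:::tokenize_windows(win, vocab))
    })
  })
}
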