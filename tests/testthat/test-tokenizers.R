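s601 <- function() substr(strrep("ACGT", 151), 1, 601)

test_that("k-mer vocabularies are exhaustive plus observed ambiguous tokens", {
  v <- build_kmer_vocab(character(0), 6, FALSE)
  expect_equal(length(v$content), 4096)
  expect_equal(vocab_size(v), 4096 + 5)
  v1 <- build_kmer_vocab(character(0), 1, FALSE)
  expect_equal(sort(v1$content), c("A", "C", "G", "T"))
  # an N-containing 6-mer aligned to a token boundary enters the vocabulary
  corpus <- paste0("NNNNNN", strrep("A", 12))
  vN <- build_kmer_vocab(corpus, 6, FALSE)
  expect_true("NNNNNN" %in% vN$content)
  expect_equal(length(vN$content), 4097)
})

test_that("token counts and spans follow the scheme definitions", {
  v <- build_kmer_vocab(s601(), 6, FALSE)
  tz <- encode(s601(), v)
  expect_length(tz$ids, 100)                 # floor(601 / 6)
  expect_equal(tz$remainder, substr(s601(), 601, 601))
  expect_equal(tz$start, (0:99) * 6)
  expect_equal(tz$end, (0:99) * 6 + 6)
  vo <- build_kmer_vocab(s601(), 6, TRUE)
  tzo <- encode(s601(), vo)
  expect_length(tzo$ids, 596)                # L - k + 1
  # adjacent overlapping tokens share k - 1 characters
  sh <- vapply(seq_len(595), function(i) {
    substr(tzo$tokens[i], 2, 6) == substr(tzo$tokens[i + 1], 1, 5)
  }, TRUE)
  expect_true(all(sh))
  vc <- dna_vocab(c("A", "C", "G", "T", "N"), scheme = "char")
  tzc <- encode(s601(), vc)
  expect_length(tzc$ids, 601)
})

test_that("detokenization reproduces the input for partition schemes", {
  set.seed(7)
  seqs <- random_dna(5, 601)
  v <- build_kmer_vocab(seqs, 6, FALSE)
  for (s in seqs) expect_equal(detokenize(encode(s, v)), s)
  bp <- train_bpe(seqs, target_vocab = 40)
  for (s in seqs) {
    expect_equal(detokenize(encode(s, bp$vocab, merges = bp$merges)), s)
  }
  wp <- train_wpc(seqs, min_pair_count = 3, target_vocab = 40)
  for (s in seqs) expect_equal(detokenize(encode(s, wp$vocab)), s)
  vc <- dna_vocab(c("A", "C", "G", "T", "N"), scheme = "char")
  for (s in seqs) expect_equal(detokenize(encode(s, vc)), s)
})

test_that("BPE merges the most frequent pair first", {
  bp <- train_bpe(rep("ACACACACAC", 100), target_vocab = 5)
  expect_equal(bp$merges$left[1], "A")
  expect_equal(bp$merges$right[1], "C")
  expect_equal(bp$merges$merged[1], "AC")
  # no merges possible when every adjacent pair is unique
  none <- train_bpe("ACGT", target_vocab = 100)
  expect_equal(nrow(none$merges), 0)
  expect_setequal(none$vocab$content, c("A", "C", "G", "T"))
  expect_error(train_bpe("ACGT", target_vocab = 2),
               class = "promtok_config_error")
})

test_that("BPE reaches exactly the requested vocabulary size on rich corpora", {
  corpus <- random_dna(30, 400, seed = 12)
  target <- 60
  bp <- train_bpe(corpus, target_vocab = target)
  expect_equal(length(bp$vocab$content), target)
  # merge ranks are well-formed: merged string = left + right
  expect_equal(bp$merges$merged, paste0(bp$merges$left, bp$merges$right))
})

test_that("BPE pair frequencies never increase along merge rank", {
  corpus <- random_dna(20, 300, seed = 3)
  bp <- train_bpe(corpus, target_vocab = 30)
  # replay training on an independent per-sequence token representation and
  # recount each selected pair's raw adjacency frequency at selection time
  apply_merge <- function(v, l, r, m) {
    ps <- which(v[-length(v)] == l & v[-1] == r)
    if (l == r && length(ps) > 1) {
      keep <- logical(length(ps)); last <- -2L
      for (j in seq_along(ps)) {
        if (ps[j] > last + 1L) { keep[j] <- TRUE; last <- ps[j] }
      }
      ps <- ps[keep]
    }
    if (length(ps) == 0) return(v)
    v[ps] <- m
    v[-(ps + 1L)]
  }
  raw_count <- function(toks, l, r) {
    sum(vapply(toks, function(v) {
      if (length(v) < 2) return(0L)
      length(which(v[-length(v)] == l & v[-1] == r))
    }, 0L))
  }
  toks <- lapply(corpus, function(s) strsplit(s, "")[[1]])
  counts <- numeric(nrow(bp$merges))
  for (r in seq_len(nrow(bp$merges))) {
    counts[r] <- raw_count(toks, bp$merges$left[r], bp$merges$right[r])
    toks <- lapply(toks, apply_merge, bp$merges$left[r], bp$merges$right[r],
                   bp$merges$merged[r])
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts >= 2))
})

test_that("WordPiece scores likelihood gain, not raw frequency", {
  # counts: (A,B)-like pair with high frequency but low score vs a rare
  # exclusive pair. DNA alphabet stand-ins: AC frequent/diluted, GT exclusive.
  corpus <- c(rep("AC", 10), rep("A", 10), rep("GT", 5))
  wp <- train_wpc(corpus, min_pair_count = 5, target_vocab = 6)
  # score(G,T) = 5 / (5 * 5) = 0.2 > score(A,C) = 10 / (20 * 10) = 0.05
  expect_equal(wp$merges$merged[1], "GT")
  # a threshold above every pair count stops training immediately
  none <- train_wpc(corpus, min_pair_count = 100)
  expect_equal(nrow(none$merges), 0)
})

test_that("subword training is deterministic and N-free", {
  ch <- promtok:::seq_to_chars(random_dna(1, 2000, seed = 9))
  ch[sample(2000, 30)] <- "N"
  corpus <- substring(promtok:::chars_to_seq(ch), seq(1, 1801, 200),
                      seq(200, 2000, 200))
  a <- train_bpe(corpus, 30); b <- train_bpe(corpus, 30)
  expect_identical(a$merges, b$merges)
  expect_identical(a$vocab$tokens, b$vocab$tokens)
  # no multi-character content token contains N
  multi <- a$vocab$content[nchar(a$vocab$content) > 1]
  expect_false(any(grepl("N", multi)))
  w <- train_wpc(corpus, min_pair_count = 2, target_vocab = 30)
  multi_w <- w$vocab$content[nchar(w$vocab$content) > 1]
  expect_false(any(grepl("N", multi_w)))
})

test_that("WordPiece inference is greedy longest-prefix with UNK fallback", {
  v <- dna_vocab(c("A", "C", "G", "T", "ACG"), scheme = "wpc")
  tz <- encode("ACGT", v)
  expect_equal(tz$tokens, c("ACG", "T"))
  expect_equal(tz$start, c(0, 3))
  expect_equal(tz$end, c(3, 4))
  # character missing from the vocabulary becomes UNK over one position
  v2 <- dna_vocab(c("A", "C", "G", "T"), scheme = "wpc")
  tz2 <- encode("ANA", v2)
  expect_equal(tz2$tokens[2], "[UNK]")
  expect_equal(tz2$ids[2], unname(v2$ids[["[UNK]"]]))
})

test_that("unknown k-mers map to UNK at encoding time", {
  v <- build_kmer_vocab(character(0), 6, FALSE)  # no ambiguous tokens seen
  tz <- encode(paste0("NNNNNN", strrep("A", 6)), v)
  expect_equal(tz$tokens[1], "NNNNNN")
  expect_equal(tz$ids[1], unname(v$ids[["[UNK]"]]))
  expect_error(encode("ACGT", v, scheme = "bogus"),
               class = "promtok_config_error")
})

test_that("vocabularies and merges round-trip through text files", {
  corpus <- random_dna(10, 300, seed = 5)
  bp <- train_bpe(corpus, 25)
  dir <- withr::local_tempdir()
  save_vocab(bp$vocab, dir, merges = bp$merges)
  back <- load_vocab(dir)
  expect_identical(back$vocab$tokens, bp$vocab$tokens)
  expect_equal(back$merges$left, bp$merges$left)
  expect_equal(back$merges$right, bp$merges$right)
  # re-encoding after reload equals the in-memory encoding
  s <- corpus[1]
  expect_identical(encode(s, back$vocab, merges = back$merges)$ids,
                   encode(s, bp$vocab, merges = bp$merges)$ids)
  # a 4096-token k-mer vocabulary survives a round trip unchanged
  kv <- build_kmer_vocab(corpus, 6, FALSE)
  d2 <- withr::local_tempdir()
  save_vocab(kv, d2)
  expect_identical(load_vocab(d2)$vocab$tokens, kv$tokens)
  # merges referencing unknown tokens are rejected
  writeLines("QQ ZZ", file.path(d2, "merges.txt"))
  expect_error(load_vocab(d2), class = "promtok_parse_error")
})
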