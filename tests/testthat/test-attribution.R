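make_preds <- function(ids, prob, label) {
  structure(data.frame(id = ids, prob = prob, label = label,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

test_that("top-confident selection ranks by probability with id tie-breaks", {
  preds <- make_preds(sprintf("w%02d", 1:8),
                      c(0.9, 0.8, 0.8, 0.1, 0.2, 0.3, 0.95, 0.05),
                      rep(c("positive", "negative"), each = 4))
  expect_equal(select_top_confident(preds, "positive", 3),
               c("w01", "w02", "w03"))
  # negatives: most confidently non-promoter = lowest probability first
  expect_equal(select_top_confident(preds, "negative", 2), c("w08", "w05"))
  expect_warning(all_ids <- select_top_confident(preds, "positive", 10),
                 "only 4")
  expect_length(all_ids, 4)
  empty <- make_preds("a", 0.5, "positive")
  expect_error(select_top_confident(empty, "negative"),
               class = "promtok_data_error")
})

# A tokenized stand-in: 10 tokens of 6 nt over a 60-nt window.
stub_tz <- function(ids = 6:15) {
  promtok:::new_tokenized(tokens = sprintf("TOK%02d", seq_along(ids)),
                          ids = as.integer(ids),
                          start = (seq_along(ids) - 1L) * 6L,
                          end = seq_along(ids) * 6L,
                          scheme = "kmer_nonoverlap", window_id = "w1")
}

test_that("occlusion attribution isolates a decisive token", {
  tz <- stub_tz()
  const <- function(ids) 0.7
  a0 <- token_attribution(const, tz)
  expect_equal(a0$scores, rep(0, 10))
  keyed <- stub_keyed_model(key_id = 9L)
  a1 <- token_attribution(keyed, tz)
  expect_equal(which.max(abs(a1$scores)), which(tz$ids == 9L))
  expect_true(all(a1$scores >= -1 & a1$scores <= 1))
})

test_that("Shapley and occlusion agree on the decisive token's argmax", {
  tz <- stub_tz()
  keyed <- stub_keyed_model(key_id = 12L)
  occ <- token_attribution(keyed, tz, method = "occlusion")
  shap <- token_attribution(keyed, tz, method = "shapley", n_samples = 8,
                            seed = 3)
  expect_equal(which.max(shap$scores), which.max(occ$scores))
  # for a single decisive token the Shapley value concentrates on it
  expect_equal(which(abs(shap$scores) > 1e-9), which(tz$ids == 12L))
})

test_that("token scores broadcast across their nucleotide spans", {
  tz <- stub_tz()
  att <- structure(list(scores = seq(0.1, 1, 0.1), method = "occlusion",
                        tz = tz), class = "token_attribution")
  prof <- positional_profile(list(att), window_length = 61)
  # positions 0-5 carry token 1's score
  expect_equal(prof$values[1:6], rep(0.1, 6))
  expect_equal(prof$values[7:12], rep(0.2, 6))
  # uncovered tail position is missing, not zero
  expect_true(is.na(prof$values[61]))
})

test_that("overlapping spans average the covering tokens' scores", {
  # two tokens covering [0,6) and [3,9): positions 3-5 see their mean
  tz <- promtok:::new_tokenized(tokens = c("t1", "t2"), ids = c(6L, 7L),
                                start = c(0L, 3L), end = c(6L, 9L),
                                scheme = "kmer_overlap", window_id = "w1")
  att <- structure(list(scores = c(0.2, 0.6), method = "occlusion", tz = tz),
                   class = "token_attribution")
  prof <- positional_profile(list(att), window_length = 9)
  expect_equal(prof$values, c(0.2, 0.2, 0.2, 0.4, 0.4, 0.4, 0.6, 0.6, 0.6))
  # brute-force per-position oracle on a random overlapping tokenization
  set.seed(5)
  k <- 4; L <- 20
  n_tok <- L - k + 1
  tz2 <- promtok:::new_tokenized(tokens = sprintf("t%d", 1:n_tok),
                                 ids = seq_len(n_tok) + 5L,
                                 start = 0:(n_tok - 1), end = k:(L),
                                 scheme = "kmer_overlap", window_id = "w2")
  sc <- rnorm(n_tok)
  att2 <- structure(list(scores = sc, method = "occlusion", tz = tz2),
                    class = "token_attribution")
  prof2 <- positional_profile(list(att2), window_length = L)
  oracle <- vapply(seq_len(L), function(p) {
    covering <- which(tz2$start < p & tz2$end >= p)
    mean(sc[covering])
  }, 1)
  expect_equal(prof2$values, oracle)
})

test_that("a multi-window profile is the mean of per-window vectors", {
  set.seed(6)
  atts <- lapply(1:4, function(i) {
    structure(list(scores = rnorm(10), method = "occlusion", tz = stub_tz()),
              class = "token_attribution")
  })
  prof <- positional_profile(atts, window_length = 61)
  per_window <- sapply(atts, promtok:::broadcast_attribution,
                       window_length = 61)
  expect_equal(prof$values[1:60], rowMeans(per_window)[1:60])
  expect_equal(prof$n_sequences, 4)
  # span outside the window is a contract error
  bad <- atts[[1]]; bad$tz$end[10] <- 70
  expect_error(positional_profile(list(bad), window_length = 61),
               class = "promtok_contract_error")
})

test_that("peak_report converts indices to TSS offsets", {
  vals <- rep(0, 601); vals[391] <- 1  # 0-based index 390
  prof <- structure(list(values = vals, n_sequences = 1,
                         class_tag = "positive", halfwidth = 300L),
                    class = "positional_profile")
  pk <- peak_report(prof, 1)
  expect_equal(pk$index, 390)
  expect_equal(pk$offset, 90)
  expect_false(attr(pk, "degenerate"))
  flat <- structure(list(values = rep(0.3, 601), n_sequences = 1,
                         class_tag = "positive", halfwidth = 300L),
                    class = "positional_profile")
  pk2 <- peak_report(flat, 3)
  expect_true(attr(pk2, "degenerate"))
  expect_equal(pk2$index, 0:2)
})

test_that("positional composition counts bases correctly", {
  win <- windows_from_seqs(c(strrep("A", 601),
                             paste0(strrep("A", 300), "C", strrep("A", 300)),
                             strrep("A", 601)))
  comp_center <- composition_at_position(win, 300)
  expect_equal(sum(comp_center), 1)
  expect_equal(unname(comp_center["C"]), 1 / 3)
  expect_equal(unname(comp_center["A"]), 2 / 3)
  comp0 <- composition_at_position(win, 0)
  expect_equal(unname(comp0["A"]), 1)
})

test_that("top_tokens ranks decisively and stably", {
  tz <- stub_tz()
  keyed <- stub_keyed_model(key_id = 8L)
  atts <- lapply(1:3, function(i) token_attribution(keyed, tz))
  rep_ <- top_tokens(atts, n_sequences = 3, n_tokens = 2)
  for (pw in rep_$per_window) {
    expect_equal(pw$token[1], tz$tokens[which(tz$ids == 8L)])
  }
  expect_equal(unname(rep_$frequency[tz$tokens[which(tz$ids == 8L)]]), 3)
  # n_tokens = 0 gives empty lists
  rep0 <- top_tokens(atts, n_sequences = 2, n_tokens = 0)
  expect_true(all(vapply(rep0$per_window, nrow, 1L) == 0))
  # tie-break: equal scores ranked by span start ascending
  att_tie <- structure(list(scores = rep(0.5, 10), method = "occlusion",
                            tz = tz), class = "token_attribution")
  r <- top_tokens(list(att_tie), 1, 3)
  expect_equal(r$per_window[[1]]$start, c(0, 6, 12))
})
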