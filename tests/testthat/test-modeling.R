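tiny_encoder <- function(pooling = "mean") {
  encoder_config(layers = 1, hidden = 16, heads = 2, max_tokens = 16,
                 pooling = pooling)
}

test_that("curriculum schedules follow the flat and evolutionary recipes", {
  ph <- generate_phylogeny(preset = "epd8")
  orgs <- ph$organisms
  flat <- make_schedule("flat", orgs, epochs = 10)
  expect_length(flat$epochs, 10)
  expect_true(all(vapply(flat$epochs, function(e) length(e) == 8, TRUE)))
  evo <- make_schedule("evolutionary", orgs, ph, target = "hsapiens",
                       epochs = 10, switch_epoch = 5)
  for (e in 1:5) expect_setequal(evo$epochs[[e]], orgs)
  for (e in 6:10) {
    expect_setequal(evo$epochs[[e]],
                    c("hsapiens", "mmulatta", "mmusculus", "rnorvegicus"))
  }
  # switch at the last epoch degenerates to the flat schedule
  evo_deg <- make_schedule("evolutionary", orgs, ph, target = "hsapiens",
                           epochs = 10, switch_epoch = 10)
  expect_identical(evo_deg$epochs, flat$epochs)
  expect_error(make_schedule("flat", orgs, epochs = 0),
               class = "promtok_config_error")
})

test_that("pretraining refuses negative windows and masks near the configured rate", {
  toy <- separable_toy()
  ec <- tiny_encoder()
  tc <- train_config(batch_size = 8, lr = 3e-3, epochs = 2, seed = 1)
  sched <- make_schedule("flat", "toy", epochs = 2)
  pos_tok <- toy$tokenized[1:20]
  mixed <- toy$tokenized[c(1:10, 41:45)]  # contains negatives
  expect_error(pretrain_mlm(ec, list(toy = mixed), sched, tc, toy$vocab),
               class = "promtok_contract_error")
  out <- pretrain_mlm(ec, list(toy = pos_tok), sched, tc, toy$vocab)
  expect_length(out$loss_trace, 2)
  expect_true(all(abs(out$mask_fraction - 0.15) < 0.01 + 1 / 10))
  # with 10-token sequences the ensure-one rule inflates the rate; check the
  # empirical fraction directly against its expectation
  expect_true(all(out$mask_fraction > 0.10 & out$mask_fraction < 0.30))
})

test_that("curriculum batches contain only scheduled organisms", {
  toy <- separable_toy()
  ec <- tiny_encoder()
  # fake two organisms by splitting the positive pool
  corpora <- list(orgA = toy$tokenized[1:12], orgB = toy$tokenized[13:24])
  d <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("orgA", "orgB"),
                                                  c("orgA", "orgB")))
  ph <- promtok:::new_phylo_table(c("orgA", "orgB"), d)
  sched <- make_schedule("evolutionary", c("orgA", "orgB"), ph,
                         target = "orgA", epochs = 4, switch_epoch = 2, m = 1)
  tc <- train_config(batch_size = 4, lr = 3e-3, epochs = 4, seed = 2)
  out <- pretrain_mlm(ec, corpora, sched, tc, toy$vocab)
  for (e in 3:4) {
    orgs_seen <- unique(unlist(out$batch_log[[e]]))
    expect_equal(orgs_seen, "orgA")
  }
  expect_setequal(unique(unlist(out$batch_log[[1]])), c("orgA", "orgB"))
})

test_that("pretraining loss traces are seed-reproducible", {
  toy <- separable_toy()
  ec <- tiny_encoder()
  tc <- train_config(batch_size = 8, lr = 3e-3, epochs = 2, seed = 9)
  sched <- make_schedule("flat", "toy", epochs = 2)
  a <- pretrain_mlm(ec, list(toy = toy$tokenized[1:16]), sched, tc, toy$vocab)
  b <- pretrain_mlm(ec, list(toy = toy$tokenized[1:16]), sched, tc, toy$vocab)
  expect_identical(a$loss_trace, b$loss_trace)
  expect_identical(a$params, b$params)
})

test_that("fine-tuning separates a toy dataset perfectly", {
  toy <- separable_toy()
  tz <- toy$tokenized
  tr <- c(1:30, 41:70); va <- c(31:34, 71:74); te <- c(35:40, 75:80)
  tc <- train_config(batch_size = 8, lr = 3e-3, epochs = 20, seed = 5,
                     patience = 5)
  cls <- finetune_classifier(NULL, tz[tr], tz[va], tiny_encoder(), tc,
                             toy$vocab)
  preds <- predict(cls, tz[te])
  expect_true(all(preds$prob >= 0 & preds$prob <= 1))
  expect_equal(auc(preds$prob, preds$label), 1.0)
  # fixed seed reproduces the whole validation curve
  cls2 <- finetune_classifier(NULL, tz[tr], tz[va], tiny_encoder(), tc,
                              toy$vocab)
  expect_identical(cls$val_curve, cls2$val_curve)
  # single-class training data is rejected
  expect_error(finetune_classifier(NULL, tz[1:10], tz[va], tiny_encoder(),
                                   tc, toy$vocab),
               class = "promtok_data_error")
})

test_that("prediction is deterministic, bounded and near 0.5 untrained", {
  toy <- separable_toy()
  ec <- tiny_encoder()
  params <- promtok:::init_encoder(ec, vocab_size(toy$vocab), seed = 3)
  cls <- structure(list(params = params, encoder_cfg = ec,
                        scheme = toy$vocab$scheme,
                        vocab_hash = promtok:::config_hash(toy$vocab$tokens),
                        vocab_size = vocab_size(toy$vocab)),
                   class = "promoter_classifier")
  preds1 <- predict(cls, toy$tokenized[1:10])
  preds2 <- predict(cls, toy$tokenized[1:10])
  expect_identical(preds1$prob, preds2$prob)
  expect_lt(abs(mean(preds1$prob) - 0.5), 0.2)
  # scheme mismatch is rejected
  vc <- dna_vocab(c("A", "C", "G", "T", "N"), scheme = "char")
  tzc <- list(encode(toy$windows$sequence[1], vc, window_id = "x",
                     label = "positive"))
  expect_error(predict(cls, tzc), class = "promtok_config_error")
})

test_that("ablation curves use balanced nested subsamples", {
  toy <- separable_toy()
  tz <- toy$tokenized
  ec <- tiny_encoder()
  tc <- train_config(batch_size = 8, lr = 3e-3, epochs = 2, seed = 4)
  params <- promtok:::init_encoder(ec, vocab_size(toy$vocab), seed = 8)
  tab <- ablation_curve(list(flat = params, evolutionary = params),
                        pool_tok = tz[c(1:30, 41:70)],
                        val_tok = tz[c(31:34, 71:74)],
                        test_tok = tz[c(35:40, 75:80)],
                        sizes = c(8, 16), encoder_cfg = ec, train_cfg = tc,
                        vocab = toy$vocab, replicates = 2)
  expect_equal(nrow(tab), 2 * 2 * 2)  # strategies x sizes x replicates
  expect_setequal(tab$strategy, c("flat", "evolutionary"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  # pool too small for the largest size
  expect_error(
    ablation_curve(list(flat = params), tz[c(1:5, 41:45)], tz[c(31, 71)],
                   tz[c(35, 75)], sizes = 40, ec, tc, toy$vocab),
    class = "promtok_data_error")
})

test_that("MLM pretraining lowers the small-n fine-tuning validation loss", {
  # Synthetic promoters with the planted downstream motif; fragment
  # negatives; n = 32 fine-tuning windows. Seed-averaged over 5 seeds the
  # pretrained start should do no worse than from-scratch.
  ph <- generate_phylogeny(preset = "epd8")
  cfg <- sim_config(n_organisms = 1, promoters_per_organism = 100,
                    tss_spacing = 1800, downstream_strength = 1.0, seed = 55)
  gs <- synthesize_genome_set(cfg, ph)
  pos <- extract_positive_windows(gs)
  neg <- build_negative_set(pos, genomes = gs, strategy = "fragment",
                            seed = 55)
  win <- promtok:::rbind_windows(pos, neg)
  v <- build_kmer_vocab(win$sequence, 6, FALSE)
  tzp <- promtok:::tokenize_windows(pos, v)
  tz <- promtok:::tokenize_windows(win, v)
  lab <- win$label
  ip <- which(lab == "positive"); ineg <- which(lab == "negative")
  ec <- encoder_config(layers = 1, hidden = 32, heads = 2, max_tokens = 104)
  sched <- make_schedule("flat", "hsapiens", epochs = 8)
  pre <- pretrain_mlm(ec, list(hsapiens = tzp[1:60]), sched,
                      train_config(epochs = 8, lr = 1e-2, seed = 1), v)
  # pretraining itself must learn: the MLM loss decreases
  expect_lt(pre$loss_trace[8], pre$loss_trace[1])
  res <- vapply(1:5, function(s) {
    tr <- c(ip[61:76], ineg[61:76]); va <- c(ip[77:88], ineg[77:88])
    tc <- train_config(batch_size = 8, lr = 1e-2, epochs = 20, seed = s,
                       patience = 20)
    c1 <- finetune_classifier(pre$params, tz[tr], tz[va], ec, tc, v)
    c0 <- finetune_classifier(NULL, tz[tr], tz[va], ec, tc, v)
    c(min(c1$val_curve), min(c0$val_curve))
  }, numeric(2))
  expect_lt(mean(res[1, ]), mean(res[2, ]))
})
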