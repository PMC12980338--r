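#' Experiment orchestration
#'
#' `run_matrix()` reproduces the study structure at configurable scale: one
#' synthetic corpus, both negative strategies, one cluster-respecting split,
#' one MLM pretraining per tokenizer (on positive training windows only),
#' then one fine-tuned classifier per tokenizer x organism x negative
#' strategy, each evaluated by AUC on the held-out test set. Completed jobs
#' are cached on disk (hash-keyed) so reruns are idempotent.
#'
#' @name orchestrator
NULL

#' Experiment configuration
#'
#' @param sim a [sim_config()].
#' @param phylo_preset phylogeny preset name (default `"epd8"`).
#' @param tokenizers tokenization schemes to compare.
#' @param negative_strategies negative-set strategies to run.
#' @param target_vocab subword vocabulary size for BPE/WPC.
#' @param encoder an [encoder_config()].
#' @param pretrain,finetune [train_config()]s for the two phases.
#' @param fractions split fractions (train, validation, test).
#' @param out_dir directory for job caches and result tables (`NULL`
#'   disables caching).
#' @param seed master seed.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              phylo_preset = "epd8",
                              tokenizers = c("kmer_nonoverlap", "kmer_overlap",
                                             "bpe", "wpc"),
                              negative_strategies = c("shuffled", "fragment"),
                              target_vocab = 64,
                              encoder = encoder_config(),
                              pretrain = train_config(epochs = 2),
                              finetune = train_config(epochs = 3),
                              fractions = c(0.65, 0.15, 0.20),
                              out_dir = NULL,
                              seed = 1) {
  if (length(tokenizers) == 0 || length(negative_strategies) == 0) {
    stop_promtok("need at least one tokenizer and one negative strategy",
                 "promtok_config_error")
  }
  structure(list(sim = sim, phylo_preset = phylo_preset,
                 tokenizers = tokenizers,
                 negative_strategies = negative_strategies,
                 target_vocab = target_vocab, encoder = encoder,
                 pretrain = pretrain, finetune = finetune,
                 fractions = fractions, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Build vocab (+ merges) for a scheme from training-positive sequences.
train_tokenizer <- function(scheme, corpus, target_vocab) {
  switch(scheme,
    kmer_nonoverlap = list(vocab = build_kmer_vocab(corpus, 6, FALSE),
                           merges = NULL),
    kmer_overlap = list(vocab = build_kmer_vocab(corpus, 6, TRUE),
                        merges = NULL),
    bpe = train_bpe(corpus, target_vocab),
    wpc = train_wpc(corpus, target_vocab = target_vocab),
    char = list(vocab = dna_vocab(c(DNA_BASES, "N"), scheme = "char"),
                merges = NULL),
    stop_promtok(sprintf("unknown tokenizer '%s'", scheme),
                 "promtok_config_error"))
}

.job_cache_path <- function(out_dir, key) {
  file.path(out_dir, "jobs", paste0(key, ".json"))
}

#' Run the tokenizer x organism x negative-strategy matrix
#'
#' @param config an [experiment_config()].
#' @return list: `results` (data frame: organism, tokenizer,
#'   negative_strategy, pretrain_strategy, n_finetune, auc, seed, runtime),
#'   `predictions` (per-job `prediction_set`s keyed
#'   `tokenizer/organism/strategy`), `split`, `windows`, and `n_jobs_run`
#'   (zero on a fully cached rerun).
#' @export
run_matrix <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  phylo <- generate_phylogeny(preset = config$phylo_preset)
  gs <- synthesize_genome_set(config$sim, phylo)
  positives <- extract_positive_windows(gs)
  negatives <- list()
  for (strat in config$negative_strategies) {
    negatives[[strat]] <- build_negative_set(
      positives, genomes = gs, strategy = strat, seed = config$seed)
  }
  clusters <- greedy_cluster(setNames(positives$sequence, positives$id))
  assignment <- accumulate_split(clusters, config$fractions)
  organisms <- unique(positives$organism)

  part_of <- function(ids, asg) asg$partition[match(ids, asg$id)]
  if (!is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, "jobs"), showWarnings = FALSE,
               recursive = TRUE)
  }
  results <- list(); predictions <- list(); n_run <- 0L
  train_pos_seq <- positives$sequence[part_of(positives$id, assignment) == "train"]

  for (tok in config$tokenizers) {
    tk <- train_tokenizer(tok, train_pos_seq, config$target_vocab)
    # pretrain once per tokenizer on pooled positive training windows
    pos_train <- positives[part_of(positives$id, assignment) == "train", ]
    corpora <- lapply(split(pos_train, pos_train$organism), tokenize_windows,
                      vocab = tk$vocab, merges = tk$merges)
    sched <- make_schedule("flat", organisms, epochs = config$pretrain$epochs)
    pre <- pretrain_mlm(config$encoder, corpora, sched, config$pretrain,
                        tk$vocab)
    for (strat in config$negative_strategies) {
      all_win <- rbind_windows(positives, negatives[[strat]])
      asg <- propagate_pairs(assignment, all_win)
      for (org in organisms) {
        key <- config_hash(list(tok, strat, org, config$seed,
                                config$encoder, config$finetune))
        cache <- if (!is.null(config$out_dir)) {
          .job_cache_path(config$out_dir, key)
        } else NULL
        if (!is.null(cache) && file.exists(cache)) {
          row <- as.data.frame(jsonlite::read_json(cache, simplifyVector = TRUE))
        } else {
          t0 <- proc.time()[["elapsed"]]
          ow <- all_win[all_win$organism == org, ]
          parts <- part_of(ow$id, asg)
          tz_of <- function(sel) tokenize_windows(ow[sel, , drop = FALSE],
                                                  tk$vocab, tk$merges)
          cls <- finetune_classifier(pre$params,
                                     tz_of(parts == "train"),
                                     tz_of(parts == "validation"),
                                     config$encoder, config$finetune, tk$vocab)
          preds <- predict(cls, tz_of(parts == "test"))
          predictions[[paste(tok, org, strat, sep = "/")]] <- preds
          row <- data.frame(organism = org, tokenizer = tok,
                            negative_strategy = strat,
                            pretrain_strategy = "flat",
                            n_finetune = sum(parts == "train"),
                            auc = auc(preds$prob, preds$label),
                            seed = config$seed,
                            runtime = proc.time()[["elapsed"]] - t0,
                            stringsAsFactors = FALSE)
          n_run <- n_run + 1L
          if (!is.null(cache)) {
            jsonlite::write_json(row, cache, auto_unbox = TRUE, digits = NA)
            jsonlite::write_json(preds, paste0(cache, ".preds"),
                                 auto_unbox = TRUE, digits = NA)
          }
        }
        if (is.null(predictions[[paste(tok, org, strat, sep = "/")]]) &&
            !is.null(cache) && file.exists(paste0(cache, ".preds"))) {
          pr <- as.data.frame(jsonlite::read_json(paste0(cache, ".preds"),
                                                  simplifyVector = TRUE))
          class(pr) <- c("prediction_set", "data.frame")
          predictions[[paste(tok, org, strat, sep = "/")]] <- pr
        }
        results[[key]] <- row
      }
    }
  }
  res <- do.call(rbind, unname(results))
  if (!is.null(config$out_dir)) {
    write.table(res, file.path(config$out_dir, "results.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = res, predictions = predictions, split = assignment,
       windows = c(list(positives = positives), negatives),
       n_jobs_run = n_run)
}

# rbind two window tables that may differ in optional columns
rbind_windows <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  out <- rbind(as.data.frame(a)[cols], as.data.frame(b)[cols])
  rownames(out) <- NULL
  validate_windows(out)
}

#' Pairwise tokenizer comparisons with FDR control
#'
#' Runs the DeLong test for every tokenizer pair within each organism and
#' negative strategy, then adjusts all p-values in one Benjamini-Hochberg
#' family (global adjustment; set `family = "per_organism"` to adjust within
#' organisms).
#'
#' @param run a [run_matrix()] result.
#' @param alpha FDR threshold for the significance flag.
#' @param family `"global"` or `"per_organism"`.
#' @return data frame: organism, strategy, method_a, method_b, auc_a, auc_b,
#'   z, p, p_adj, significant.
#' @export
compare_methods <- function(run, alpha = 0.05, family = c("global", "per_organism")) {
  family <- match.arg(family)
  keys <- strsplit(names(run$predictions), "/", fixed = TRUE)
  info <- data.frame(tokenizer = vapply(keys, `[`, "", 1),
                     organism = vapply(keys, `[`, "", 2),
                     strategy = vapply(keys, `[`, "", 3),
                     stringsAsFactors = FALSE)
  rows <- list()
  for (org in unique(info$organism)) {
    for (strat in unique(info$strategy)) {
      toks <- sort(info$tokenizer[info$organism == org & info$strategy == strat])
      if (length(toks) < 2) next
      pairs <- utils::combn(toks, 2)
      for (cp in seq_len(ncol(pairs))) {
        a <- run$predictions[[paste(pairs[1, cp], org, strat, sep = "/")]]
        b <- run$predictions[[paste(pairs[2, cp], org, strat, sep = "/")]]
        if (!identical(a$id, b$id)) {
          stop_promtok("prediction sets cover different records",
                       "promtok_pairing_error")
        }
        dl <- delong_test(a$prob, b$prob, a$label)
        rows[[length(rows) + 1L]] <- data.frame(
          organism = org, strategy = strat,
          method_a = pairs[1, cp], method_b = pairs[2, cp],
          auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z, p = dl$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (family == "global") bh_fdr(out$p) else {
    stats::ave(out$p, out$organism, FUN = bh_fdr)
  }
  out$significant <- out$p_adj < alpha
  out
}

#' Cross-species evaluation against an external organism
#'
#' Evaluates per-organism classifiers on an external test set (positives
#' filtered through [filter_external()], plus paired negatives), sorts by
#' divergence time from the external organism, and appends the Pearson
#' correlation between distance and AUC.
#'
#' @param models named list: training organism -> `promoter_classifier`
#'   (one shared tokenizer).
#' @param external_pos filtered external positives (must come from
#'   [filter_external()]).
#' @param external_neg negatives paired to the external positives.
#' @param phylo a `phylo_table` covering all organisms.
#' @param target external organism name.
#' @param vocab,merges the shared tokenizer.
#' @return list: `table` (organism, distance, auc, sorted by distance) and
#'   `pearson` (list r, p, n).
#' @export
cross_species_eval <- function(models, external_pos, external_neg, phylo,
                               target, vocab, merges = NULL) {
  if (!isTRUE(attr(external_pos, "filtered"))) {
    stop_promtok("external positives must pass filter_external() first",
                 "promtok_contract_error")
  }
  ext <- rbind_windows(external_pos, external_neg)
  tz <- tokenize_windows(ext, vocab, merges)
  rows <- lapply(names(models), function(org) {
    preds <- predict(models[[org]], tz)
    data.frame(organism = org,
               distance = phylo$distance[org, target],
               auc = auc(preds$prob, preds$label),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$distance, tab$organism), ]
  rownames(tab) <- NULL
  pe <- if (nrow(tab) >= 3) pearson_test(tab$distance, tab$auc) else NULL
  list(table = tab, pearson = pe)
}
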