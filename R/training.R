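#' Pretraining curricula and classifier training
#'
#' Pretraining is masked-language modeling on positive (promoter) windows
#' only. Two curricula are supported: `flat` draws every epoch's batches
#' from all organisms; `evolutionary` uses all organisms for the first
#' `switch_epoch` epochs and only the `m = 4` species closest to the target
#' organism afterwards. An epoch is one pass over the union of the scheduled
#' organisms' sequences, so the flat curriculum sees roughly twice as many
#' observations per late epoch as the evolutionary one.
#'
#' @name training
NULL

#' Build a pretraining curriculum schedule
#'
#' @param strategy `"flat"` or `"evolutionary"`.
#' @param organisms organisms available for pretraining.
#' @param phylo a `phylo_table` (evolutionary strategy).
#' @param target target organism for the evolutionary curriculum.
#' @param epochs total pretraining epochs (default 10).
#' @param switch_epoch last epoch of the all-organisms phase (default 5,
#'   capped at `epochs`).
#' @param m late-phase subset size (default 4).
#' @return a `curriculum_schedule`: list with `epochs` (per-epoch organism
#'   character vectors) and `strategy`.
#' @export
make_schedule <- function(strategy = c("flat", "evolutionary"), organisms,
                          phylo = NULL, target = NULL, epochs = 10,
                          switch_epoch = min(5, epochs), m = 4) {
  strategy <- match.arg(strategy)
  if (epochs < 1) stop_promtok("epochs must be positive", "promtok_config_error")
  if (switch_epoch > epochs) {
    stop_promtok("switch_epoch cannot exceed epochs", "promtok_config_error")
  }
  per_epoch <- replicate(epochs, organisms, simplify = FALSE)
  if (strategy == "evolutionary" && switch_epoch < epochs) {
    stopifnot(!is.null(phylo), !is.null(target))
    late <- nearest_species(phylo, target, m)
    late <- late[late %in% organisms]
    for (e in seq(switch_epoch + 1L, epochs)) per_epoch[[e]] <- late
  }
  structure(list(epochs = per_epoch, strategy = strategy),
            class = "curriculum_schedule")
}

CLS_ID <- 4L   # position of "[CLS]" among the specials
MASK_ID <- 3L  # position of "[MASK]"

# Corrupt one id sequence for MLM: choose positions at `rate` (at least one),
# then 80% MASK / 10% random content id / 10% keep.
mask_tokens <- function(ids, vocab_size, rate, n_specials = 5L) {
  T_ <- length(ids)
  sel <- which(runif(T_) < rate)
  if (length(sel) == 0) sel <- sample.int(T_, 1L)
  ids_in <- ids
  u <- runif(length(sel))
  ids_in[sel[u < 0.8]] <- MASK_ID
  rnd <- sel[u >= 0.8 & u < 0.9]
  if (length(rnd) > 0) {
    ids_in[rnd] <- sample.int(vocab_size - n_specials, length(rnd),
                              replace = TRUE) + n_specials
  }
  list(ids_in = ids_in, mask_pos = sel, targets = ids[sel])
}

#' Masked-LM pretraining under a curriculum
#'
#' @param encoder_cfg an [encoder_config()].
#' @param corpora named list: organism -> list of `tokenized_seq` objects,
#'   all carrying `label = "positive"`. A negative-labeled (or unlabeled)
#'   sequence is a contract violation.
#' @param schedule a `curriculum_schedule` from [make_schedule()].
#' @param train_cfg a [train_config()].
#' @param vocab the `dna_vocab` used for tokenization.
#' @param params optional initial parameters (else freshly initialized).
#' @return list: `params` (trained state), `loss_trace` (per-epoch mean MLM
#'   loss), `mask_fraction` (per-epoch fraction of masked positions) and
#'   `batch_log` (per-epoch list of per-batch organism vectors, for
#'   curriculum audits).
#' @export
pretrain_mlm <- function(encoder_cfg, corpora, schedule, train_cfg, vocab,
                         params = NULL) {
  stopifnot(inherits(schedule, "curriculum_schedule"))
  for (org in names(corpora)) {
    labs <- vapply(corpora[[org]],
                   function(tz) tz$label %||% "unlabeled", "")
    if (any(labs != "positive")) {
      stop_promtok(sprintf(
        "pretraining corpus for '%s' contains non-positive windows", org),
        "promtok_contract_error")
    }
  }
  missing <- setdiff(unique(unlist(schedule$epochs)), names(corpora))
  if (length(missing) > 0) {
    stop_promtok(paste("corpora missing for:", paste(missing, collapse = ", ")),
                 "promtok_config_error")
  }
  V <- vocab_size(vocab)
  with_seed(train_cfg$seed, {
    if (is.null(params)) {
      params <- init_encoder(encoder_cfg, V, seed = sample.int(2^30, 1))
    }
    opt <- adam_init(params)
    loss_trace <- numeric(0)
    mask_fraction <- numeric(0)
    batch_log <- list()
    for (e in seq_along(schedule$epochs)) {
      orgs <- schedule$epochs[[e]]
      pool <- unlist(lapply(orgs, function(o) corpora[[o]]), recursive = FALSE)
      pool_orgs <- rep(orgs, vapply(orgs, function(o) length(corpora[[o]]), 1L))
      ord <- sample.int(length(pool))
      losses <- numeric(0)
      masked <- 0L; total <- 0L
      epoch_batches <- list()
      i <- 1L
      while (i <= length(pool)) {
        idx <- ord[i:min(i + train_cfg$batch_size - 1L, length(pool))]
        total_g <- NULL
        bl <- numeric(length(idx))
        for (b in seq_along(idx)) {
          tz <- pool[[idx[b]]]
          mk <- mask_tokens(tz$ids, V, train_cfg$mask_rate)
          res <- mlm_loss_grad(params, encoder_cfg, mk$ids_in, mk$mask_pos,
                               mk$targets)
          bl[b] <- res$loss
          masked <- masked + length(mk$mask_pos)
          total <- total + length(tz$ids)
          total_g <- accumulate_grads(total_g, res$grads)
        }
        st <- adam_step(params, scale_grads(total_g, 1 / length(idx)),
                        opt, train_cfg$lr)
        params <- st$params; opt <- st$state
        losses <- c(losses, bl)
        epoch_batches[[length(epoch_batches) + 1L]] <- pool_orgs[idx]
        i <- i + train_cfg$batch_size
      }
      loss_trace <- c(loss_trace, mean(losses))
      mask_fraction <- c(mask_fraction, masked / total)
      batch_log[[e]] <- epoch_batches
    }
    list(params = params, loss_trace = loss_trace,
         mask_fraction = mask_fraction, batch_log = batch_log)
  })
}

# Tokenize a window table into a list of tokenized_seq with provenance.
tokenize_windows <- function(windows, vocab, merges = NULL) {
  lapply(seq_len(nrow(windows)), function(i) {
    encode(windows$sequence[i], vocab, merges = merges,
           window_id = windows$id[i], label = windows$label[i])
  })
}

#' Fine-tune a binary promoter classifier
#'
#' Attaches a tanh pooler + logistic head to the CLS position of the encoder
#' and trains with binary cross-entropy, early-stopping on validation loss.
#' Passing `pretrained = NULL` gives the from-scratch (no-pretrain)
#' baseline.
#'
#' @param pretrained encoder parameters from [pretrain_mlm()], or `NULL`.
#' @param train_tok,val_tok lists of `tokenized_seq` with `label` set.
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param vocab the `dna_vocab` used for tokenization.
#' @return a `promoter_classifier`: parameters, configs, scheme and a
#'   vocabulary hash, plus the training/validation loss curves.
#' @export
finetune_classifier <- function(pretrained, train_tok, val_tok, encoder_cfg,
                                train_cfg, vocab) {
  labs <- vapply(train_tok, function(tz) tz$label %||% NA_character_, "")
  if (length(unique(labs)) < 2) {
    stop_promtok("training data must contain both classes", "promtok_data_error")
  }
  V <- vocab_size(vocab)
  with_seed(train_cfg$seed, {
    params <- pretrained %||% init_encoder(encoder_cfg, V,
                                           seed = sample.int(2^30, 1))
    opt <- adam_init(params)
    y <- as.numeric(labs == "positive")
    val_y <- as.numeric(vapply(val_tok, function(tz) tz$label, "") == "positive")
    best <- list(loss = Inf, params = params, epoch = 0L)
    train_curve <- numeric(0); val_curve <- numeric(0)
    wait <- 0L
    for (e in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(train_tok))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + train_cfg$batch_size - 1L, length(ord))]
        total_g <- NULL
        for (b in idx) {
          tz <- train_tok[[b]]
          res <- cls_loss_grad(params, encoder_cfg, c(CLS_ID, tz$ids), y[b])
          losses <- c(losses, res$loss)
          total_g <- accumulate_grads(total_g, res$grads)
        }
        st <- adam_step(params, scale_grads(total_g, 1 / length(idx)),
                        opt, train_cfg$lr)
        params <- st$params; opt <- st$state
        i <- i + train_cfg$batch_size
      }
      vl <- if (length(val_tok) > 0) {
        mean(vapply(seq_along(val_tok), function(j) {
          cls_loss_grad(params, encoder_cfg, c(CLS_ID, val_tok[[j]]$ids),
                        val_y[j], want_grad = FALSE)$loss
        }, 1))
      } else {
        mean(losses)  # no validation windows: early-stop on training loss
      }
      train_curve <- c(train_curve, mean(losses))
      val_curve <- c(val_curve, vl)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = e)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) break
      }
    }
    structure(list(params = best$params, encoder_cfg = encoder_cfg,
                   train_cfg = train_cfg, scheme = vocab$scheme,
                   vocab_hash = config_hash(vocab$tokens),
                   vocab_size = V,
                   train_curve = train_curve, val_curve = val_curve,
                   best_epoch = best$epoch),
              class = "promoter_classifier")
  })
}

#' @export
print.promoter_classifier <- function(x, ...) {
  cat(sprintf("<promoter_classifier> scheme=%s, best epoch %d (val loss %.4f)\n",
              x$scheme, x$best_epoch, min(x$val_curve)))
  invisible(x)
}

# Probability that an id sequence (without CLS) is a promoter.
classifier_prob <- function(classifier, ids) {
  cls_forward(classifier$params, classifier$encoder_cfg,
              c(CLS_ID, ids))$prob
}

#' Predict promoter probabilities
#'
#' @param object a `promoter_classifier`.
#' @param tokenized list of `tokenized_seq` (same scheme and vocabulary as
#'   used in training; a mismatch is an error).
#' @param ... unused.
#' @return a `prediction_set` data frame: `id`, `prob`, `label`.
#' @export
predict.promoter_classifier <- function(object, tokenized, ...) {
  schemes <- unique(vapply(tokenized, `[[`, "", "scheme"))
  if (!identical(schemes, object$scheme)) {
    stop_promtok(sprintf("tokenization scheme %s does not match classifier (%s)",
                         paste(schemes, collapse = ","), object$scheme),
                 "promtok_config_error")
  }
  bad <- vapply(tokenized, function(tz) max(tz$ids) > object$vocab_size, TRUE)
  if (any(bad)) {
    stop_promtok("token ids exceed classifier vocabulary", "promtok_config_error")
  }
  out <- data.frame(
    id = vapply(tokenized, function(tz) tz$window_id %||% NA_character_, ""),
    prob = vapply(tokenized, function(tz) classifier_prob(object, tz$ids), 1),
    label = vapply(tokenized, function(tz) tz$label %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Fine-tuning sample-size ablation
#'
#' For each pretraining strategy, fine-tunes from the pretrained state on
#' nested balanced subsamples of a held-out pool (`sizes[1] ⊂ sizes[2] ⊂
#' ...`) and evaluates AUC on a fixed test set. Replicates redraw the
#' subsample order and model seeds.
#'
#' @param states named list of pretrained parameter states (e.g. `flat`,
#'   `evolutionary`).
#' @param pool_tok list of labeled `tokenized_seq` to subsample from.
#' @param val_tok validation list for early stopping.
#' @param test_tok fixed labeled test list.
#' @param sizes total fine-tuning set sizes (balanced across classes).
#' @param encoder_cfg,train_cfg,vocab as in [finetune_classifier()].
#' @param replicates number of replicate runs.
#' @return data frame: strategy, n, replicate, auc.
#' @export
ablation_curve <- function(states, pool_tok, val_tok, test_tok, sizes,
                           encoder_cfg, train_cfg, vocab, replicates = 1) {
  labs <- vapply(pool_tok, function(tz) tz$label, "")
  pos <- which(labs == "positive"); neg <- which(labs == "negative")
  if (2 * min(length(pos), length(neg)) < max(sizes)) {
    stop_promtok("pool too small for the largest ablation size",
                 "promtok_data_error")
  }
  test_labels <- vapply(test_tok, function(tz) tz$label, "") == "positive"
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    base_seed <- train_cfg$seed + 1000L * rep_i
    pos_ord <- with_seed(base_seed, sample(pos))
    neg_ord <- with_seed(base_seed + 1L, sample(neg))
    for (strat in names(states)) {
      for (n in sizes) {
        sub <- c(pos_ord[seq_len(n %/% 2)], neg_ord[seq_len(n %/% 2)])
        cfg_n <- train_cfg
        cfg_n$seed <- base_seed + 7L
        cls <- finetune_classifier(states[[strat]], pool_tok[sub], val_tok,
                                   encoder_cfg, cfg_n, vocab)
        preds <- predict(cls, test_tok)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strat, n = n, replicate = rep_i,
          auc = auc(preds$prob, test_labels), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
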