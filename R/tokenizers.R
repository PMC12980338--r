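#' DNA tokenization schemes
#'
#' Five schemes over A/C/G/T/N windows, all reporting per-token nucleotide
#' spans so that token-level attribution can be broadcast back to positions:
#'
#' * `kmer_nonoverlap`: adjacent k-mers, stride k; a trailing remainder
#'   shorter than k is dropped and recorded.
#' * `kmer_overlap`: k-mers at stride 1 (`L - k + 1` tokens).
#' * `bpe`: byte-pair encoding; training repeatedly merges the globally most
#'   frequent adjacent token pair.
#' * `wpc`: WordPiece; training merges the pair maximizing
#'   `count(ab) / (count(a) * count(b))`; inference is greedy longest-prefix
#'   match.
#' * `char`: one token per nucleotide (baseline).
#'
#' Pairs with 'N' on either side are excluded from frequency-based merging,
#' so no multi-character BPE/WPC token ever contains 'N'. Merge ties are
#' broken by the lexicographically smallest (left, right) pair, making
#' training deterministic.
#'
#' @name tokenizers
NULL

SPECIAL_TOKENS <- c(PAD = "[PAD]", UNK = "[UNK]", MASK = "[MASK]",
                    CLS = "[CLS]", SEP = "[SEP]")

#' Construct a vocabulary object
#'
#' @param content ordered character vector of content tokens.
#' @param scheme one of `"kmer_nonoverlap"`, `"kmer_overlap"`, `"bpe"`,
#'   `"wpc"`, `"char"`.
#' @param k k-mer length for k-mer schemes, else `NULL`.
#' @return a `dna_vocab`: specials first (ids 1-5), then content tokens.
#' @export
dna_vocab <- function(content, scheme, k = NULL) {
  if (anyDuplicated(content)) {
    stop_promtok("duplicate content tokens", "promtok_uniqueness_error")
  }
  if (any(content %in% SPECIAL_TOKENS)) {
    stop_promtok("content tokens collide with specials",
                 "promtok_uniqueness_error")
  }
  tokens <- c(unname(SPECIAL_TOKENS), content)
  structure(list(tokens = tokens, content = content,
                 specials = SPECIAL_TOKENS, scheme = scheme, k = k,
                 ids = setNames(seq_along(tokens), tokens)),
            class = "dna_vocab")
}

#' @export
print.dna_vocab <- function(x, ...) {
  cat(sprintf("<dna_vocab> scheme=%s, %d content tokens (+%d specials)\n",
              x$scheme, length(x$content), length(x$specials)))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

# ids for token strings, UNK fallback for out-of-vocabulary content
vocab_ids <- function(vocab, tokens) {
  ids <- vocab$ids[tokens]
  ids[is.na(ids)] <- vocab$ids[[SPECIAL_TOKENS[["UNK"]]]]
  unname(ids)
}

.kmer_starts <- function(L, k, overlapping) {
  if (overlapping) seq_len(max(L - k + 1L, 0L)) else {
    n <- L %/% k
    if (n == 0) integer(0) else (seq_len(n) - 1L) * k + 1L
  }
}

#' Build a k-mer vocabulary
#'
#' The content is the exhaustive set of `4^k` unambiguous k-mers plus every
#' ambiguous ('N'-containing) k-mer actually observed when tokenizing the
#' corpus under the given mode.
#'
#' @param corpus character vector of sequences.
#' @param k k-mer length (default 6).
#' @param overlapping logical; stride 1 vs stride k.
#' @return a `dna_vocab`.
#' @export
build_kmer_vocab <- function(corpus, k = 6, overlapping = FALSE) {
  stopifnot(k >= 1)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  exhaustive <- sort(do.call(paste0, rev(grid)))
  ambiguous <- character(0)
  for (s in corpus) {
    st <- .kmer_starts(nchar(s), k, overlapping)
    toks <- substring(s, st, st + k - 1L)
    ambiguous <- c(ambiguous, toks[grepl("N", toks, fixed = TRUE)])
  }
  dna_vocab(c(exhaustive, sort(unique(ambiguous))),
            scheme = if (overlapping) "kmer_overlap" else "kmer_nonoverlap",
            k = as.integer(k))
}

# ---- subword training (BPE / WordPiece) ------------------------------------

# Shared merge engine over a flat integer token stream with 0 separators.
.train_subword <- function(corpus, mode, target_vocab, min_pair_count) {
  chars <- sort(unique(unlist(strsplit(corpus, ""))))
  if (target_vocab < length(chars)) {
    stop_promtok("target_vocab below alphabet size", "promtok_config_error")
  }
  tok_strings <- chars
  has_n <- grepl("N", tok_strings, fixed = TRUE)
  stream <- unlist(lapply(corpus, function(s) {
    c(match(seq_to_chars(s), tok_strings), 0L)
  }))
  merges <- list()
  M <- 2^20  # pair key base; token count stays far below this
  repeat {
    if (length(tok_strings) >= target_vocab) break
    v1 <- stream[-length(stream)]; v2 <- stream[-1]
    valid <- v1 > 0L & v2 > 0L & !has_n[pmax(v1, 1L)] & !has_n[pmax(v2, 1L)]
    if (!any(valid)) break
    keys <- v1[valid] * M + v2[valid]
    r <- rle(sort(keys))
    if (mode == "bpe") {
      best_stat <- max(r$lengths)
      if (best_stat < max(2L, min_pair_count)) break
      cand <- r$values[r$lengths == best_stat]
    } else {
      tok_counts <- tabulate(stream[stream > 0L], nbins = length(tok_strings))
      lefts <- r$values %/% M; rights <- r$values %% M
      score <- r$lengths / (tok_counts[lefts] * tok_counts[rights])
      best <- max(score)
      cand <- r$values[score >= best - 1e-15]
      best_count <- max(r$lengths[score >= best - 1e-15])
      if (max(r$lengths[match(cand, r$values)]) < min_pair_count) break
    }
    lefts <- cand %/% M; rights <- cand %% M
    ord <- order(tok_strings[lefts], tok_strings[rights])
    if (mode == "wpc" && length(cand) > 1) {
      # among tied scores keep only pairs achieving the max raw count first
      cnts <- r$lengths[match(cand, r$values)]
      keep <- cnts == max(cnts)
      cand <- cand[keep]; lefts <- lefts[keep]; rights <- rights[keep]
      ord <- order(tok_strings[lefts], tok_strings[rights])
    }
    l <- lefts[ord[1]]; rt <- rights[ord[1]]
    if (mode == "wpc" && r$lengths[match(l * M + rt, r$values)] < min_pair_count) break
    new_id <- length(tok_strings) + 1L
    tok_strings <- c(tok_strings, paste0(tok_strings[l], tok_strings[rt]))
    has_n <- c(has_n, FALSE)
    merges[[length(merges) + 1L]] <-
      data.frame(left = tok_strings[l], right = tok_strings[rt],
                 merged = tok_strings[new_id], stringsAsFactors = FALSE)
    ps <- which(stream[-length(stream)] == l & stream[-1] == rt)
    if (l == rt && length(ps) > 1) {      # greedy leftmost, non-overlapping
      keep <- logical(length(ps)); last <- -2L
      for (j in seq_along(ps)) {
        if (ps[j] > last + 1L) { keep[j] <- TRUE; last <- ps[j] }
      }
      ps <- ps[keep]
    }
    stream[ps] <- new_id
    stream <- stream[-(ps + 1L)]
  }
  merge_df <- if (length(merges) > 0) {
    out <- do.call(rbind, merges); out$rank <- seq_len(nrow(out)); out
  } else {
    data.frame(left = character(0), right = character(0),
               merged = character(0), rank = integer(0))
  }
  list(vocab = dna_vocab(tok_strings, scheme = mode), merges = merge_df)
}

#' Train a byte-pair-encoding tokenizer
#'
#' Starts from single characters and repeatedly merges the globally most
#' frequent adjacent token pair, never across sequence boundaries and never
#' involving a token containing 'N'. Stops at `target_vocab` content tokens
#' or when no pair occurs at least twice.
#'
#' @param corpus character vector of training sequences.
#' @param target_vocab content-vocabulary size to stop at.
#' @param seed accepted for interface symmetry; training is deterministic.
#' @return list with `vocab` (a `dna_vocab`) and `merges` (a rank-ordered
#'   data frame `left`, `right`, `merged`, `rank`).
#' @export
train_bpe <- function(corpus, target_vocab, seed = NULL) {
  .train_subword(corpus, "bpe", target_vocab, min_pair_count = 2L)
}

#' Train a WordPiece tokenizer
#'
#' Each round merges the pair maximizing `count(ab) / (count(a) * count(b))`;
#' stops when the best pair's raw count falls below `min_pair_count` or the
#' content vocabulary reaches `target_vocab`.
#'
#' @param corpus character vector of training sequences.
#' @param min_pair_count frequency threshold stopping criterion (default 2).
#' @param target_vocab optional size cap (default unlimited).
#' @param seed accepted for interface symmetry; training is deterministic.
#' @return as [train_bpe()].
#' @export
train_wpc <- function(corpus, min_pair_count = 2L, target_vocab = Inf,
                      seed = NULL) {
  .train_subword(corpus, "wpc", target_vocab, min_pair_count)
}

# ---- encoding ---------------------------------------------------------------

new_tokenized <- function(tokens, ids, start, end, scheme, remainder = "",
                          window_id = NULL, label = NULL) {
  structure(list(tokens = tokens, ids = ids, start = start, end = end,
                 scheme = scheme, remainder = remainder,
                 window_id = window_id, label = label),
            class = "tokenized_seq")
}

#' Tokenize a nucleotide sequence
#'
#' @param seq nucleotide string.
#' @param vocab a `dna_vocab` whose scheme matches `scheme`.
#' @param scheme tokenization scheme (defaults to the vocabulary's).
#' @param merges merge table, required for `scheme = "bpe"`.
#' @param window_id optional source window id carried on the result.
#' @param label optional source label (`"positive"`/`"negative"`) carried on
#'   the result; pretraining uses it to enforce positives-only input.
#' @return a `tokenized_seq`: `tokens`, `ids`, 0-based half-open nucleotide
#'   spans (`start`, `end`), the dropped `remainder` (non-overlapping k-mer
#'   only), scheme, and provenance fields.
#' @export
encode <- function(seq, vocab, scheme = vocab$scheme, merges = NULL,
                   window_id = NULL, label = NULL) {
  L <- nchar(seq)
  if (!identical(scheme, vocab$scheme)) {
    stop_promtok(sprintf("vocabulary scheme '%s' does not match '%s'",
                         vocab$scheme, scheme), "promtok_config_error")
  }
  if (scheme %in% c("kmer_nonoverlap", "kmer_overlap")) {
    k <- vocab$k
    st <- .kmer_starts(L, k, scheme == "kmer_overlap")
    tokens <- substring(seq, st, st + k - 1L)
    rem <- if (scheme == "kmer_nonoverlap" && L %% k != 0) {
      substr(seq, L - L %% k + 1L, L)
    } else ""
    return(new_tokenized(tokens, vocab_ids(vocab, tokens), st - 1L,
                         if (scheme == "kmer_overlap") st - 1L + k
                         else st - 1L + k,
                         scheme, rem, window_id, label))
  }
  if (scheme == "char") {
    tokens <- seq_to_chars(seq)
    return(new_tokenized(tokens, vocab_ids(vocab, tokens),
                         0:(L - 1L), 1:L, scheme, "", window_id, label))
  }
  if (scheme == "bpe") {
    if (is.null(merges)) {
      stop_promtok("bpe encoding requires a merge table", "promtok_config_error")
    }
    toks <- seq_to_chars(seq)
    start <- 0:(L - 1L); end <- 1:L
    for (r in seq_len(nrow(merges))) {
      l <- merges$left[r]; rt <- merges$right[r]
      repeat {
        ps <- which(toks[-length(toks)] == l & toks[-1] == rt)
        if (length(ps) == 0) break
        if (l == rt && length(ps) > 1) {
          keep <- logical(length(ps)); last <- -2L
          for (j in seq_along(ps)) {
            if (ps[j] > last + 1L) { keep[j] <- TRUE; last <- ps[j] }
          }
          ps <- ps[keep]
        }
        toks[ps] <- merges$merged[r]
        end[ps] <- end[ps + 1L]
        toks <- toks[-(ps + 1L)]
        start <- start[-(ps + 1L)]; end <- end[-(ps + 1L)]
        break
      }
    }
    return(new_tokenized(toks, vocab_ids(vocab, toks), start, end,
                         scheme, "", window_id, label))
  }
  if (scheme == "wpc") {
    content <- vocab$content
    max_len <- max(nchar(content))
    in_vocab <- new.env(parent = emptyenv(), size = length(content) * 2L)
    for (tk in content) assign(tk, TRUE, envir = in_vocab)
    toks <- character(0); start <- integer(0); end <- integer(0)
    i <- 1L
    while (i <= L) {
      found <- FALSE
      for (len in seq(min(max_len, L - i + 1L), 1L)) {
        cand <- substr(seq, i, i + len - 1L)
        if (!is.null(get0(cand, envir = in_vocab))) {
          toks <- c(toks, cand); start <- c(start, i - 1L)
          end <- c(end, i + len - 1L)
          i <- i + len; found <- TRUE; break
        }
      }
      if (!found) {  # out-of-vocabulary character: consume one as UNK
        toks <- c(toks, SPECIAL_TOKENS[["UNK"]])
        start <- c(start, i - 1L); end <- c(end, i)
        i <- i + 1L
      }
    }
    return(new_tokenized(toks, vocab_ids(vocab, toks), start, end,
                         scheme, "", window_id, label))
  }
  stop_promtok(sprintf("unknown tokenization scheme '%s'", scheme),
               "promtok_config_error")
}

#' @export
print.tokenized_seq <- function(x, ...) {
  cat(sprintf("<tokenized_seq> scheme=%s, %d tokens%s\n", x$scheme,
              length(x$ids),
              if (nzchar(x$remainder)) sprintf(", remainder '%s'", x$remainder)
              else ""))
  invisible(x)
}

#' Reconstruct the input sequence from a tokenization
#'
#' Concatenates tokens (plus the recorded remainder) for partition-style
#' schemes; not defined for overlapping k-mers.
#'
#' @param tz a `tokenized_seq`.
#' @return the reconstructed nucleotide string.
#' @export
detokenize <- function(tz) {
  if (tz$scheme == "kmer_overlap") {
    stop_promtok("overlapping tokenization is not invertible by concatenation",
                 "promtok_config_error")
  }
  paste0(paste(tz$tokens, collapse = ""), tz$remainder)
}

# ---- vocabulary I/O ---------------------------------------------------------

#' Save / load a vocabulary (and merge table) as plain text
#'
#' `vocab.txt` holds one token per line (specials included); `meta.yaml`
#' holds the scheme and k; `merges.txt` (subword schemes) holds one
#' "left right" pair per line in rank order.
#'
#' @param vocab a `dna_vocab`.
#' @param dir directory.
#' @param merges optional merge table.
#' @return `load_vocab` returns `list(vocab, merges)`.
#' @export
save_vocab <- function(vocab, dir, merges = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(vocab$tokens, file.path(dir, "vocab.txt"))
  yaml::write_yaml(list(scheme = vocab$scheme, k = vocab$k),
                   file.path(dir, "meta.yaml"))
  if (!is.null(merges)) {
    writeLines(paste(merges$left, merges$right), file.path(dir, "merges.txt"))
  }
  invisible(dir)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  tokens <- readLines(file.path(dir, "vocab.txt"))
  content <- setdiff(tokens, SPECIAL_TOKENS)
  vocab <- dna_vocab(content, scheme = meta$scheme,
                     k = if (is.null(meta$k)) NULL else as.integer(meta$k))
  merges <- NULL
  mpath <- file.path(dir, "merges.txt")
  if (file.exists(mpath)) {
    lines <- readLines(mpath)
    parts <- strsplit(lines, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      stop_promtok(sprintf("malformed merges line %d", bad[1]),
                   "promtok_parse_error")
    }
    merges <- data.frame(left = vapply(parts, `[`, "", 1),
                         right = vapply(parts, `[`, "", 2),
                         stringsAsFactors = FALSE)
    merges$merged <- paste0(merges$left, merges$right)
    merges$rank <- seq_len(nrow(merges))
    unknown <- !(merges$merged %in% vocab$tokens)
    if (any(unknown)) {
      stop_promtok(sprintf("merges reference token '%s' absent from vocabulary",
                           merges$merged[which(unknown)[1]]),
                   "promtok_parse_error")
    }
  }
  list(vocab = vocab, merges = merges)
}
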