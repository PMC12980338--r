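#' Positional attribution analysis
#'
#' The explainability layer: select the most confidently classified windows,
#' attribute the classifier's promoter probability to individual tokens,
#' broadcast token scores across the nucleotides they cover, and average per
#' TSS-relative position across windows. Running the same pipeline on the
#' most confident negatives gives the negative-control profile.
#'
#' Attribution scores are on the probability scale and signed: a positive
#' score means the token pushed the prediction toward the promoter class.
#'
#' @name attribution
NULL

#' Select the most confidently classified windows
#'
#' Positives are ranked by predicted probability descending, negatives
#' ascending; ties are broken by id. If fewer than `n` records of the class
#' exist, all are returned with a warning.
#'
#' @param preds a `prediction_set` (see [predict.promoter_classifier()]).
#' @param target_class `"positive"` or `"negative"`.
#' @param n how many ids to return (default 100).
#' @return character vector of window ids.
#' @export
select_top_confident <- function(preds, target_class = c("positive", "negative"),
                                 n = 100) {
  target_class <- match.arg(target_class)
  sub <- preds[preds$label == target_class, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_promtok(sprintf("no records of class '%s'", target_class),
                 "promtok_data_error")
  }
  ord <- if (target_class == "positive") {
    order(-sub$prob, sub$id)
  } else {
    order(sub$prob, sub$id)
  }
  if (nrow(sub) < n) {
    warning(sprintf("only %d %s records available (requested %d)",
                    nrow(sub), target_class, n))
    n <- nrow(sub)
  }
  sub$id[ord][seq_len(n)]
}

# Resolve a model argument to a probability function over id vectors.
as_prob_fn <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "promoter_classifier")) {
    return(function(ids) classifier_prob(model, ids))
  }
  stop_promtok("model must be a promoter_classifier or a function(ids) -> prob",
               "promtok_config_error")
}

#' Per-token attribution of the promoter probability
#'
#' Two methods:
#' * `occlusion`: `score_t = P(x) - P(x with token t replaced by MASK)`;
#'   scores are bounded in [-1, 1].
#' * `shapley`: Monte-Carlo Shapley values over tokens with the all-MASK
#'   sequence as background; `n_samples` random insertion orders are
#'   averaged.
#'
#' @param model a `promoter_classifier`, or a `function(ids) -> prob` (used
#'   by tests with stub models).
#' @param tz a `tokenized_seq`.
#' @param method `"occlusion"` (default, dependency-free) or `"shapley"`.
#' @param n_samples permutations for the Shapley estimate.
#' @param seed seed for the Shapley permutations.
#' @return a `token_attribution`: `scores` (one per token, signed), `method`,
#'   and the tokenization (`tz`).
#' @export
token_attribution <- function(model, tz, method = c("occlusion", "shapley"),
                              n_samples = 16, seed = 1) {
  method <- match.arg(method)
  f <- as_prob_fn(model)
  T_ <- length(tz$ids)
  if (method == "occlusion") {
    base <- f(tz$ids)
    scores <- vapply(seq_len(T_), function(t) {
      ids2 <- tz$ids
      ids2[t] <- MASK_ID
      base - f(ids2)
    }, 1)
  } else {
    scores <- with_seed(seed, {
      acc <- numeric(T_)
      for (s in seq_len(n_samples)) {
        perm <- sample.int(T_)
        cur <- rep(MASK_ID, T_)
        p_prev <- f(cur)
        for (t in perm) {
          cur[t] <- tz$ids[t]
          p_new <- f(cur)
          acc[t] <- acc[t] + (p_new - p_prev)
          p_prev <- p_new
        }
      }
      acc / n_samples
    })
  }
  structure(list(scores = scores, method = method, tz = tz),
            class = "token_attribution")
}

# Broadcast one attribution to per-position values (NA where uncovered).
broadcast_attribution <- function(attr_obj, window_length) {
  tz <- attr_obj$tz
  if (any(tz$start < 0) || any(tz$end > window_length)) {
    stop_promtok("token span outside the window", "promtok_contract_error")
  }
  total <- numeric(window_length)
  count <- integer(window_length)
  for (t in seq_along(attr_obj$scores)) {
    idx <- (tz$start[t] + 1L):tz$end[t]
    total[idx] <- total[idx] + attr_obj$scores[t]
    count[idx] <- count[idx] + 1L
  }
  out <- total / count
  out[count == 0L] <- NA_real_
  out
}

#' Positional attribution profile
#'
#' Each position receives the score of its covering token (the mean over
#' covering tokens for overlapping tokenizations; `NA` at uncovered
#' positions such as the non-overlapping 6-mer's final base), then positions
#' are averaged across windows, ignoring missing values.
#'
#' @param attributions list of `token_attribution` objects over windows of a
#'   common length and scheme.
#' @param window_length window length in nt (default 601).
#' @param class_tag `"positive"` or `"negative"` (bookkeeping only).
#' @return a `positional_profile`: `values` (length `window_length`, index i
#'   is TSS offset `i - 1 - halfwidth`), `n_sequences`, `class_tag`.
#' @export
positional_profile <- function(attributions, window_length = 601,
                               class_tag = "positive") {
  mat <- vapply(attributions, broadcast_attribution, numeric(window_length),
                window_length = window_length)
  values <- rowMeans(mat, na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  structure(list(values = values, n_sequences = length(attributions),
                 class_tag = class_tag,
                 halfwidth = (window_length - 1L) %/% 2L),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> %s, n=%d, peak offset %+d\n",
              x$class_tag, x$n_sequences,
              which.max(x$values) - 1L - x$halfwidth))
  invisible(x)
}

#' Report the highest-attribution positions of a profile
#'
#' @param profile a `positional_profile`.
#' @param top_k how many positions to report.
#' @return data frame: `index` (0-based), `offset` (TSS-relative), `value`;
#'   attribute `degenerate` is `TRUE` for a constant profile.
#' @export
peak_report <- function(profile, top_k = 1) {
  v <- profile$values
  ok <- which(!is.na(v))
  ord <- ok[order(-v[ok], ok)]
  idx <- head(ord, top_k)
  out <- data.frame(index = idx - 1L,
                    offset = idx - 1L - profile$halfwidth,
                    value = v[idx])
  attr(out, "degenerate") <- diff(range(v[ok])) < 1e-12
  out
}

#' Nucleotide composition at one window position
#'
#' @param windows a `promoter_windows` data frame.
#' @param index 0-based window index.
#' @return named numeric vector of A/C/G/T/N frequencies summing to 1.
#' @export
composition_at_position <- function(windows, index) {
  L <- nchar(windows$sequence[1])
  stopifnot(index >= 0, index < L)
  ch <- substr(windows$sequence, index + 1L, index + 1L)
  counts <- table(factor(ch, levels = c(DNA_BASES, "N")))
  setNames(as.numeric(counts) / sum(counts), names(counts))
}

#' Highest-attribution tokens per window
#'
#' For each of the first `n_sequences` attributions, reports the `n_tokens`
#' tokens with the largest scores (ties: earlier span first), plus an
#' aggregate frequency table of the reported token strings.
#'
#' @param attributions list of `token_attribution` objects.
#' @param n_sequences windows to report (default 5).
#' @param n_tokens tokens per window.
#' @return list: `per_window` (list of data frames: token, score, start,
#'   end) and `frequency` (named count vector, decreasing).
#' @export
top_tokens <- function(attributions, n_sequences = 5, n_tokens = 10) {
  use <- head(attributions, n_sequences)
  per_window <- lapply(use, function(a) {
    ord <- order(-a$scores, a$tz$start)
    idx <- head(ord, n_tokens)
    data.frame(token = a$tz$tokens[idx], score = a$scores[idx],
               start = a$tz$start[idx], end = a$tz$end[idx],
               stringsAsFactors = FALSE)
  })
  all_tokens <- unlist(lapply(per_window, `[[`, "token"))
  freq <- sort(table(all_tokens), decreasing = TRUE)
  list(per_window = per_window, frequency = freq)
}
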