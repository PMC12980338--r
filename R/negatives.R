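#' Negative-set construction
#'
#' Two strategies for generating non-promoter sequences, one per positive:
#'
#' * **Shuffled negatives** divide each positive window into `n_segments`
#'   contiguous segments of `seg_len` nt (25 x 24 by default, tiling the
#'   first 600 positions; the final base is untouched), pick `n_perturb`
#'   segments uniformly without replacement, and permute the nucleotides
#'   inside each chosen segment. The whole-sequence nucleotide multiset is
#'   preserved exactly and every unperturbed position is byte-identical to
#'   the positive. A `substitute` mode (i.i.d. uniform bases inside chosen
#'   segments) is available for sensitivity analysis.
#' * **Fragment negatives** sample a random surrogate TSS from the same
#'   chromosome as the paired positive, at least `min_dist` nt (600 by
#'   default) from every positive TSS and every previously accepted negative
#'   TSS, and extract the corresponding window.
#'
#' @name negatives
NULL

#' Expected TATA-box retention under segment perturbation
#'
#' A motif survives iff its segment is unperturbed, so a positive-set TATA
#' prevalence of `p_tata` percent yields an expected negative-set frequency
#' of `p_tata * (n_segments - n_perturb) / n_segments` percent.
#'
#' @param p_tata TATA prevalence in the positives, percent (0-100).
#' @param n_perturb number of perturbed segments.
#' @param n_segments total number of segments.
#' @return expected TATA frequency in shuffled negatives, percent.
#' @export
expected_tata_frequency <- function(p_tata, n_perturb = 8, n_segments = 25) {
  stopifnot(p_tata >= 0, p_tata <= 100, n_perturb <= n_segments)
  p_tata * (n_segments - n_perturb) / n_segments
}

#' Make one shuffled negative from a positive window
#'
#' @param positive positive window sequence.
#' @param n_segments number of segments (default 25).
#' @param seg_len segment length in nt (default 24).
#' @param n_perturb segments to perturb (default 8).
#' @param mode `"shuffle"` permutes each chosen segment in place;
#'   `"substitute"` replaces it with i.i.d. uniform A/C/G/T.
#' @param seed optional seed; when `NULL` the caller's RNG stream is used.
#' @return list with `sequence` (same length as input) and `mask` (logical
#'   vector of length `n_segments`, `TRUE` = perturbed).
#' @export
make_shuffled_negative <- function(positive, n_segments = 25, seg_len = 24,
                                   n_perturb = 8, mode = c("shuffle", "substitute"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  L <- nchar(positive)
  if (n_segments * seg_len > L || n_perturb > n_segments) {
    stop_promtok("inconsistent segmentation parameters", "promtok_config_error")
  }
  with_seed(seed, {
    chars <- seq_to_chars(positive)
    mask <- logical(n_segments)
    mask[sample.int(n_segments, n_perturb)] <- TRUE
    for (s in which(mask)) {
      idx <- ((s - 1L) * seg_len + 1L):(s * seg_len)
      chars[idx] <- if (mode == "shuffle") {
        chars[idx][sample.int(seg_len)]
      } else {
        sample(DNA_BASES, seg_len, replace = TRUE)
      }
    }
    list(sequence = chars_to_seq(chars), mask = mask)
  })
}

#' Sample a fragment-negative surrogate TSS
#'
#' Draws uniform positions until one lies at least `min_dist` nt from every
#' occupied TSS (positives and previously accepted negatives) and a full
#' window fits on the chromosome.
#'
#' @param chrom_seq chromosome sequence.
#' @param occupied_tss 0-based positions already claimed.
#' @param min_dist minimum |TSS - TSS| distance in nt (default 600).
#' @param halfwidth window half-width (default 300).
#' @param max_tries attempts before giving up (default 1000).
#' @param seed optional seed.
#' @return a 0-based position; the caller must append it to `occupied_tss`
#'   before the next draw.
#' @export
sample_fragment_tss <- function(chrom_seq, occupied_tss, min_dist = 600,
                                halfwidth = 300, max_tries = 1000,
                                seed = NULL) {
  len <- nchar(chrom_seq)
  if (len < 2 * halfwidth + 1) {
    stop_promtok("chromosome shorter than one window", "promtok_config_error")
  }
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      p <- sample.int(len - 2L * halfwidth, 1L) + halfwidth - 1L  # 0-based
      if (length(occupied_tss) == 0 || all(abs(p - occupied_tss) >= min_dist)) {
        return(p)
      }
    }
    stop_promtok(sprintf("no valid fragment TSS found in %d tries", max_tries),
                 "promtok_placement_error")
  })
}

#' Build a balanced negative set paired to a positive set
#'
#' One negative per positive, carrying `paired_positive_id`. Fragment
#' negatives are drawn from the same chromosome as their paired positive;
#' failed placements are skipped with a warning, and the achieved imbalance
#' is reported in the `n_failed` attribute.
#'
#' @param positives a `promoter_windows` data frame of positives (fragment
#'   strategy additionally needs `chrom`, `tss_pos` and `organism` columns).
#' @param genomes a `genome_set` (required for the fragment strategy).
#' @param strategy `"shuffled"` or `"fragment"`.
#' @param seed integer seed; the whole build is deterministic given it.
#' @param ... passed to [make_shuffled_negative()] (e.g. `mode`,
#'   `n_perturb`) or [sample_fragment_tss()] (e.g. `min_dist`, `max_tries`).
#' @return a `promoter_windows` data frame of negatives.
#' @export
build_negative_set <- function(positives, genomes = NULL,
                               strategy = c("shuffled", "fragment"),
                               seed = 1, ...) {
  strategy <- match.arg(strategy)
  stopifnot(nrow(positives) > 0)
  hw <- (nchar(positives$sequence[1]) - 1L) %/% 2L
  with_seed(seed, {
    if (strategy == "shuffled") {
      rows <- lapply(seq_len(nrow(positives)), function(i) {
        p <- positives[i, ]
        neg <- make_shuffled_negative(p$sequence, ...)
        data.frame(id = paste0(p$id, "_neg"), organism = p$organism,
                   sequence = neg$sequence, label = "negative",
                   source = "shuffled_negative", paired_positive_id = p$id,
                   mask = paste(as.integer(neg$mask), collapse = ""),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      attr(out, "n_failed") <- 0L
      return(validate_windows(out))
    }
    if (is.null(genomes) || !inherits(genomes, "genome_set")) {
      stop_promtok("fragment strategy needs a genome_set", "promtok_config_error")
    }
    # occupied positions per organism/chromosome, seeded with positive TSSs
    occupied <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(positives))) {
      key <- paste(positives$organism[i], positives$chrom[i], sep = "/")
      assign(key, c(get0(key, envir = occupied, ifnotfound = integer(0)),
                    positives$tss_pos[i]), envir = occupied)
    }
    rows <- list(); n_failed <- 0L
    for (i in seq_len(nrow(positives))) {
      p <- positives[i, ]
      chrom_seq <- genomes$genomes[[p$organism]][[p$chrom]]
      if (is.null(chrom_seq)) {
        stop_promtok(sprintf("chromosome %s/%s not in genome set",
                             p$organism, p$chrom), "promtok_lookup_error")
      }
      key <- paste(p$organism, p$chrom, sep = "/")
      occ <- get(key, envir = occupied)
      pos <- tryCatch(
        sample_fragment_tss(chrom_seq, occ, halfwidth = hw, ...),
        promtok_placement_error = function(e) NULL)
      if (is.null(pos)) { n_failed <- n_failed + 1L; next }
      assign(key, c(occ, pos), envir = occupied)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(p$id, "_neg"), organism = p$organism,
        sequence = extract_window(chrom_seq, list(pos = pos, strand = "+"), hw),
        label = "negative", source = "fragment_negative",
        paired_positive_id = p$id, mask = NA_character_,
        chrom = p$chrom, tss_pos = pos, strand = "+",
        stringsAsFactors = FALSE)
    }
    if (n_failed > 0) {
      warning(sprintf("%d fragment negatives could not be placed; set is imbalanced",
                      n_failed))
    }
    out <- validate_windows(do.call(rbind, rows))
    attr(out, "n_failed") <- n_failed
    out
  })
}
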