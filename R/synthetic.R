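#' Synthetic multi-organism promoter corpus
#'
#' `synthesize_genome_set()` builds, per organism, a chromosome-scale
#' background sequence plus a table of planted transcription start sites.
#' Promoter loci carry the hallmarks the downstream analysis is designed to
#' detect: a GC-enriched core around the TSS, a TATA-box at a uniform offset
#' in `tata_offset_range` in a `tata_fraction` of promoters, and a fixed
#' downstream hexamer at `downstream_offset` in a `downstream_strength`
#' fraction. Background composition is a first-order (dinucleotide) chain
#' whose GC content drifts away from the reference organism proportionally to
#' phylogenetic distance, giving each organism a separable sequence
#' "dialect". Ambiguous 'N' bases are injected i.i.d. at `n_rate`, never
#' inside planted motifs.
#'
#' @name synthetic
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

base_freqs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

# First-order transition matrix with CpG depletion (C->G rate scaled by 0.25).
transition_matrix <- function(gc) {
  f <- base_freqs(gc)
  m <- matrix(rep(f, each = 4), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["C", "G"] <- m["C", "G"] * 0.25
  m / rowSums(m)
}

# Sample a length-L base-index vector from a first-order chain.
markov_chain <- function(L, trans, init = NULL) {
  if (L <= 0) return(integer(0))
  cum <- t(apply(trans, 1, cumsum))
  u <- runif(L)
  s <- integer(L)
  if (is.null(init)) init <- colSums(trans) / 4
  s[1] <- findInterval(u[1], cumsum(init)) + 1L
  s[1] <- min(s[1], 4L)
  for (i in seq_len(L - 1L)) {
    s[i + 1L] <- min(findInterval(u[i + 1L], cum[s[i], ]) + 1L, 4L)
  }
  s
}

markov_seq_chars <- function(L, trans) DNA_BASES[markov_chain(L, trans)]

# Synthesize one promoter window (character vector, TSS frame) and report
# which window indices are covered by planted motifs (1-based).
synth_promoter_window <- function(cfg, gc) {
  hw <- cfg$window_halfwidth
  L <- 2L * hw + 1L
  w <- markov_seq_chars(L, transition_matrix(gc))
  # GC-enriched core around the TSS
  core <- (hw + 1L - 60L):(hw + 1L + 60L)
  core <- core[core >= 1 & core <= L]
  w[core] <- markov_seq_chars(length(core),
                              transition_matrix(clamp(gc + cfg$core_gc_boost, 0.05, 0.95)))
  protected <- integer(0)
  has_tata <- runif(1) < cfg$tata_fraction
  if (has_tata) {
    off <- sample(cfg$tata_offset_range[1]:cfg$tata_offset_range[2], 1)
    motif <- seq_to_chars("TATAAA")
    motif[5] <- sample(c("A", "T"), 1)  # one degenerate position: TATA[AT]A
    idx <- (hw + 1L + off):(hw + off + length(motif))
    w[idx] <- motif
    protected <- c(protected, idx)
  }
  if (runif(1) < cfg$downstream_strength) {
    motif <- seq_to_chars(cfg$downstream_motif)
    idx <- (hw + 1L + cfg$downstream_offset):
      (hw + cfg$downstream_offset + length(motif))
    w[idx] <- motif
    protected <- c(protected, idx)
  }
  list(chars = w, protected = protected,
       promoter_class = if (has_tata) "TATA" else "nonTATA")
}

# Mutate exactly floor((1 - identity) * L) positions of a window, avoiding
# `protected` indices, substituting a different base at each site.
mutate_window <- function(chars, identity, protected = integer(0)) {
  L <- length(chars)
  n_mut <- floor((1 - identity) * L)
  pool <- setdiff(seq_len(L), protected)
  sites <- sample(pool, min(n_mut, length(pool)))
  for (i in sites) {
    cur <- chars[i]
    alt <- setdiff(DNA_BASES, cur)
    chars[i] <- alt[sample.int(length(alt), 1)]
  }
  chars
}

#' Generate genomes and TSS annotations for a phylogeny
#'
#' @param config a [sim_config()].
#' @param phylo a `phylo_table`; its first `n_organisms` organisms are
#'   simulated and the first organism is the composition reference.
#' @return a `genome_set`: `genomes` (per-organism named list of chromosome
#'   strings), `tss` (data frame: organism, chrom, pos (0-based), strand,
#'   promoter_class, family), plus the config and phylogeny used.
#' @export
synthesize_genome_set <- function(config, phylo) {
  stopifnot(inherits(config, "sim_config"), inherits(phylo, "phylo_table"))
  cfg <- validate_sim_config(config)
  orgs <- phylo$organisms[seq_len(min(cfg$n_organisms, length(phylo$organisms)))]
  if (length(orgs) < cfg$n_organisms) {
    stop_promtok("phylogeny has fewer organisms than n_organisms",
                 "promtok_config_error")
  }
  hw <- cfg$window_halfwidth
  n <- cfg$promoters_per_organism
  need <- 2L * (hw + 1L) + (n - 1L) * cfg$tss_spacing
  if (need > cfg$chromosome_length) {
    stop_promtok(sprintf(
      "cannot place %d promoters at spacing %d on a %d-nt chromosome",
      n, cfg$tss_spacing, cfg$chromosome_length), "promtok_capacity_error")
  }
  if (cfg$family_count * cfg$family_size > n) {
    stop_promtok("family_count * family_size exceeds promoters_per_organism",
                 "promtok_config_error")
  }
  ref <- orgs[1]
  with_seed(cfg$seed, {
    genomes <- list()
    tss_rows <- list()
    for (org in orgs) {
      d <- phylo$distance[ref, org]
      gc <- clamp(0.45 - cfg$gc_drift_rate * d, 0.25, 0.70)
      chrom <- markov_seq_chars(cfg$chromosome_length, transition_matrix(gc))
      jitter <- sample.int(max(1L, cfg$tss_spacing %/% 4L), n, replace = TRUE) - 1L
      pos <- hw + 1L + (seq_len(n) - 1L) * cfg$tss_spacing + jitter  # 1-based
      if (pos[n] + hw > cfg$chromosome_length) pos <- pos - jitter
      strand <- sample(c("+", "-"), n, replace = TRUE)
      wins <- lapply(seq_len(n), function(i) synth_promoter_window(cfg, gc))
      family <- rep(NA_integer_, n)
      if (cfg$family_count > 0) {
        for (f in seq_len(cfg$family_count)) {
          members <- ((f - 1L) * cfg$family_size + 1L):(f * cfg$family_size)
          family[members] <- f
          seed_win <- wins[[members[1]]]
          for (m in members[-1]) {
            wins[[m]] <- list(
              chars = mutate_window(seed_win$chars, cfg$family_identity,
                                    seed_win$protected),
              protected = seed_win$protected,
              promoter_class = seed_win$promoter_class)
          }
        }
      }
      protected_chrom <- logical(cfg$chromosome_length)
      for (i in seq_len(n)) {
        w <- wins[[i]]$chars
        span <- (pos[i] - hw):(pos[i] + hw)
        if (strand[i] == "+") {
          chrom[span] <- w
          protected_chrom[pos[i] - hw - 1L + wins[[i]]$protected] <- TRUE
        } else {
          chrom[span] <- rev(chartr("ACGT", "TGCA", w))
          protected_chrom[pos[i] + hw + 1L - wins[[i]]$protected] <- TRUE
        }
      }
      if (cfg$n_rate > 0) {
        n_idx <- which(runif(cfg$chromosome_length) < cfg$n_rate & !protected_chrom)
        chrom[n_idx] <- "N"
      }
      genomes[[org]] <- c(chr1 = chars_to_seq(chrom))
      tss_rows[[org]] <- data.frame(
        organism = org, chrom = "chr1", pos = pos - 1L,  # 0-based internal
        strand = strand,
        promoter_class = vapply(wins, `[[`, "", "promoter_class"),
        family = family, stringsAsFactors = FALSE)
    }
    tss <- do.call(rbind, unname(tss_rows))
    rownames(tss) <- NULL
    structure(list(genomes = genomes, tss = tss, config = cfg, phylo = phylo),
              class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d organisms, %d TSS records, chromosome %d nt\n",
              length(x$genomes), nrow(x$tss), x$config$chromosome_length))
  invisible(x)
}

#' Append near-duplicate families to a window set
#'
#' For each of `family_count` randomly chosen seed windows, appends
#' `family_size - 1` copies mutated at exactly `floor((1 - identity) * L)`
#' positions, so that every member's Hamming identity to its seed is at least
#' `identity`. Family membership is recorded in the `family` column for use
#' as a clustering oracle.
#'
#' @param windows a promoter-window data frame (see [extract_positive_windows()]).
#' @param family_count number of families to plant.
#' @param family_size members per family (the seed counts as one).
#' @param identity minimum within-family identity, in (0, 1].
#' @param seed integer seed.
#' @return the input plus `family_count * (family_size - 1)` appended rows.
#' @export
inject_redundancy <- function(windows, family_count, family_size, identity,
                              seed = 1) {
  if (nrow(windows) == 0) return(windows)
  stopifnot(identity > 0, identity <= 1, family_size >= 2)
  if (family_count > nrow(windows)) {
    stop_promtok("more families than available seed windows",
                 "promtok_config_error")
  }
  with_seed(seed, {
    if (!"family" %in% names(windows)) windows$family <- NA_integer_
    seeds <- sample.int(nrow(windows), family_count)
    extra <- list()
    for (f in seq_along(seeds)) {
      s <- seeds[f]
      windows$family[s] <- f
      chars <- seq_to_chars(windows$sequence[s])
      for (m in seq_len(family_size - 1L)) {
        row <- windows[s, , drop = FALSE]
        row$id <- sprintf("%s_fam%d_m%d", windows$id[s], f, m)
        row$sequence <- chars_to_seq(mutate_window(chars, identity))
        row$family <- f
        extra[[length(extra) + 1L]] <- row
      }
    }
    out <- rbind(windows, do.call(rbind, extra))
    rownames(out) <- NULL
    out
  })
}
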