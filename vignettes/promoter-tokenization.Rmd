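---
title: "Promoter classifiers at desk scale: tokenization, negatives, splits and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter classifiers at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`promtok` is a comparative framework for building promoter classifiers on
TSS-centered DNA windows and for auditing *what* such classifiers learn. This
vignette is the package's methods account: the models and procedures it
implements, the assumptions behind them, the defaults and why they were
chosen, and what the package's tests do and do not establish.

## 1. The data model

A promoter window is a sequence of length `2·halfwidth + 1` (601 nt by
default) over A/C/G/T/N, centered on a transcription start site: window
index `i` (0-based) corresponds to TSS offset `i − halfwidth`, so index 390
is offset +90. Windows are stranded; minus-strand windows are
reverse-complemented at extraction so that every window reads 5′→3′ with the
TSS at its center. Internal coordinates are 0-based; the TSV interchange
formats are 1-based (the convention of curated promoter databases), with
conversion confined to the I/O boundary.

Record tables carry, besides the sequence: organism, label
(positive/negative), provenance (`epd_like`, `shuffled_negative`,
`fragment_negative`), the paired positive's id for negatives, and — for
shuffled negatives — a 25-flag perturbation mask.

## 2. The synthetic corpus generator

Real promoter corpora cannot be bundled or downloaded here, so the
`synthetic_data` layer generates a multi-organism corpus with exactly the
statistical structure the downstream analysis assumes:

* **Background**: a first-order (dinucleotide) Markov chain per organism,
  with CpG depletion (the C→G transition scaled by 0.25). The chain's GC
  content drifts away from the reference organism linearly in phylogenetic
  distance (`gc_drift_rate`, default 2×10⁻⁴ per MYA-like unit), giving each
  organism a separable compositional "dialect" — the ingredient that makes
  curriculum pretraining and cross-species transfer meaningful.
* **Promoters**: a GC-enriched core (±60 nt around the TSS, `core_gc_boost`
  = 0.12); a TATA-box (`TATAAA` with one degenerate fifth position, matching
  the scanner's `TATA[AT]A`) planted at a uniform offset in [−35, −25] in a
  `tata_fraction` of promoters (default 0.129, the prevalence printed for
  the real multi-organism corpus); and a fixed GC-rich hexamer (`GGCGGC`)
  planted at offset +90 in a `downstream_strength` fraction (default 0.9).
  The +90 motif emulates the downstream positional signal that positional
  attribution is designed to detect; 0.9 keeps it strong but not universal,
  which is what a desk-scale model can recover reliably.
* **Phylogeny**: preset `"epd8"` fixes eight organisms whose divergence
  ranking from the reference puts `mmulatta`, `mmusculus` and `rnorvegicus`
  closest to `hsapiens`; `"epd9"` adds `cfamiliaris` for external
  validation. No published divergence times are reproduced — the preset
  encodes the ordinal structure only, with indicative MYA-like heights, and
  is ultrametric by construction. Random phylogenies (for property tests)
  are built by random sequential agglomeration, also ultrametric.
* **Redundancy**: near-duplicate families are planted by mutating a seed
  window at exactly `⌊(1−identity)·L⌋` positions, so within-family identity
  is *at least* the configured value (default 0.92, chosen above the 0.8
  clustering threshold so families must co-cluster).
* **Ambiguity**: 'N' bases are injected i.i.d. at `n_rate` (default 10⁻⁴,
  reflecting the extreme sparsity of assembly gaps in curated promoter
  windows), never inside planted motifs.

What the generator does **not** emulate: indels and rearrangements (all
divergence is compositional), nucleosome positioning and CpG-island
biophysics, realistic TSS clustering along chromosomes, or the per-organism
corpus sizes of any real database. Tests passing on this corpus therefore
establish that the pipeline's *mechanics* are correct and that the model
class can recover planted positional signals — not that any particular AUC
would be attained on real promoters.

All generation flows through one seeded RNG; fixed seeds give byte-identical
corpora.

## 3. Negative-set strategies

Two constructions, one negative per positive, both auditable after the fact:

* **Shuffled**: the positive is divided into 25 contiguous 24-nt segments
  (covering positions 1–600; the 601st base is deliberately untouched — the
  minimal-intervention reading of a 25×24 tiling of a 601-nt window).
  Eight segments are chosen uniformly without replacement and each is
  permuted *in place*. Permutation (rather than substitution) makes the
  whole-sequence nucleotide multiset identical to the positive by
  definition, which is the stronger of the two published descriptions of
  this scheme; an i.i.d.-substitution mode is retained behind a flag for
  sensitivity analysis. Each chosen segment is permuted independently
  (pooling the 8 segments before reshuffling would also preserve the
  multiset but destroy segment-level composition; the independent variant
  is the default). A TATA-box survives iff its segment is untouched, so
  retention is `p · 17/25` — 12.9% → 8.8%.
* **Fragment**: a surrogate TSS is drawn uniformly from the *same
  chromosome* as the paired positive, rejected until it lies ≥ 600 nt from
  every positive TSS and every previously accepted negative TSS (distances
  measured between TSS coordinates, not window edges, so windows may touch
  at exactly 600). After `max_tries` (default 1000) failed draws the record
  is skipped and the imbalance reported — never silently resampled from
  another chromosome.

## 4. Redundancy clustering and the split

Identity is ungapped Hamming identity over equal-length windows,
case-insensitive, with 'N' matching nothing. This deviates from the
word-filtered banded alignment of the external clustering tool the split
was designed around; since all windows here have equal length and no indels
exist in the synthetic corpus, Hamming identity is exact rather than
approximate, and a `.clstr` importer is provided for clusterings produced
externally.

Clustering is incremental-greedy: sequences in deterministic order (length
descending, then id ascending) join the earliest cluster whose
representative they match at ≥ 0.8, else found a new cluster. The
O(n²) representative scan is vectorized over byte matrices and is exact; at
the package's working scales (≤ a few thousand windows) no k-mer prefilter
is needed.

The split assigns whole clusters, sorted by size ascending (ties by
representative id), to **test** until it holds ≥ 20% of records, then to
**validation** until ≥ 15%, with everything remaining — including all large
families — going to **train**. A cluster that crosses a target boundary
stays whole in the set being filled; this overshoot rule is why achieved
fractions deviate slightly from the targets, and the achieved fractions are
reported on the assignment object. Negatives inherit their paired
positive's partition. External-organism sets are first stripped of
'N'-containing sequences, then clustered jointly with the training pool;
only externals whose cluster contains no training member are retained.

## 5. Tokenization

Five schemes, all reporting half-open nucleotide spans per token so
attribution can be broadcast back to positions:

* `kmer_nonoverlap` (the 6-mer default): ⌊L/k⌋ tokens at stride k; the
  trailing remainder (1 nt for L = 601, k = 6) is dropped but recorded, and
  the uncovered tail position is treated as missing (not zero) in
  positional profiles. The vocabulary is the exhaustive 4⁶ = 4096 set plus
  every 'N'-containing 6-mer observed in the training corpus.
* `kmer_overlap`: L−k+1 tokens at stride 1.
* `bpe`: training starts from single characters and repeatedly merges the
  globally most frequent adjacent pair, stopping at the target content
  vocabulary or when no pair occurs twice. Inference replays merges in rank
  order (the classic scheme).
* `wpc`: training merges the pair maximizing
  `count(ab)/(count(a)·count(b))` — a likelihood-gain score that can prefer
  a rare exclusive pair over a frequent diluted one — and stops when the
  best pair's raw count falls below `min_pair_count` or a size cap is
  reached (both stop modes are exposed, since published descriptions of
  this tokenizer specify "a frequency threshold" without the value).
  Inference is greedy longest-prefix match with single-character UNK
  fallback (standard WordPiece behavior).
* `char`: one token per nucleotide (baseline).

Subword training never merges across sequence boundaries, and pairs with
'N' on either side are ineligible, so no multi-character token ever
contains 'N'. Merge ties are broken by the lexicographically smallest
(left, right) pair — an arbitrary but deterministic rule, chosen so that
training is a pure function of the corpus. Pair counting is a full
vectorized recount per merge over a flat integer stream; at desk-scale
corpora this is fast and easy to verify, and only the merge application is
incremental.

## 6. The encoder and training

The encoder is a pre-norm transformer: token + learned positional
embeddings, multi-head scaled-dot-product self-attention, GELU feed-forward
blocks, residual connections, final layer norm. It is implemented directly
on R matrices with hand-derived backpropagation (verified against central
finite differences in the test suite) and an Adam optimizer. The default
configuration — 2 layers, 64 hidden units, 4 heads — is a deliberate
desk-scale working point; all sizes are configuration, so the same code
expresses larger models.

* **Pretraining** is masked-LM on *positive windows only* (a hard
  contract: a negative-labeled window in a pretraining corpus is an error).
  Mask rate 0.15 with the standard 80/10/10 mask/random/keep corruption.
  The loss is computed only at masked positions, and output projections are
  evaluated only there.
* **Curricula**: `flat` draws every epoch from all organisms;
  `evolutionary` uses all organisms for epochs 1..switch (default 5 of 10)
  and only the `nearest_species(…, 4)` set afterwards. An epoch is one pass
  over the union of the scheduled organisms' sequences, so the flat
  curriculum sees roughly twice as many late-phase observations — that
  asymmetry is part of the design being compared, not a bug. Per-batch
  organism provenance is logged so tests can audit that no excluded
  organism ever enters a late batch.
* **Fine-tuning** attaches a tanh pooler and logistic head, trains with
  binary cross-entropy, batch size 8, Adam, early stopping on validation
  loss (patience 3 by default), and supports a from-scratch mode as the
  no-pretraining baseline. Pooling is the **mean of final hidden states**
  by default rather than the CLS position: with 1–2-layer models at this
  scale, CLS-only pooling routes all gradient through a single attention
  position and a substantial fraction of seeded runs never left the
  `log 2` plateau, while mean pooling gives every token a direct gradient
  path and recovered planted signals in every seeded run. CLS pooling
  remains available (`encoder_config(pooling = "cls")`) for fidelity to the
  BERT convention.
* **Determinism**: all training randomness (init, shuffling, masking)
  derives from the training config's seed; identical seeds give identical
  loss traces and parameters.

The sample-size ablation fine-tunes from a shared pretrained state on
nested balanced subsamples (size n's subsample is contained in size
n+step's), evaluating each on a fixed test set, with replicates redrawing
subsample order and seeds.

## 7. Positional attribution

For each organism/model, the `n` most confidently classified positives
(probability descending; default 100, or as many as exist) are attributed
per token and broadcast to nucleotides: each position receives its covering
token's score, the mean over covering tokens where spans overlap, `NA`
where no token covers (the non-overlapping 6-mer's final base). The profile
is the per-position mean over windows, ignoring missing values. The same
pipeline run on the most confident *negatives* is the negative control: a
positional feature that appears in both profiles is an artifact of
negative-set construction, not promoter biology.

Attribution operates on the probability scale (bounded, comparable across
models) and scores are signed. Two methods:

* `occlusion` (default, dependency-free): `score_t = P(x) − P(x with token
  t masked)`, bounded in [−1, 1].
* `shapley`: Monte-Carlo Shapley values over tokens with the all-MASK
  sequence as background, averaging marginal contributions over random
  insertion orders (`n_samples`, default 16). For a model driven by a
  single decisive token the two methods agree on the argmax, which the
  suite checks.

Diagnostics around the profile: `peak_report` (top positions with
TSS-relative offsets, flagged when degenerate), `composition_at_position`
(base frequencies at one index, for checking whether a peak is mere
compositional bias), and `top_tokens` (highest-scoring tokens per window
with an aggregate frequency table).

## 8. Evaluation statistics

* **AUC** in Mann–Whitney form via midranks.
* **DeLong test** for correlated ROC curves from structural components:
  per-positive and per-negative placement values per model (midrank tie
  treatment), empirical covariance matrices, variance of the AUC
  difference, standard-normal reference, two-sided p. Degenerate cases are
  explicit: identical scores give z = 0, p = 1; zero variance with a
  nonzero AUC difference is reported as p = 0 with a warning.
* **FDR**: Benjamini–Hochberg step-up (delegated to `stats::p.adjust`),
  with a global family by default across all tokenizer-pair comparisons
  (per-organism families available) — the more conservative reading when
  the published analysis does not state the family.
* **Pearson** distance–AUC correlation with the exact t-based two-sided p
  (delegated to `stats::cor.test`), used by the cross-species evaluation.

## 9. Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path with comfortable margins: corpora
of 100–500 promoters per run, 601-nt windows, 1-layer/32-unit encoders for
end-to-end checks, 15-window attribution sets, 5-seed replication for
directional claims, and 2000-replicate null simulations for test
calibration. These are the package's own working points; the same functions
scale by configuration.

Numerical conventions: layer norm uses ε = 10⁻⁵; softmax subtracts row
maxima; cross-entropy clamps probabilities at 10⁻¹²; Adam uses
β = (0.9, 0.999), ε = 10⁻⁸; early stopping requires improvement > 10⁻⁹;
attribution tie-breaks are by span start; selection tie-breaks are by
record id.

## 10. Known limitations

* The encoder is desk-scale; absolute classification performance on the
  synthetic corpus (AUCs typically 0.6–0.95 depending on seed and size) is
  not evidence about full-scale models on real data, and the
  pretraining-benefit effect at n = 32 fine-tuning windows, while
  consistent in direction across seeds, is small in magnitude.
* Hamming identity understates similarity between sequences related by
  indels; on real data, importing a `.clstr` file from an alignment-based
  tool is the faithful route.
* The Shapley estimator is Monte-Carlo and priced for stub-model tests;
  occlusion is the default for real attribution runs.
* Fragment negatives inherit the background model's compositional
  simplicity; on real genomes they would carry repeats, CpG islands and
  other structure the generator does not emulate.
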