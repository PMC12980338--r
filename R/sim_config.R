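#' Simulation configuration
#'
#' Bundles every tunable of the synthetic promoter corpus generator. The
#' defaults encode the study conditions the rest of the package assumes:
#' 601-nt windows (`window_halfwidth = 300`), a TATA-box planted at a uniform
#' offset in `[-35, -25]` in 12.9% of promoters, and a fixed GC-rich hexamer
#' planted at TSS offset +90 (window index 390) in a configurable fraction of
#' promoters.
#'
#' @param n_organisms number of organisms to simulate.
#' @param promoters_per_organism promoter (TSS) count per organism.
#' @param chromosome_length chromosome length in nt; `NULL` sizes the
#'   chromosome automatically from `promoters_per_organism` and `tss_spacing`.
#' @param window_halfwidth half-width of the promoter window in nt (window
#'   length is `2 * window_halfwidth + 1`).
#' @param tata_fraction fraction of promoters carrying a planted TATA-box.
#' @param tata_offset_range integer TSS-relative interval for the TATA-box
#'   start position.
#' @param downstream_motif hexamer planted downstream of the TSS.
#' @param downstream_offset TSS-relative start offset of the downstream motif.
#' @param downstream_strength probability that a promoter carries the
#'   downstream motif.
#' @param core_gc_boost additive GC enrichment applied to the core region
#'   around the TSS.
#' @param gc_drift_rate GC-composition change per unit phylogenetic distance.
#' @param n_rate per-base probability of an ambiguous 'N' call.
#' @param tss_spacing minimum distance between consecutive planted TSSs, nt.
#' @param family_count,family_size,family_identity redundancy controls: number
#'   of near-duplicate families per organism, members per family, and
#'   within-family sequence identity. `family_identity` must exceed 0.8 so
#'   that planted families co-cluster at the 80% identity threshold.
#' @param seed integer seed driving all randomness in generation.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_organisms = 8,
                       promoters_per_organism = 100,
                       chromosome_length = NULL,
                       window_halfwidth = 300,
                       tata_fraction = 0.129,
                       tata_offset_range = c(-35, -25),
                       downstream_motif = "GGCGGC",
                       downstream_offset = 90,
                       downstream_strength = 0.9,
                       core_gc_boost = 0.12,
                       gc_drift_rate = 2e-4,
                       n_rate = 1e-4,
                       tss_spacing = 2000,
                       family_count = 0,
                       family_size = 4,
                       family_identity = 0.92,
                       seed = 1) {
  if (is.null(chromosome_length)) {
    chromosome_length <- promoters_per_organism * tss_spacing +
      2 * (window_halfwidth + 1) + tss_spacing
  }
  cfg <- structure(list(
    n_organisms = as.integer(n_organisms),
    promoters_per_organism = as.integer(promoters_per_organism),
    chromosome_length = as.integer(chromosome_length),
    window_halfwidth = as.integer(window_halfwidth),
    tata_fraction = tata_fraction,
    tata_offset_range = as.integer(tata_offset_range),
    downstream_motif = toupper(downstream_motif),
    downstream_offset = as.integer(downstream_offset),
    downstream_strength = downstream_strength,
    core_gc_boost = core_gc_boost,
    gc_drift_rate = gc_drift_rate,
    n_rate = n_rate,
    tss_spacing = as.integer(tss_spacing),
    family_count = as.integer(family_count),
    family_size = as.integer(family_size),
    family_identity = family_identity,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$tata_fraction, cfg$downstream_strength, cfg$n_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_promtok("probabilities must lie in [0, 1]", "promtok_config_error")
  }
  if (cfg$window_halfwidth <= 0) {
    stop_promtok("window_halfwidth must be positive", "promtok_config_error")
  }
  if (cfg$chromosome_length < 2 * cfg$window_halfwidth + 1) {
    stop_promtok("chromosome shorter than one window", "promtok_config_error")
  }
  if (cfg$family_count > 0 &&
      (cfg$family_identity <= 0.8 || cfg$family_identity > 1)) {
    stop_promtok("family_identity must lie in (0.8, 1] so families co-cluster",
                 "promtok_config_error")
  }
  if (cfg$tata_offset_range[1] > cfg$tata_offset_range[2]) {
    stop_promtok("tata_offset_range must be an increasing interval",
                 "promtok_config_error")
  }
  assert_dna(cfg$downstream_motif, "downstream_motif")
  cfg
}

#' Write / read a simulation configuration as YAML
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[setdiff(names(raw), "chromosome_length")] |>
            (\(x) c(x, list(chromosome_length = raw$chromosome_length)))())
}
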