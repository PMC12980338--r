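#' Promoter windows and corpus I/O
#'
#' Promoter windows are TSS-centered sequences of length
#' `2 * halfwidth + 1` (601 nt by default), covering TSS-relative offsets
#' `-halfwidth .. +halfwidth`; offset `o` corresponds to 0-based window index
#' `o + halfwidth` (so index 390 is offset +90 under the default halfwidth).
#' Internally all chromosome coordinates are 0-based; the TSV interchange
#' format is 1-based, with conversion only at the I/O boundary. Minus-strand
#' windows are reverse-complemented at extraction so every window reads
#' 5' to 3' with the TSS base at its center.
#'
#' @name corpus_io
NULL

#' Convert between TSS-relative offsets and 0-based window indices
#' @param offset TSS-relative offset(s) in `[-halfwidth, +halfwidth]`.
#' @param index 0-based window index/indices in `[0, 2 * halfwidth]`.
#' @param halfwidth window half-width (default 300).
#' @return the corresponding index (resp. offset) vector.
#' @export
offset_to_index <- function(offset, halfwidth = 300) offset + halfwidth

#' @rdname offset_to_index
#' @export
index_to_offset <- function(index, halfwidth = 300) index - halfwidth

#' Extract a TSS-centered window from a chromosome
#'
#' @param chrom_seq chromosome sequence (character scalar).
#' @param tss a list or one-row data frame with `pos` (0-based chromosome
#'   coordinate) and `strand` (`"+"` or `"-"`).
#' @param halfwidth window half-width in nt.
#' @return the window sequence; for `strand == "-"` the reverse complement,
#'   so the TSS base sits at 0-based index `halfwidth` reading 5' to 3'.
#' @export
extract_window <- function(chrom_seq, tss, halfwidth = 300) {
  pos <- as.integer(tss$pos)
  len <- nchar(chrom_seq)
  if (pos < halfwidth || pos + halfwidth >= len) {
    stop_promtok(sprintf(
      "TSS at %d too close to chromosome edge for halfwidth %d (length %d)",
      pos, halfwidth, len), "promtok_boundary_error")
  }
  w <- substr(chrom_seq, pos - halfwidth + 1L, pos + halfwidth + 1L)
  if (identical(tss$strand, "-")) w <- revcomp(w)
  w
}

#' Scan a window for a TATA-box
#'
#' Returns `TRUE` iff the degenerate pattern `TATA[AT]A` starts at a
#' TSS-relative offset inside `scan_range`. 'N' never matches.
#'
#' @param window window sequence (odd length; TSS at the center).
#' @param scan_range TSS-relative interval for the motif start
#'   (default `c(-40, -20)`).
#' @return logical scalar.
#' @export
classify_tata <- function(window, scan_range = c(-40, -20)) {
  hw <- (nchar(window) - 1L) %/% 2L
  stopifnot(scan_range[1] >= -hw, scan_range[2] <= hw)
  lo <- scan_range[1] + hw + 1L           # 1-based start of scan region
  hi <- scan_range[2] + hw + 1L
  region <- substr(window, lo, min(hi + 5L, nchar(window)))
  m <- gregexpr("TATA[AT]A", region)[[1]]
  any(m > 0 & m <= (hi - lo + 1L))
}

#' Construct a promoter-window record table
#'
#' @param id,organism,sequence,label,source,paired_positive_id,mask vectors of
#'   equal length (scalars recycled); `mask` is a 25-character "0"/"1" string
#'   for shuffled negatives, `NA` otherwise.
#' @param ... further columns (e.g. chrom, tss_pos, strand, promoter_class).
#' @return a validated data frame of class `promoter_windows`.
#' @export
promoter_windows <- function(id, organism, sequence, label, source,
                             paired_positive_id = NA_character_,
                             mask = NA_character_, ...) {
  df <- data.frame(id = id, organism = organism, sequence = sequence,
                   label = label, source = source,
                   paired_positive_id = paired_positive_id, mask = mask,
                   ..., stringsAsFactors = FALSE)
  validate_windows(df)
}

validate_windows <- function(df) {
  if (anyDuplicated(df$id)) {
    stop_promtok("duplicate window ids", "promtok_uniqueness_error")
  }
  lens <- nchar(df$sequence)
  if (length(unique(lens)) > 1) {
    stop_promtok("windows have inconsistent lengths", "promtok_domain_error")
  }
  if (any(lens %% 2 == 0)) {
    stop_promtok("window length must be odd (2 * halfwidth + 1)",
                 "promtok_domain_error")
  }
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad)) stop_promtok("sequences contain non-ACGTN characters",
                             "promtok_domain_error")
  neg <- df$label == "negative"
  if (any(neg & is.na(df$paired_positive_id))) {
    stop_promtok("negative windows must carry paired_positive_id",
                 "promtok_domain_error")
  }
  shuf <- df$source == "shuffled_negative"
  if (any(shuf & is.na(df$mask)) || any(!shuf & !is.na(df$mask))) {
    stop_promtok("mask must be present iff source is shuffled_negative",
                 "promtok_domain_error")
  }
  class(df) <- c("promoter_windows", "data.frame")
  df
}

#' Extract all positive promoter windows from a genome set
#'
#' TSS records whose window would cross a chromosome end are skipped with a
#' warning.
#'
#' @param gs a `genome_set` from [synthesize_genome_set()].
#' @param halfwidth window half-width (defaults to the generating config's).
#' @return a `promoter_windows` data frame with one positive per usable TSS.
#' @export
extract_positive_windows <- function(gs, halfwidth = NULL) {
  stopifnot(inherits(gs, "genome_set"))
  if (is.null(halfwidth)) halfwidth <- gs$config$window_halfwidth
  rows <- list()
  counters <- list()
  skipped <- 0L
  for (i in seq_len(nrow(gs$tss))) {
    rec <- gs$tss[i, ]
    chrom_seq <- gs$genomes[[rec$organism]][[rec$chrom]]
    w <- tryCatch(extract_window(chrom_seq, rec, halfwidth),
                  promtok_boundary_error = function(e) NULL)
    if (is.null(w)) { skipped <- skipped + 1L; next }
    k <- (counters[[rec$organism]] %||% 0L) + 1L
    counters[[rec$organism]] <- k
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("p%04d_%s", k, rec$organism),
      organism = rec$organism, sequence = w, label = "positive",
      source = "epd_like", paired_positive_id = NA_character_,
      mask = NA_character_, chrom = rec$chrom, tss_pos = rec$pos,
      strand = rec$strand, promoter_class = rec$promoter_class,
      family = rec$family, stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(sprintf("%d TSS records skipped: window out of bounds", skipped))
  }
  validate_windows(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write TSS annotation tables
#'
#' The interchange TSV is 1-based and strand-aware with columns
#' `organism, chrom, pos, strand, class` (`class` in TATA/nonTATA/unknown);
#' positions are converted to the package's 0-based internal convention on
#' load. Lines starting with `#` are provenance comments.
#'
#' @param path file path.
#' @param tss internal TSS data frame (0-based `pos`).
#' @param seed optional seed recorded in the provenance header.
#' @return `load_tss_table` returns a data frame with 0-based `pos`.
#' @export
load_tss_table <- function(path) {
  if (!file.exists(path)) stop_promtok(paste("no such file:", path),
                                       "promtok_io_error")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) < 1) stop_promtok("empty TSS table", "promtok_parse_error")
  header <- strsplit(body[1], "\t")[[1]]
  need <- c("organism", "chrom", "pos", "strand", "class")
  if (!identical(header[seq_along(need)], need)) {
    stop_promtok("TSS table header must be: organism chrom pos strand class",
                 "promtok_parse_error")
  }
  rows <- lapply(seq_along(body[-1]) + 1L, function(i) {
    f <- strsplit(body[i], "\t")[[1]]
    pos <- suppressWarnings(as.integer(f[3]))
    if (length(f) < 5 || is.na(pos) || pos < 1 || !f[4] %in% c("+", "-") ||
        !f[5] %in% c("TATA", "nonTATA", "unknown")) {
      stop_promtok(sprintf("malformed TSS row at line %d", lineno[i]),
                   "promtok_parse_error")
    }
    data.frame(organism = f[1], chrom = f[2], pos = pos - 1L, strand = f[4],
               promoter_class = f[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname load_tss_table
#' @export
write_tss_table <- function(tss, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed = seed), con)
  writeLines("organism\tchrom\tpos\tstrand\tclass", con)
  writeLines(sprintf("%s\t%s\t%d\t%s\t%s", tss$organism, tss$chrom,
                     tss$pos + 1L, tss$strand, tss$promoter_class), con)
  invisible(path)
}

#' Write / read a promoter-window dataset
#'
#' Sequences go to a FASTA file (80-column wrap) with headers
#' `id|organism|label|source|paired_id`; the full record table, including
#' perturbation masks, goes to a sidecar manifest TSV at
#' `<path>.manifest.tsv` with a provenance comment header. `load_dataset`
#' reads both and checks that they agree.
#'
#' @param windows a `promoter_windows` data frame.
#' @param path FASTA file path.
#' @param seed optional seed recorded in the provenance header.
#' @return `load_dataset` returns a `promoter_windows` data frame.
#' @export
write_dataset <- function(windows, path, seed = NULL) {
  windows <- validate_windows(as.data.frame(windows))
  dss <- Biostrings::DNAStringSet(windows$sequence)
  names(dss) <- sprintf("%s|%s|%s|%s|%s", windows$id, windows$organism,
                        windows$label, windows$source,
                        ifelse(is.na(windows$paired_positive_id), ".",
                               windows$paired_positive_id))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  man <- paste0(path, ".manifest.tsv")
  con <- file(man, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed = seed), con)
  cols <- names(windows)
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(windows, function(x) {
    x <- as.character(x); x[is.na(x)] <- "."; x
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop_promtok(paste("no such file:", path),
                                       "promtok_io_error")
  dss <- Biostrings::readDNAStringSet(path)
  man <- paste0(path, ".manifest.tsv")
  if (file.exists(man)) {
    lines <- readLines(man)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    header <- strsplit(body[1], "\t")[[1]]
    parts <- strsplit(body[-1], "\t")
    bad <- which(lengths(parts) != length(header))
    if (length(bad) > 0) {
      stop_promtok(sprintf("malformed manifest row %d", bad[1]),
                   "promtok_parse_error")
    }
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- header
    df[df == "."] <- NA
    for (col in intersect(c("tss_pos", "family"), names(df))) {
      df[[col]] <- as.integer(df[[col]])
    }
  } else {
    fields <- strsplit(names(dss), "|", fixed = TRUE)
    bad <- which(lengths(fields) != 5)
    if (length(bad) > 0) {
      stop_promtok(sprintf("malformed FASTA header for record %d", bad[1]),
                   "promtok_parse_error")
    }
    m <- do.call(rbind, fields)
    df <- data.frame(id = m[, 1], organism = m[, 2], label = m[, 3],
                     source = m[, 4],
                     paired_positive_id = ifelse(m[, 5] == ".", NA, m[, 5]),
                     mask = NA_character_, stringsAsFactors = FALSE)
  }
  df$sequence <- as.character(dss)
  if (anyDuplicated(df$id)) {
    stop_promtok("duplicate window ids in dataset", "promtok_uniqueness_error")
  }
  validate_windows(df)
}

#' Write a genome set to a directory
#'
#' Chromosomes as one FASTA per organism, TSS annotations as a 1-based TSV,
#' and the generating configuration as YAML.
#'
#' @param gs a `genome_set`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (org in names(gs$genomes)) {
    dss <- Biostrings::DNAStringSet(gs$genomes[[org]])
    Biostrings::writeXStringSet(dss, file.path(dir, paste0(org, ".fasta")),
                                width = 80L)
  }
  write_tss_table(gs$tss, file.path(dir, "tss.tsv"), seed = gs$config$seed)
  write_sim_config(gs$config, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
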