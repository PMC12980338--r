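#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom runif rnorm setNames aggregate pt cor.test p.adjust pnorm
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_promtok <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "promtok_error")))
}

#' Reverse complement of a nucleotide string
#'
#' 'N' maps to itself; input must be over A/C/G/T/N (uppercase).
#'
#' @param seq character scalar.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

seq_to_chars <- function(seq) strsplit(seq, "")[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

assert_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    stop_promtok(sprintf("%s contains characters outside A/C/G/T/N", what),
                 "promtok_domain_error")
  }
  invisible(seq)
}

# Stable short hash of an R object (configuration fingerprints, resume keys).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 4294967291
    h2 <- (h2 * 31 + b) %% 4294967279
  }
  sprintf("%08x%08x", as.integer(h1 %% 2^31), as.integer(h2 %% 2^31))
}

provenance_lines <- function(seed = NULL, config = NULL) {
  out <- c(sprintf("# promtok %s", as.character(packageVersion("promtok"))))
  if (!is.null(seed))   out <- c(out, sprintf("# seed: %s", seed))
  if (!is.null(config)) out <- c(out, sprintf("# config_hash: %s", config_hash(config)))
  out
}
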