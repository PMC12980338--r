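#' Identity clustering and leakage-free data splitting
#'
#' Sequences are grouped at an identity threshold (default 80%) with an
#' incremental greedy scheme, whole clusters are then assigned to
#' test/validation/train by size-ascending accumulation, and negatives
#' follow their paired positives. The identity measure is ungapped Hamming
#' identity over equal-length windows; `read_clstr()` imports clusterings
#' produced by external tools in the standard `.clstr` dialect as a faithful
#' alternative.
#'
#' @name redundancy_split
NULL

#' Ungapped pairwise sequence identity
#'
#' Fraction of positions at which two equal-length sequences agree,
#' case-insensitive; 'N' matches nothing (including another 'N').
#'
#' @param a,b sequences of equal length.
#' @return identity in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop_promtok("sequences must have equal length", "promtok_length_error")
  }
  ra <- charToRaw(toupper(a)); rb <- charToRaw(toupper(b))
  n_raw <- charToRaw("N")
  mean(ra == rb & ra != n_raw)
}

# byte matrix (rows = sequences) for vectorized identity computations
.seq_byte_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  m <- matrix(0L, length(seqs), L)
  for (i in seq_along(seqs)) m[i, ] <- as.integer(charToRaw(toupper(seqs[i])))
  m
}

#' Greedy identity clustering
#'
#' Sequences are processed in deterministic order (length descending, then id
#' ascending). Each sequence joins the earliest-founded cluster whose
#' representative it matches at `>= threshold` identity, otherwise it founds
#' a new cluster with itself as representative.
#'
#' @param sequences named character vector (names are record ids).
#' @param threshold identity threshold in (0, 1] (default 0.80).
#' @return list of clusters, each `list(id, representative_id, member_ids)`.
#' @export
greedy_cluster <- function(sequences, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sequences) == 0) return(list())
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_promtok("sequences must have unique names", "promtok_uniqueness_error")
  }
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  lens <- nchar(seqs)
  n_code <- as.integer(charToRaw("N"))
  clusters <- list()
  rep_mat <- NULL   # byte matrix of representatives (equal-length case)
  rep_len <- integer(0)
  for (i in seq_along(seqs)) {
    s <- as.integer(charToRaw(toupper(seqs[i])))
    joined <- FALSE
    if (length(clusters) > 0) {
      cand <- which(rep_len == lens[i])
      if (length(cand) > 0) {
        sm <- matrix(s, nrow = length(cand), ncol = lens[i], byrow = TRUE)
        hits <- rowSums(rep_mat[cand, , drop = FALSE] == sm & sm != n_code)
        ok <- cand[hits / lens[i] >= threshold]
        if (length(ok) > 0) {
          k <- ok[1]
          clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, ids[i])
          joined <- TRUE
        }
      }
    }
    if (!joined) {
      k <- length(clusters) + 1L
      clusters[[k]] <- list(id = sprintf("C%04d", k),
                            representative_id = ids[i],
                            member_ids = ids[i])
      rep_len <- c(rep_len, lens[i])
      row <- matrix(s, 1L)
      rep_mat <- if (is.null(rep_mat)) row else {
        if (ncol(rep_mat) == lens[i]) rbind(rep_mat, row) else {
          # ragged lengths: pad with zeros (lengths tracked separately)
          w <- max(ncol(rep_mat), lens[i])
          a <- cbind(rep_mat, matrix(0L, nrow(rep_mat), w - ncol(rep_mat)))
          rbind(a, c(s, integer(w - lens[i])))
        }
      }
    }
  }
  clusters
}

#' Read a .clstr clustering file
#'
#' Parses the standard dialect: `>Cluster n` headers followed by member
#' lines; the representative member is flagged with a trailing `*`.
#'
#' @param path file path.
#' @return list of clusters as in [greedy_cluster()].
#' @export
read_clstr <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  clusters <- list()
  current <- NULL
  flush <- function(cl) {
    if (is.null(cl)) return(invisible())
    if (is.na(cl$representative_id)) {
      stop_promtok(sprintf("cluster '%s' has no representative (*)", cl$id),
                   "promtok_parse_error")
    }
    clusters[[length(clusters) + 1L]] <<- cl
  }
  for (ln in lines) {
    if (startsWith(ln, ">Cluster")) {
      flush(current)
      current <- list(id = sprintf("C%04d", length(clusters) + 1L),
                      representative_id = NA_character_,
                      member_ids = character(0))
    } else {
      if (is.null(current)) {
        stop_promtok("member line before any >Cluster header",
                     "promtok_parse_error")
      }
      m <- regmatches(ln, regexec(">([^ .]+)", ln))[[1]]
      if (length(m) < 2) {
        stop_promtok(sprintf("cannot parse member line: %s", ln),
                     "promtok_parse_error")
      }
      id <- m[2]
      current$member_ids <- c(current$member_ids, id)
      if (grepl("\\*\\s*$", ln)) current$representative_id <- id
    }
  }
  flush(current)
  clusters
}

#' Size-ascending cluster-accumulation split
#'
#' Clusters are sorted by size ascending (ties by representative id) and
#' assigned whole, smallest first: to the test set until its target count is
#' reached, then to validation, with everything remaining (including all
#' large families) going to train. A cluster that crosses a target boundary
#' stays whole in the set being filled, which is why achieved fractions can
#' deviate slightly from the targets.
#'
#' @param clusters list of clusters from [greedy_cluster()] or [read_clstr()].
#' @param fractions numeric `(train, validation, test)` targets summing to 1
#'   (default `c(0.65, 0.15, 0.20)`).
#' @return a `split_assignment` data frame (`id`, `partition`, `cluster_id`)
#'   with attribute `achieved_fractions`.
#' @export
accumulate_split <- function(clusters, fractions = c(0.65, 0.15, 0.20)) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  if (length(clusters) == 0) {
    return(structure(data.frame(id = character(0), partition = character(0),
                                cluster_id = character(0)),
                     achieved_fractions = c(train = NA, validation = NA,
                                            test = NA),
                     class = c("split_assignment", "data.frame")))
  }
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), 1L)
  reps <- vapply(clusters, `[[`, "", "representative_id")
  ord <- order(sizes, reps)
  total <- sum(sizes)
  target_test <- fractions[3] * total
  target_val <- fractions[2] * total
  part <- character(length(clusters))
  cum <- 0; phase <- "test"
  for (j in ord) {
    if (phase == "test") {
      part[j] <- "test"; cum <- cum + sizes[j]
      if (cum >= target_test) { phase <- "validation"; cum <- 0 }
    } else if (phase == "validation") {
      part[j] <- "validation"; cum <- cum + sizes[j]
      if (cum >= target_val) phase <- "train"
    } else {
      part[j] <- "train"
    }
  }
  if (!"train" %in% part && length(clusters) >= 1) {
    warning("degenerate split: no cluster reached the training set")
  }
  rows <- do.call(rbind, lapply(seq_along(clusters), function(j) {
    data.frame(id = clusters[[j]]$member_ids, partition = part[j],
               cluster_id = clusters[[j]]$id, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  counts <- c(train = sum(rows$partition == "train"),
              validation = sum(rows$partition == "validation"),
              test = sum(rows$partition == "test"))
  structure(rows, achieved_fractions = counts / total,
            class = c("split_assignment", "data.frame"))
}

#' Propagate partitions from positives to their paired negatives
#'
#' @param assignment a `split_assignment` covering the positive ids.
#' @param windows a `promoter_windows` data frame containing the negatives
#'   (and possibly the positives).
#' @return the assignment extended with one row per negative, inheriting its
#'   paired positive's partition.
#' @export
propagate_pairs <- function(assignment, windows) {
  negs <- windows[windows$label == "negative", , drop = FALSE]
  if (nrow(negs) == 0) return(assignment)
  idx <- match(negs$paired_positive_id, assignment$id)
  if (anyNA(idx)) {
    stop_promtok(sprintf("negative '%s' has no assigned paired positive",
                         negs$id[which(is.na(idx))[1]]),
                 "promtok_pairing_error")
  }
  extra <- data.frame(id = negs$id, partition = assignment$partition[idx],
                      cluster_id = assignment$cluster_id[idx],
                      stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(assignment), extra)
  rownames(out) <- NULL
  structure(out, achieved_fractions = attr(assignment, "achieved_fractions"),
            class = c("split_assignment", "data.frame"))
}

#' Filter an external-organism set against a training pool
#'
#' Drops external sequences containing 'N', clusters the union of external
#' and training sequences, and keeps only external sequences whose cluster
#' contains no training member (single-member with respect to training).
#'
#' @param external,training_pool `promoter_windows` data frames.
#' @param threshold identity threshold (default 0.80).
#' @return the retained rows of `external`.
#' @export
filter_external <- function(external, training_pool, threshold = 0.80) {
  keep <- !grepl("N", external$sequence, fixed = TRUE)
  external <- external[keep, , drop = FALSE]
  if (nrow(external) == 0) {
    attr(external, "filtered") <- TRUE
    return(external)
  }
  pool <- c(setNames(external$sequence, external$id),
            setNames(training_pool$sequence, training_pool$id))
  clusters <- greedy_cluster(pool, threshold)
  train_ids <- training_pool$id
  ok <- unlist(lapply(clusters, function(cl) {
    if (any(cl$member_ids %in% train_ids)) character(0) else cl$member_ids
  }))
  out <- external[external$id %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filtered") <- TRUE
  out
}

#' Write / read a split manifest TSV
#' @param assignment a `split_assignment`.
#' @param path file path.
#' @return `read_split_manifest` returns a `split_assignment`.
#' @export
write_split_manifest <- function(assignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(), con)
  writeLines("id\tpartition\tcluster_id", con)
  writeLines(sprintf("%s\t%s\t%s", assignment$id, assignment$partition,
                     assignment$cluster_id), con)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body[-1], "\t")
  df <- data.frame(id = vapply(parts, `[`, "", 1),
                   partition = vapply(parts, `[`, "", 2),
                   cluster_id = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  structure(df, class = c("split_assignment", "data.frame"))
}
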