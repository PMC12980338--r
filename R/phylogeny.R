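#' Phylogeny tables
#'
#' A `phylo_table` holds an ordered set of organism names and a symmetric
#' matrix of divergence times (arbitrary MYA-like units). Distances are
#' ultrametric by construction: every table is derived from a rooted tree and
#' `d(a, b)` is the height of the most recent common ancestor of `a` and `b`.
#'
#' @name phylo_table
NULL

new_phylo_table <- function(organisms, distance) {
  stopifnot(is.character(organisms), is.matrix(distance))
  dimnames(distance) <- list(organisms, organisms)
  obj <- structure(list(organisms = organisms, distance = distance),
                   class = "phylo_table")
  validate_phylo_table(obj)
}

validate_phylo_table <- function(x) {
  d <- x$distance
  n <- length(x$organisms)
  if (!all(dim(d) == c(n, n))) {
    stop_promtok("distance matrix dimensions do not match organisms",
                 "promtok_invalid_phylogeny")
  }
  if (any(d < 0) || any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0)) {
    stop_promtok("distance matrix must be symmetric, non-negative, zero-diagonal",
                 "promtok_invalid_phylogeny")
  }
  x
}

#' @export
print.phylo_table <- function(x, ...) {
  cat(sprintf("<phylo_table> %d organisms: %s\n",
              length(x$organisms), paste(x$organisms, collapse = ", ")))
  invisible(x)
}

# Divergence-height presets. Heights encode the ordinal structure of the
# TimeTree-style divergence ranking used for curriculum construction: the
# nearest-4 set of the reference organism ("hsapiens") is
# {hsapiens, mmulatta, mmusculus, rnorvegicus}. Values are indicative MYA.
.preset_heights <- function() {
  list(
    list(c("hsapiens", "mmulatta"), 29),
    list(c("mmusculus", "rnorvegicus"), 21),
    list(c("hsapiens", "mmusculus"), 87),       # primates vs murid rodents
    list(c("hsapiens", "cfamiliaris"), 94),     # + carnivores
    list(c("hsapiens", "ggallus"), 319),        # + birds
    list(c("hsapiens", "drerio"), 429),         # + teleost fish
    list(c("dmelanogaster", "celegans"), 590),
    list(c("hsapiens", "dmelanogaster"), 686)   # deuterostome/protostome root
  )
}

.build_preset <- function(organisms) {
  # union-find agglomeration over the preset height list
  parent <- seq_along(organisms)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- matrix(0, length(organisms), length(organisms),
              dimnames = list(organisms, organisms))
  for (ev in .preset_heights()) {
    pair <- ev[[1]]; h <- ev[[2]]
    if (!all(pair %in% organisms)) next
    i <- find(match(pair[1], organisms)); j <- find(match(pair[2], organisms))
    if (i == j) next
    a <- organisms[vapply(seq_along(organisms), find, 1L) == i]
    b <- organisms[vapply(seq_along(organisms), find, 1L) == j]
    d[a, b] <- h; d[b, a] <- h
    parent[j] <- i
  }
  new_phylo_table(organisms, d)
}

phylo_presets <- function() {
  epd8 <- c("hsapiens", "mmulatta", "mmusculus", "rnorvegicus",
            "ggallus", "dmelanogaster", "drerio", "celegans")
  list(epd8 = epd8, epd9 = c(epd8, "cfamiliaris"))
}

#' Generate or look up a phylogeny table
#'
#' Random tables are built by random sequential agglomeration: leaves start at
#' height zero and random pairs of clades merge at strictly increasing
#' heights, so the resulting divergence matrix is ultrametric. The `"epd8"`
#' preset returns eight organisms whose distance ranking from the reference
#' (`hsapiens`) places `mmulatta`, `mmusculus` and `rnorvegicus` closest;
#' `"epd9"` adds `cfamiliaris` as an external-validation organism.
#'
#' @param n number of organisms (ignored when `preset` is given); must be >= 2.
#' @param seed integer seed for the random tree.
#' @param preset optional preset name (`"epd8"` or `"epd9"`).
#' @return a `phylo_table`.
#' @export
generate_phylogeny <- function(n = 8, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    presets <- phylo_presets()
    if (!preset %in% names(presets)) {
      stop_promtok(sprintf("unknown phylogeny preset '%s'", preset),
                   "promtok_lookup_error")
    }
    return(.build_preset(presets[[preset]]))
  }
  if (n < 2) stop_promtok("need at least 2 organisms", "promtok_invalid_size")
  organisms <- sprintf("org%02d", seq_len(n))
  with_seed(seed, {
    groups <- as.list(seq_len(n))
    d <- matrix(0, n, n)
    h <- 0
    while (length(groups) > 1) {
      h <- h + runif(1, 10, 100)
      ij <- sample(length(groups), 2)
      a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
      d[a, b] <- h; d[b, a] <- h
      groups[[ij[1]]] <- c(a, b)
      groups[[ij[2]]] <- NULL
    }
    new_phylo_table(organisms, d)
  })
}

#' Nearest species by divergence time
#'
#' Returns the `m` organisms with the smallest divergence from `target`,
#' always including the target itself (distance zero). Ties are broken by
#' organism name, ascending.
#'
#' @param phylo a `phylo_table`.
#' @param target organism name present in the table.
#' @param m subset size (default 4, the curriculum's late-phase size).
#' @return character vector of `m` organism names, sorted by distance.
#' @export
nearest_species <- function(phylo, target, m = 4) {
  stopifnot(inherits(phylo, "phylo_table"))
  if (!target %in% phylo$organisms) {
    stop_promtok(sprintf("organism '%s' not in phylogeny", target),
                 "promtok_lookup_error")
  }
  if (m > length(phylo$organisms)) {
    stop_promtok("m exceeds number of organisms", "promtok_invalid_size")
  }
  dist <- phylo$distance[target, ]
  ord <- order(dist, names(dist))
  names(dist)[ord][seq_len(m)]
}
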