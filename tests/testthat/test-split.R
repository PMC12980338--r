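test_that("pairwise identity counts matching non-N positions", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("acgt", "ACGT"), 1.0)  # case-insensitive
  expect_equal(pairwise_identity("ANGT", "ANGT"), 0.75) # N matches nothing
  a <- random_dna(1, 601, seed = 1)
  ch <- promtok:::seq_to_chars(a)
  flip <- sample(601, 120)
  ch[flip] <- vapply(ch[flip], function(x) setdiff(c("A","C","G","T"), x)[1], "")
  expect_equal(pairwise_identity(a, promtok:::chars_to_seq(ch)), 481 / 601)
  expect_error(pairwise_identity("ACG", "ACGT"), class = "promtok_length_error")
})

test_that("greedy clustering handles degenerate corpora", {
  seqs <- setNames(rep(strrep("ACGT", 25), 5), paste0("s", 1:5))
  cl <- greedy_cluster(seqs)
  expect_length(cl, 1)
  expect_equal(sort(cl[[1]]$member_ids), paste0("s", 1:5))
  # mutually dissimilar sequences stay singletons
  distinct <- setNames(c(strrep("A", 100), strrep("C", 100),
                         strrep("G", 100)), c("a", "b", "c"))
  expect_length(greedy_cluster(distinct), 3)
  expect_length(greedy_cluster(setNames(character(0), character(0))), 0)
})

test_that("greedy clustering recovers planted redundancy families", {
  base <- windows_from_seqs(random_dna(12, 601, seed = 6))
  win <- inject_redundancy(base, family_count = 3, family_size = 4,
                           identity = 0.9, seed = 13)
  cl <- greedy_cluster(setNames(win$sequence, win$id))
  # oracle: the planted family labels
  for (f in 1:3) {
    fam_ids <- win$id[which(win$family == f)]
    holding <- vapply(cl, function(c0) any(fam_ids %in% c0$member_ids), TRUE)
    expect_equal(sum(holding), 1)  # family never straddles clusters
    expect_setequal(cl[[which(holding)]]$member_ids, fam_ids)
  }
})

test_that(".clstr files round-trip through the parser", {
  path <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(
    ">Cluster 0",
    "0\t601nt, >hsapiens_p0001... *",
    "1\t601nt, >hsapiens_p0002... at +/98.17%",
    ">Cluster 1",
    "0\t601nt, >mmulatta_p0001... *"), path)
  cl <- read_clstr(path)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$representative_id, "hsapiens_p0001")
  expect_setequal(cl[[1]]$member_ids, c("hsapiens_p0001", "hsapiens_p0002"))
  expect_equal(cl[[2]]$member_ids, "mmulatta_p0001")
  # empty file -> no clusters
  empty <- withr::local_tempfile(fileext = ".clstr")
  writeLines(character(0), empty)
  expect_length(read_clstr(empty), 0)
  # missing representative marker
  bad <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0", "0\t601nt, >x..."), bad)
  expect_error(read_clstr(bad), class = "promtok_parse_error")
  # member line before any header
  bad2 <- withr::local_tempfile(fileext = ".clstr")
  writeLines("0\t601nt, >x... *", bad2)
  expect_error(read_clstr(bad2), class = "promtok_parse_error")
})

make_clusters <- function(sizes) {
  lapply(seq_along(sizes), function(i) {
    ids <- sprintf("c%02d_m%02d", i, seq_len(sizes[i]))
    list(id = sprintf("C%04d", i), representative_id = ids[1],
         member_ids = ids)
  })
}

test_that("size-ascending accumulation fills test, then validation, then train", {
  # sizes 1,1,2,2,4,10 with total 20: test target 4 -> {1,1,2};
  # validation target 3 -> {2,4} (overshoot kept whole); train -> {10}
  cl <- make_clusters(c(1, 1, 2, 2, 4, 10))
  asg <- accumulate_split(cl, c(0.65, 0.15, 0.20))
  sizes_by <- function(part) {
    tab <- table(asg$cluster_id[asg$partition == part])
    sort(as.integer(tab))
  }
  expect_equal(sizes_by("test"), c(1, 1, 2))
  expect_equal(sizes_by("validation"), c(2, 4))
  expect_equal(sizes_by("train"), 10)
  expect_equal(unname(attr(asg, "achieved_fractions")),
               c(10, 6, 4) / 20)
})

test_that("a single dominating cluster yields a degenerate split with warning", {
  cl <- make_clusters(30)
  expect_warning(asg <- accumulate_split(cl), "degenerate")
  expect_true(all(asg$partition == "test"))
})

test_that("no cluster ever spans two partitions", {
  set.seed(42)
  for (rep_i in 1:5) {
    sizes <- sample(1:15, 12, replace = TRUE)
    asg <- accumulate_split(make_clusters(sizes))
    spans <- tapply(asg$partition, asg$cluster_id,
                    function(x) length(unique(x)))
    expect_true(all(spans == 1))
  }
})

test_that("the split is a deterministic function of its inputs", {
  sizes <- c(3, 1, 4, 1, 5, 9, 2, 6)
  a <- accumulate_split(make_clusters(sizes))
  b <- accumulate_split(make_clusters(sizes))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("negatives follow their paired positive's partition", {
  pos <- small_positives()
  neg <- build_negative_set(pos, strategy = "shuffled", seed = 2)
  cl <- greedy_cluster(setNames(pos$sequence, pos$id))
  asg <- accumulate_split(cl)
  full <- propagate_pairs(asg, neg)
  m <- match(neg$paired_positive_id, asg$id)
  expect_equal(full$partition[match(neg$id, full$id)], asg$partition[m])
  # class balance per partition
  for (part in unique(full$partition)) {
    ids <- full$id[full$partition == part]
    expect_equal(sum(ids %in% pos$id), sum(ids %in% neg$id))
  }
  # orphan negative
  orphan <- neg[1, ]; orphan$id <- "orphan"; orphan$paired_positive_id <- "nope"
  expect_error(propagate_pairs(asg, promtok:::rbind_windows(pos, orphan)),
               class = "promtok_pairing_error")
})

test_that("external filtering drops N-containing and training-like sequences", {
  train <- windows_from_seqs(random_dna(6, 601, seed = 21), organism = "hsapiens")
  ext_seqs <- random_dna(4, 601, seed = 22)
  ext_seqs[2] <- train$sequence[1]                       # identical to training
  ch <- promtok:::seq_to_chars(ext_seqs[3]); ch[5] <- "N" # contains N
  ext_seqs[3] <- promtok:::chars_to_seq(ch)
  ext <- windows_from_seqs(ext_seqs, organism = "cfamiliaris", prefix = "x")
  kept <- filter_external(ext, train)
  expect_setequal(kept$id, c("x0001", "x0004"))
  expect_true(isTRUE(attr(kept, "filtered")))
})

test_that("no leakage: test sequences stay below threshold identity to train", {
  base <- windows_from_seqs(random_dna(40, 601, seed = 30))
  win <- inject_redundancy(base, family_count = 5, family_size = 4,
                           identity = 0.9, seed = 31)
  cl <- greedy_cluster(setNames(win$sequence, win$id))
  asg <- accumulate_split(cl)
  te <- win$sequence[win$id %in% asg$id[asg$partition == "test"]]
  tr <- win$sequence[win$id %in% asg$id[asg$partition != "test"]]
  worst <- max(vapply(te, function(a) {
    max(vapply(tr, function(b) pairwise_identity(a, b), 1))
  }, 1))
  expect_lt(worst, 0.80)
})

test_that("split manifests round-trip", {
  asg <- accumulate_split(make_clusters(c(1, 2, 3, 4, 5, 15)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(asg, path)
  back <- read_split_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(asg),
               ignore_attr = TRUE)
})
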