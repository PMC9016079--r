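# Exhaustive oracle for the one-mismatch collapse on tiny inputs:
# enumerate all pairwise Hamming distances, apply the same directional
# ordering rule by explicit bookkeeping, then the conflict rule.
oracle_collapse <- function(calls) {
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  calls <- calls[order(-calls$n_reads, calls$umi), , drop = FALSE]
  cluster <- rep(NA_integer_, nrow(calls))
  seeds <- integer(0)
  for (i in seq_len(nrow(calls))) {
    placed <- FALSE
    for (s in seeds) {
      if (hd(calls$umi[i], calls$umi[s]) <= 1) {
        cluster[i] <- cluster[s]; placed <- TRUE; break
      }
    }
    if (!placed) { cluster[i] <- length(seeds) + 1L; seeds <- c(seeds, i) }
  }
  keep <- lapply(unique(cluster), function(cl) {
    mem <- calls[cluster == cl, ]
    if (length(unique(mem$allele)) > 1L) return(NULL)
    data.frame(umi = mem$umi[1], allele = mem$allele[1],
               n_reads = sum(mem$n_reads))
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- data.frame(umi = character(0),
                                      allele = character(0),
                                      n_reads = integer(0))
  rownames(out) <- NULL
  out
}

random_calls <- function(n_umi, len = 4) {
  data.frame(umi = replicate(n_umi, paste(sample(c("A", "C", "G", "T"),
                                                 len, TRUE),
                                          collapse = "")),
             allele = sample(c("C", "T"), n_umi, TRUE),
             n_reads = sample(1:9, n_umi, TRUE))
}

test_that("per-UMI calls keep agreeing reads and drop conflicts", {
  reads <- data.frame(
    umi = c("u1", "u1", "u1", "u2", "u2", "u2", "u3"),
    allele = c("A", "A", "A", "A", "A", "G", "A"),
    n_reads = 1L,
    transcript_assigned = c(rep(TRUE, 6), FALSE))
  calls <- call_umi_alleles(reads)
  expect_equal(calls$umi, "u1")          # u2 conflicted, u3 unassigned
  expect_equal(calls$allele, "A")
  expect_equal(calls$n_reads, 3L)
  expect_equal(nrow(call_umi_alleles(reads[reads$umi == "u3", ])), 0L)
})

test_that("one-mismatch collapsing merges, separates and removes conflicts", {
  # distance 1, same allele: absorbed into the better-supported UMI
  calls <- data.frame(umi = c("AAAA", "AAAT"), allele = "A",
                      n_reads = c(3L, 1L))
  out <- collapse_umis(calls)
  expect_equal(out, data.frame(umi = "AAAA", allele = "A", n_reads = 4L))
  # distance 4: untouched
  calls2 <- data.frame(umi = c("AAAA", "TTTT"), allele = "A",
                       n_reads = c(2L, 2L))
  expect_equal(nrow(collapse_umis(calls2)), 2L)
  # distance 1 but different alleles: merged group removed entirely
  calls3 <- data.frame(umi = c("AAAA", "AAAT"), allele = c("A", "G"),
                       n_reads = c(3L, 1L))
  expect_equal(nrow(collapse_umis(calls3)), 0L)
  expect_error(collapse_umis(data.frame(umi = c("AAAA", "AA"),
                                        allele = "A", n_reads = 1L)),
               "unequal")
})

test_that("collapsing matches the exhaustive oracle on random UMI sets", {
  set.seed(13)
  for (i in 1:25) {
    calls <- random_calls(sample(2:8, 1))
    calls <- calls[!duplicated(calls$umi), , drop = FALSE]
    expect_equal(collapse_umis(calls), oracle_collapse(calls))
  }
})

test_that("collapsing is order-independent given unique support maxima", {
  set.seed(17)
  for (i in 1:20) {
    calls <- random_calls(6)
    calls <- calls[!duplicated(calls$umi), , drop = FALSE]
    calls$n_reads <- sample(seq_len(nrow(calls)) * 3L)  # unique counts
    ref <- collapse_umis(calls)
    perm <- calls[sample(nrow(calls)), , drop = FALSE]
    expect_equal(collapse_umis(perm), ref)
  }
})

test_that("a conflict-free, well-separated UMI set passes through unchanged", {
  calls <- data.frame(umi = c("AAAA", "CCCC", "GGGG", "TTTT"),
                      allele = c("C", "C", "T", "T"),
                      n_reads = c(4L, 2L, 7L, 1L))
  out <- collapse_umis(calls)
  expect_setequal(out$umi, calls$umi)
  expect_equal(sum(out$n_reads), sum(calls$n_reads))
})

test_that("surviving UMIs never exceed the distinct (cell, UMI) pairs", {
  set.seed(23)
  for (i in 1:10) {
    reads <- data.frame(
      cell_barcode = sample(c("c1", "c2"), 20, TRUE),
      umi = replicate(20, paste(sample(c("A", "C"), 3, TRUE),
                                collapse = "")),
      chrom = "chr1", pos = 10L,
      allele = sample(c("C", "T"), 20, TRUE),
      n_reads = 1L, transcript_assigned = TRUE)
    calls <- umi_allele_calls(reads)
    n_pairs <- nrow(unique(reads[, c("cell_barcode", "umi")]))
    expect_lte(nrow(calls), n_pairs)
  }
})

test_that("pseudo-bulk aggregation counts collapsed UMIs per subject", {
  calls <- data.frame(
    cell_barcode = c("c1", "c1", "c1", "c2"),
    chrom = "chr1", pos = 10L,
    umi = c("AAA", "CCC", "GGG", "AAA"),   # AAA reappears in another cell
    allele = c("A", "A", "B", "A"))
  map <- data.frame(cell_barcode = c("c1", "c2"),
                    subject_id = "S", cell_type = "neuron")
  agg <- aggregate_to_subject(calls, map)
  expect_equal(agg$count[agg$allele == "A"], 3L)  # per-cell UMI identity
  expect_equal(agg$count[agg$allele == "B"], 1L)

  expect_message(
    agg2 <- aggregate_to_subject(calls, map[1, , drop = FALSE]),
    "unmapped")
  expect_equal(sum(agg2$count), 3L)
  expect_error(aggregate_to_subject(calls, rbind(map, map[1, ])),
               "duplicate")
  expect_equal(nrow(aggregate_to_subject(calls[0, ], map)), 0L)
})
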