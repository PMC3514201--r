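# k-mer index, seed-and-verify mapping, pileups, voting correction.

test_that("k-mer index stores every occurrence as a couple", {
  idx <- build_kmer_index(c(s1 = "ATCA"), k = 3)
  expect_identical(lookup_kmer(idx, "ATC"), data.frame(sid = 1L, pos = 0L))
  expect_identical(lookup_kmer(idx, "TCA"), data.frame(sid = 1L, pos = 1L))
  expect_identical(nrow(lookup_kmer(idx, "GGG")), 0L)
  # a repeated k-mer yields one couple per occurrence
  idx2 <- build_kmer_index(c(a = "AAAA"), k = 3)
  expect_identical(lookup_kmer(idx2, "AAA"), data.frame(sid = 1L, pos = c(0L, 1L)))
  # sequence shorter than k indexes nothing
  idx3 <- build_kmer_index(c(a = "AT"), k = 3)
  expect_identical(length(idx3$keys), 0L)
  expect_error(build_kmer_index(c(a = "ACGT"), k = 0), "k must be")
})

# Brute-force mapping oracle: all placements passing the mapping predicate
# that are discoverable through at least one exact shared k-mer consistent
# with the placement (the operation's seed-and-verify contract).
brute_map <- function(target, read, k, d) {
  hits <- list()
  for (strand in c("+", "-")) {
    rt <- if (strand == "+") read else reverse_complement(read)
    if (nchar(rt) < k) next
    for (i in (-nchar(rt) + 1):(nchar(target) - 1)) {
      if (!is_mapped(target, i, rt, d, min_overlap = k)) next
      seeded <- FALSE
      for (p in 0:(nchar(rt) - k)) {
        tpos <- i + p
        if (tpos < 0 || tpos + k > nchar(target)) next
        if (substr(rt, p + 1, p + k) == substr(target, tpos + 1, tpos + k)) {
          seeded <- TRUE
          break
        }
      }
      if (seeded) hits[[length(hits) + 1L]] <- list(offset = i, strand = strand)
    }
  }
  hits
}

test_that("map_reads equals brute-force seeded placement enumeration", {
  set.seed(10)
  for (rep in 1:60) {
    k <- sample(3:4, 1)
    target <- paste(sample(c("A", "C", "G", "T"), sample(6:12, 1),
      replace = TRUE), collapse = "")
    read <- paste(sample(c("A", "C", "G", "T"), sample(3:9, 1),
      replace = TRUE), collapse = "")
    d <- sample(0:2, 1)
    idx <- build_kmer_index(c(tg = target), k)
    got <- map_reads(c(r = read), idx, d = d)
    want <- brute_map(target, read, k, d)
    got_key <- sort(paste(got$offset, got$strand))
    want_key <- sort(vapply(want, function(h) paste(h$offset, h$strand),
      character(1)))
    expect_identical(got_key, want_key)
  }
})

test_that("map_reads finds the expected example placements", {
  idx <- build_kmer_index(c(tg = "ACGTACGT"), 3)
  m <- map_reads(c(r = "CGTA"), idx, d = 0)
  expect_setequal(m$offset[m$strand == "+"], c(1L, 5L))
  idx2 <- build_kmer_index(c(tg = "ACGTT"), 3)
  m2 <- map_reads(c(r = "AACGT"), idx2, d = 0)
  rev_hit <- m2[m2$strand == "-", ]
  expect_identical(rev_hit$offset, 0L)
  expect_identical(rev_hit$text, "ACGTT")  # stored oriented to the target
  idx3 <- build_kmer_index(c(tg = "AAAA"), 3)
  m3 <- map_reads(c(r = "TTTT"), idx3, d = 0)
  expect_identical(sort(m3$offset), c(-1L, 0L, 1L))
  expect_true(all(m3$strand == "-"))
})

test_that("mapping streams files identically to in-memory reads", {
  set.seed(11)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  sim <- simulate_reads(ref, 30, 10, 0.01, seed = 12)
  idx <- build_kmer_index(c(ref = substr(ref, 31, 80)), 15)
  mem <- map_reads(stats::setNames(sim$reads$text, sim$reads$read_id), idx, d = 1)
  fa <- tempfile(fileext = ".fasta")
  fq_gz <- tempfile(fileext = ".fastq.gz")
  write_reads_fasta(sim, fa)
  write_reads_fastq(sim, fq_gz)
  from_fa <- map_reads(fa, idx, d = 1, chunk_records = 7)  # odd chunking
  from_fq <- map_reads(fq_gz, idx, d = 1)
  key <- function(m) sort(paste(m$read_id, m$offset, m$strand))
  expect_identical(key(from_fa), key(mem))
  expect_identical(key(from_fq), key(mem))
  expect_identical(attr(from_fa, "n_records"), nrow(sim$reads))
})

test_that("pileup tallies columns and conserves count mass", {
  m <- mapped_tbl(c("AC", "CC"), c(0, 0))
  p <- build_pileup(m)
  td <- tidy(p)
  expect_identical(td$A, c(1L, 0L))
  expect_identical(td$C, c(1L, 2L))
  # duplication: two identical reads double every column
  p2 <- build_pileup(mapped_tbl(c("ACG", "ACG"), c(0, 0)))
  expect_true(all(tidy(p2)$depth == 2))
  expect_identical(ncol(build_pileup(mapped_tbl(character(0), integer(0)))$counts), 0L)
  # conservation incl. negative offsets and overhangs
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    texts <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE),
        collapse = "")
    }, character(1))
    offs <- sample(-3:6, n, replace = TRUE)
    p3 <- build_pileup(mapped_tbl(texts, offs))
    expect_identical(sum(p3$counts), sum(nchar(texts)))
    expect_identical(p3$origin, min(offs))
  }
})

test_that("voting correction substitutes a unique winner and truncates ambiguity", {
  # unique alternative above threshold -> substituted
  m <- mapped_tbl(c(rep("A", 5), "C"), rep(0, 6))
  cr <- correct_mapped_reads(m, build_pileup(m), t = 2, target = "A", d = 1,
    min_len = 1)
  expect_identical(unique(cr$text), "A")
  # own nucleotide already at threshold -> unchanged
  m2 <- mapped_tbl(rep("A", 3), rep(0, 3))
  cr2 <- correct_mapped_reads(m2, build_pileup(m2), t = 2, target = "A", d = 0,
    min_len = 1)
  expect_identical(cr2$text, m2$text)
  # three-way tie below threshold at position 5 -> truncation to 4 chars
  m3 <- mapped_tbl(c("AAAAA", "AAAAC", "AAAAG"), rep(0, 3))
  cr3 <- correct_mapped_reads(m3, build_pileup(m3), t = 2, target = "AAAAA",
    d = 0, min_len = 1)
  expect_identical(unique(cr3$text), "AAAA")
  # truncation below the minimum length drops the read
  cr4 <- correct_mapped_reads(m3, build_pileup(m3), t = 2, target = "AAAAA",
    d = 0, min_len = 5)
  expect_identical(nrow(cr4), 0L)
})

test_that("correction is idempotent against the same pileup", {
  set.seed(14)
  for (rep in 1:10) {
    ref <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    sim <- simulate_reads(ref, 12, 8, 0.05, seed = rep)
    m <- mapped_tbl(ifelse(sim$reads$strand == "-",
      reverse_complement(sim$reads$text), sim$reads$text), sim$reads$start)
    pu <- build_pileup(m)
    once <- correct_mapped_reads(m, pu, t = 2, target = ref, d = 12, min_len = 1)
    twice <- correct_mapped_reads(once, pu, t = 2, target = ref, d = 12,
      min_len = 1)
    expect_identical(twice$text, once$text)
  }
})

test_that("correction removes nearly all substitution errors at ample coverage", {
  set.seed(15)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  sim <- simulate_reads(ref, 50, 40, 0.01, seed = 16)   # coverage >= 2t
  oriented <- ifelse(sim$reads$strand == "-",
    reverse_complement(sim$reads$text), sim$reads$text)
  m <- mapped_tbl(oriented, sim$reads$start, ids = sim$reads$read_id)
  pu <- build_pileup(m)
  cr <- correct_mapped_reads(m, pu, t = 5, target = ref, d = 50, min_len = 10)
  # count erroneous positions surviving within corrected reads
  bad_before <- 0L; bad_after <- 0L
  for (i in seq_len(nrow(cr))) {
    row <- cr[i, ]
    truth <- substr(ref, row$offset + 1, row$offset + nchar(row$text))
    bad_after <- bad_after + overlap_hamming(truth, 0L, row$text)
  }
  for (i in seq_len(nrow(m))) {
    truth <- substr(ref, m$offset[i] + 1, m$offset[i] + nchar(m$text[i]))
    bad_before <- bad_before + overlap_hamming(truth, 0L, m$text[i])
  }
  expect_gt(bad_before, 50)          # errors were actually planted
  expect_lt(bad_after / bad_before, 0.01)
})
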