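# Sub-starter enumeration: worked cases, oracle equivalence, the live
# candidate bound and invariant re-checks.

test_that("identical perfect copies yield exactly the starter as sub-starter", {
  s <- "ACGTAC"
  m <- mapped_tbl(rep(s, 4), rep(0, 4))
  ss <- find_substarters(m, s, c_min = 2, d = 1)
  expect_identical(ss$substarter, s)
  expect_identical(ss$distance, 0L)
  expect_identical(ss$min_coverage, 4L)
  expect_true(is_read_coherent(ss))
  expect_false(is_read_coherent(find_substarters(
    mapped_tbl(character(0), integer(0)), s, 2, 1)))
})

test_that("phased sites give the two haplotypes; distant sites give all four combinations", {
  # sites within every read: only the two phased consensuses
  s <- "ACGTA"
  m <- mapped_tbl(c("ACGTA", "ACGTA", "AGGTC", "AGGTC"), rep(0, 4))
  ss <- find_substarters(m, s, c_min = 2, d = 2)
  expect_setequal(ss$substarter, c("ACGTA", "AGGTC"))
  bf <- brute_force_substarters(m, s, c_min = 2, d = 2)
  expect_setequal(bf$substarter, ss$substarter)
  # sites farther apart than any read: the 2x2 allele combinations appear
  cs <- make_two_site_case(span = 50, site_positions = c(4, 45),
    alleles = list(c("A", "C"), c("G", "T")), read_length = 14,
    depth_per_haplotype = 2, seed = 101)
  idx <- build_kmer_index(c(st = cs$truth$starter), 7)
  m2 <- map_reads(stats::setNames(cs$reads$text, cs$reads$read_id), idx, d = 2)
  # forward placements only: this check is about the enumeration, not about
  # chance reverse-strand matches of short reads at small k
  m2 <- m2[m2$target == "st" & m2$strand == "+", ]
  ss2 <- find_substarters(m2, cs$truth$starter, c_min = 2, d = 2)
  expect_identical(nrow(ss2), 4L)
  expect_identical(sort(ss2$distance), c(0L, 1L, 1L, 2L))
})

test_that("sweep + finalization equals the brute-force power-set oracle", {
  n_ok <- 0L
  for (seed in 1:120) {
    inst <- random_substarter_instance(seed)
    got <- find_substarters(inst$mapped, inst$s, inst$c_min, inst$d)
    want <- brute_force_substarters(inst$mapped, inst$s, inst$c_min, inst$d)
    expect_identical(got$substarter, want$substarter,
      info = sprintf("instance seed %d", seed))
    # the live candidate count respects the |Sigma|^d bound
    expect_lte(attr(got, "peak_candidates"), 4L^inst$d)
    if (nrow(got) > 0L) n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 10L)  # the instance family is not degenerate
})

test_that("returned sub-starters satisfy all three conditions independently", {
  for (seed in c(7, 42, 99)) {
    inst <- random_substarter_instance(seed)
    ss <- find_substarters(inst$mapped, inst$s, inst$c_min, inst$d)
    for (i in seq_len(nrow(ss))) {
      cons <- ss$substarter[i]
      expect_identical(nchar(cons), nchar(inst$s))
      expect_lte(overlap_hamming(inst$s, 0L, cons), inst$d)
      expect_true(all(ss$coverage[[i]] >= inst$c_min))
      rd <- ss$reads[[i]]
      for (j in seq_len(nrow(rd))) {
        expect_identical(overlap_hamming(cons, rd$offset[j], rd$text[j]), 0L)
      }
    }
  }
})

test_that("maximality filtering keeps supersets and the cap limits output", {
  # one candidate's member set contains the other's -> only the superset
  s <- "AAAA"
  m <- mapped_tbl(c("AAAA", "AAAA", "AAAA"), c(0, 0, 0))
  cands <- generate_candidate_subsets(m, s, c_min = 1, d = 0)
  out <- finalize_substarters(cands, s, c_min = 1, d = 0)
  expect_identical(out$n_reads, 3L)
  # a candidate covering only part of the starter is dropped
  m2 <- mapped_tbl(c("AA", "AA"), c(0, 0))
  out2 <- finalize_substarters(
    generate_candidate_subsets(m2, "AAAA", 1, 0), "AAAA", 1, 0)
  expect_identical(nrow(out2), 0L)
  # cap: more valid consensuses than the cap -> exactly cap returned,
  # preferring higher minimum coverage
  s3 <- "AAAAA"
  texts <- c(rep("AAAAA", 3), unlist(lapply(c("C", "G", "T"), function(b) {
    rep(paste0(b, "AAAA"), 2)
  })))
  m3 <- mapped_tbl(texts, rep(0, length(texts)))
  out3 <- find_substarters(m3, s3, c_min = 2, d = 1, cap = 2)
  expect_identical(nrow(out3), 2L)
  expect_identical(out3$substarter[1], "AAAAA")  # highest coverage first
})

test_that("read input order never changes the result", {
  for (seed in c(5, 23)) {
    inst <- random_substarter_instance(seed)
    base <- find_substarters(inst$mapped, inst$s, inst$c_min, inst$d)
    set.seed(seed + 1000)
    for (rep in 1:5) {
      perm <- inst$mapped[sample(nrow(inst$mapped)), ]
      got <- find_substarters(perm, inst$s, inst$c_min, inst$d)
      expect_identical(got$substarter, base$substarter)
      expect_identical(got$coverage, base$coverage)
    }
  }
})

test_that("the brute-force oracle guards its input size", {
  m <- mapped_tbl(rep("A", 16), rep(0, 16))
  expect_error(brute_force_substarters(m, "A", 1, 0), "15 reads")
})
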