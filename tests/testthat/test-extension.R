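# Extension computation, enrichment, node addition with convergence,
# SNP merging, simplification and consensus extraction.

test_that("extensions are gated column-by-column by coverage", {
  # three reads extend a node end; agreement on 3 columns, then support
  # drops below 2, so the trailing character is not stored
  node <- "GGTC"
  m <- mapped_tbl(c("CACTT", "TCACT", "GTCAC"), c(3, 2, 1))
  ext <- compute_extensions(node, m, c_min = 2)
  expect_length(ext, 1L)
  expect_identical(ext[[1]]$text, "ACT")
  expect_identical(ext[[1]]$coverage, c(3, 3, 2))
  # no read extends past the node
  expect_length(compute_extensions("ACGT", mapped_tbl("ACGT", 0), 2), 0L)
  expect_length(compute_extensions("ACGT", mapped_tbl(character(0), integer(0)), 2), 0L)
  # branching column: two nucleotides each reach the threshold
  m2 <- mapped_tbl(c("CGTAA", "CGTAC", "CGTGG", "CGTGT"), rep(1, 4))
  ext2 <- compute_extensions("ACGT", m2, c_min = 2)
  expect_setequal(vapply(ext2, `[[`, character(1), "text"), c("A", "G"))
})

test_that("enrichment prepends exactly the k-1 terminal characters", {
  e <- enrich_extension("GGTC", list(text = "ACT", coverage = c(3, 3, 2)), k = 3)
  expect_identical(e$text, "TCACT")
  expect_identical(enrich_extension("GGTC", "ACT", k = 1)$text, "ACT")
  expect_identical(enrich_extension("AAAA", "G", k = 4)$text, "AAAG")
  expect_error(enrich_extension("AC", "G", k = 5), "too short")
})

test_that("first extension creates one node and one edge; bubbles reconverge", {
  k <- 5
  g <- seedasm:::new_extension_graph("ACGTACGTAC", rep(1, 10), k)
  e1 <- enrich_extension("ACGTACGTAC", list(text = "TTG", coverage = rep(2, 3)), k)
  res <- add_extension_node(g, 1L, e1)
  expect_true(res$novel)
  expect_identical(nrow(res$graph$edges), 1L)
  # adding the same enriched extension from the same parent converges (i=0)
  res2 <- add_extension_node(res$graph, 1L, e1)
  expect_false(res2$novel)
  expect_identical(res2$child, res$child)
  expect_identical(length(res2$graph$nodes), 2L)
})

test_that("a planted SNP yields a two-path reconvergent bubble in graph mode", {
  fx <- snp_bubble_fixture(seed = 21)
  res <- assemble_starters(c(roi = fx$starter), fx$reads, k = 15, d = 0,
    c_min = 2, max_iterations = 30, mode = "graph")
  ag <- res$graphs[[1]]
  expect_identical(nrow(ag$nodes), 4L)
  expect_identical(nrow(ag$edges), 4L)
  branch_ids <- ag$edges$to[ag$edges$from == "root"]
  expect_length(branch_ids, 2L)
  branches <- ag$nodes[ag$nodes$id %in% branch_ids, ]
  # divergence relocated to the single SNP position
  expect_identical(branches$length, c(1L, 1L))
  expect_setequal(
    ag$edges$to[ag$edges$from %in% branch_ids],
    setdiff(ag$nodes$id, c("root", branch_ids)))
  # both alleles present with the allele characters of the two references
  expect_setequal(branches$text,
    c(substr(fx$reference, fx$snp_at, fx$snp_at),
      substr(fx$alt_reference, fx$snp_at, fx$snp_at)))
})

test_that("a repeat in three contexts shows three branches on each side", {
  set.seed(77)
  unit <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rc <- make_repeat_case(unit, n_occurrences = 3, flank_length = 80, seed = 88)
  sim <- simulate_reads(rc$reference, 40, 20, 0, seed = 89)
  res <- assemble_starters(c(rep1 = unit), sim$reads, k = 15, d = 0,
    c_min = 2, max_iterations = 30, mode = "graph")
  ag <- res$graphs[[1]]
  expect_identical(sum(ag$edges$from == "root"), 3L)
  expect_identical(sum(ag$edges$to == "root"), 3L)
  # each right branch starts spelling one of the true right flanks
  right_children <- ag$edges$to[ag$edges$from == "root"]
  starts <- vapply(right_children, function(id) {
    substr(ag$nodes$text[ag$nodes$id == id], 1, 10)
  }, character(1))
  expect_setequal(starts, substr(rc$truth$right_flanks, 1, 10))
})

test_that("a single context stays linear", {
  set.seed(78)
  unit <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rc <- make_repeat_case(unit, n_occurrences = 1, flank_length = 80, seed = 90)
  sim <- simulate_reads(rc$reference, 40, 20, 0, seed = 91)
  res <- assemble_starters(c(u = unit), sim$reads, k = 15, d = 0,
    max_iterations = 30, mode = "graph")
  ag <- res$graphs[[1]]
  expect_lte(sum(ag$edges$from == "root"), 1L)
  expect_lte(sum(ag$edges$to == "root"), 1L)
  expect_silent(linear_consensus(ag))
})

test_that("SNP merging collapses single-substitution bundles by coverage", {
  exts <- list(list(text = "ACGT", coverage = c(5, 5, 5, 5)),
               list(text = "ACTT", coverage = c(2, 2, 2, 2)))
  merged <- merge_snp_extensions(exts, enabled = TRUE)
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$text, "ACGT")
  expect_identical(merge_snp_extensions(exts, enabled = FALSE), exts)
  two_diff <- list(list(text = "ACGT", coverage = rep(1, 4)),
                   list(text = "TGCA", coverage = rep(9, 4)))
  expect_identical(merge_snp_extensions(two_diff, enabled = TRUE), two_diff)
})

# all start-to-leaf strings of a combined assembly graph
assembly_paths <- function(ag) {
  starts <- setdiff(ag$nodes$id, ag$edges$to)
  out <- character(0)
  walk <- function(id, acc) {
    acc <- paste0(acc, ag$nodes$text[ag$nodes$id == id])
    nxt <- ag$edges$to[ag$edges$from == id]
    if (length(nxt) == 0) out[[length(out) + 1L]] <<- acc
    for (ch in nxt) walk(ch, acc)
  }
  for (s in starts) walk(s, "")
  out
}

test_that("sequence mode stops at a heterozygous SNP unless merging is on", {
  fx <- snp_bubble_fixture(seed = 33)
  stopped <- assemble_starters(c(roi = fx$starter), fx$reads, k = 15, d = 0,
    max_iterations = 30, mode = "sequence", snp_merge = FALSE)
  merged <- assemble_starters(c(roi = fx$starter), fx$reads, k = 15, d = 0,
    max_iterations = 30, mode = "sequence", snp_merge = TRUE)
  con_stop <- stopped$consensus$consensus
  con_merge <- merged$consensus$consensus
  # without merging, the consensus ends before the SNP position
  loc <- regexpr(con_stop, fx$reference, fixed = TRUE)[1]
  expect_gt(loc, 0)
  expect_lt(loc + nchar(con_stop) - 1, fx$snp_at)
  # with merging, it extends through the site
  expect_gt(nchar(con_merge), nchar(con_stop))
  # sequence-mode output is a substring-extension of some graph-mode path
  graphed <- assemble_starters(c(roi = fx$starter), fx$reads, k = 15, d = 0,
    max_iterations = 30, mode = "graph")
  spelled <- assembly_paths(graphed$graphs[[1]])
  expect_true(any(vapply(spelled, function(p) {
    grepl(con_stop, p, fixed = TRUE)
  }, logical(1))))
})

test_that("simplification preserves spelled strings and is idempotent", {
  for (seed in 1:40) {
    g <- random_enriched_graph(seed)
    before <- sort(spell_paths(g))
    gs <- simplify_graph(g)
    after <- sort(spell_paths(gs))
    expect_identical(after, before, info = sprintf("graph seed %d", seed))
    again <- simplify_graph(gs)
    expect_identical(sort(spell_paths(again)), before)
    # edge overlap invariant held before simplification
    expect_true(seedasm:::edges_enriched_ok(g))
  }
})

test_that("a linear chain simplifies to a single node", {
  k <- 4
  g <- seedasm:::new_extension_graph("ACGTACG", rep(1, 7), k)
  id <- 1L
  txt <- "ACGTACG"
  for (step in 1:3) {
    e <- enrich_extension(txt, list(text = "GATC", coverage = rep(2, 4)), k)
    res <- add_extension_node(g, id, e)
    g <- res$graph
    id <- res$child
    txt <- e$text
  }
  gs <- simplify_graph(g)
  expect_identical(length(gs$nodes), 1L)
  expect_identical(seedasm:::node_of(gs, gs$root)$text,
    paste0("ACGTACG", strrep("GATC", 3)))
})

test_that("prefix factorization relocates the branch point", {
  k <- 3
  g <- seedasm:::new_extension_graph("TTTT", rep(1, 4), k)
  for (child in c("AGGT", "AGCT")) {
    e <- enrich_extension("TTTT", list(text = child, coverage = rep(2, 4)), k)
    g <- add_extension_node(g, 1L, e)$graph
  }
  gs <- simplify_graph(g)
  root_txt <- seedasm:::node_of(gs, gs$root)$text
  kids <- vapply(seedasm:::out_edges(gs, gs$root), function(id) {
    seedasm:::node_of(gs, id)$text
  }, character(1))
  expect_identical(root_txt, "TTTTAG")
  expect_setequal(kids, c("GT", "CT"))
})

test_that("linear consensus refuses branching graphs", {
  fx <- snp_bubble_fixture(seed = 21)
  res <- assemble_starters(c(roi = fx$starter), fx$reads, k = 15, d = 0,
    max_iterations = 30, mode = "graph")
  expect_error(linear_consensus(res$graphs[[1]]), "graph mode")
})
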