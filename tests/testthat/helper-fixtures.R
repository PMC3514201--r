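# Shared fixture builders. Everything is generated in code under fixed
# seeds; no fixture files are stored.

# A mapped-read tibble in the shape map_reads() returns.
mapped_tbl <- function(texts, offsets, target = "s", ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(texts))
  tibble::tibble(
    target = target,
    read_id = ids,
    text = texts,
    offset = as.integer(offsets),
    strand = "+",
    mismatches = 0L
  )
}

# Random planted-variant instance for the sub-starter oracle: a starter,
# up to d variant sites, haplotype templates within distance d, and
# error-free reads tiled from random templates at random positions.
random_substarter_instance <- function(seed) {
  set.seed(seed)
  s_len <- sample(6:12, 1)
  read_len <- sample(3:min(8, s_len), 1)
  d <- sample(0:2, 1)
  c_min <- sample(1:2, 1)
  s <- paste(sample(c("A", "C", "G", "T"), s_len, replace = TRUE), collapse = "")
  n_sites <- if (d == 0) 0L else sample(0:d, 1)
  sites <- if (n_sites > 0) sort(sample(s_len, n_sites)) else integer(0)
  # 1-2 haplotype templates over the variant sites
  n_hap <- sample(1:2, 1)
  haps <- vapply(seq_len(n_hap), function(i) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in sites) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, character(1))
  n_reads <- sample(3:8, 1)
  starts <- sample(0:(s_len - read_len), n_reads, replace = TRUE)
  hap_of <- sample(n_hap, n_reads, replace = TRUE)
  texts <- substring(haps[hap_of], starts + 1, starts + read_len)
  list(
    s = s, d = d, c_min = c_min,
    mapped = mapped_tbl(texts, starts)
  )
}

# Two-haplotype read set with one SNP planted right of the starter.
snp_bubble_fixture <- function(seed = 21, span = 260, snp_at = 200,
                               starter_from = 101, starter_to = 140,
                               read_len = 40, coverage = 15) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), span, replace = TRUE),
    collapse = "")
  alt <- if (substr(base, snp_at, snp_at) == "A") "C" else "A"
  h2 <- paste0(substr(base, 1, snp_at - 1), alt, substr(base, snp_at + 1, span))
  r1 <- simulate_reads(base, read_len, coverage, 0, seed = seed + 1)$reads
  r2 <- simulate_reads(h2, read_len, coverage, 0, seed = seed + 2)$reads
  r2$read_id <- paste0("b", r2$read_id)
  list(
    reference = base, alt_reference = h2, snp_at = snp_at,
    starter = substr(base, starter_from, starter_to),
    reads = rbind(r1, r2)
  )
}

# Random enriched extension graph for simplification properties: a random
# tree (occasionally with a reconvergent bubble) whose non-root nodes carry
# the k-1 suffix of their parent as prefix.
random_enriched_graph <- function(seed, k = 5) {
  set.seed(seed)
  root_len <- sample(k:(k + 6), 1)
  root <- paste(sample(c("A", "C", "G", "T"), root_len, replace = TRUE),
    collapse = "")
  g <- seedasm:::new_extension_graph(root, rep(1, root_len), k)
  frontier <- 1L
  n_nodes <- sample(2:8, 1)
  for (i in seq_len(n_nodes)) {
    parent <- sample(frontier, 1)
    ptext <- seedasm:::node_of(g, parent)$text
    ext_len <- sample(1:6, 1)
    ext <- paste(sample(c("A", "C", "G", "T"), ext_len, replace = TRUE),
      collapse = "")
    en <- enrich_extension(ptext, list(text = ext, coverage = rep(1, ext_len)),
      k, node_cov = seedasm:::node_of(g, parent)$cov)
    id <- g$next_id
    g$next_id <- g$next_id + 1L
    g$nodes[[as.character(id)]] <- list(text = en$text,
      cov = as.numeric(en$coverage), is_root = FALSE)
    g <- seedasm:::register_last_kmer(g, id)
    g <- seedasm:::add_edge(g, parent, id)
    frontier <- c(frontier, id)
  }
  g
}
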