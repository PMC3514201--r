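# Iterative targeted assembly: coverage-gated extension computation, k-1
# enrichment, growth of a rooted directed string graph with convergence
# detection, and graph simplification.
#
# One-sided graphs extend rightwards from a root; leftward extension is
# realised by extending the reverse complement of the root and mirroring the
# result. Until simplification, every non-root node is "enriched": its first
# k-1 characters repeat the terminal k-1 characters of the sequence it
# extends, so that k-mers spanning node boundaries remain seedable.

new_extension_graph <- function(root_text, root_cov, k) {
  g <- list(
    nodes = setNames(list(list(text = root_text,
      cov = as.numeric(root_cov), is_root = TRUE)), "1"),
    edges = data.frame(from = integer(0), to = integer(0)),
    root = 1L, next_id = 2L, k = as.integer(k), stripped = FALSE,
    root_core = nchar(root_text), last_k = list()
  )
  register_last_kmer(g, 1L)
}

node_of <- function(g, id) g$nodes[[as.character(id)]]

register_last_kmer <- function(g, id) {
  txt <- node_of(g, id)$text
  if (nchar(txt) >= g$k) {
    km <- substr(txt, nchar(txt) - g$k + 1L, nchar(txt))
    g$last_k[[km]] <- unique(c(g$last_k[[km]], id))
  }
  g
}

unregister_last_kmer <- function(g, id) {
  txt <- node_of(g, id)$text
  if (nchar(txt) >= g$k) {
    km <- substr(txt, nchar(txt) - g$k + 1L, nchar(txt))
    left <- setdiff(g$last_k[[km]], id)
    if (length(left) == 0L) g$last_k[[km]] <- NULL else g$last_k[[km]] <- left
  }
  g
}

add_edge <- function(g, from, to) {
  if (!any(g$edges$from == from & g$edges$to == to)) {
    g$edges <- rbind(g$edges, data.frame(from = from, to = to))
  }
  g
}

#' Compute coverage-gated extensions of a node from its mapped reads
#'
#' Reads mapped to `node_text` with zero mismatches whose suffix extends past
#' the node end are piled up column by column beyond the end. A column where
#' a single nucleotide reaches count `c_min` extends the current branch; a
#' column where several nucleotides each reach `c_min` splits the branch; a
#' column where no nucleotide reaches `c_min` terminates the branch without
#' storing the column.
#'
#' @param node_text Sequence of the node being extended.
#' @param mapped Tibble of reads mapped to the node at `d = 0` (columns
#'   `text`, `offset`).
#' @param c_min Minimum per-column support for a branch to survive.
#' @return List of extensions, each a list with `text` and `coverage`
#'   (per-character support counts); empty list when nothing extends.
#' @export
compute_extensions <- function(node_text, mapped, c_min) {
  node_len <- nchar(node_text)
  if (nrow(mapped) == 0L) return(list())
  ext_len <- mapped$offset + nchar(mapped$text) - node_len
  idx <- which(ext_len > 0L)
  if (length(idx) == 0L) return(list())
  tails <- substring(mapped$text[idx],
    nchar(mapped$text[idx]) - ext_len[idx] + 1L, nchar(mapped$text[idx]))
  tail_chars <- strsplit(tails, "", fixed = TRUE)
  tail_len <- nchar(tails)
  done <- list()
  branches <- list(list(text = "", cov = numeric(0), reads = seq_along(tails)))
  j <- 1L
  while (length(branches) > 0L) {
    nxt <- list()
    for (br in branches) {
      sup <- br$reads[tail_len[br$reads] >= j]
      chars <- vapply(tail_chars[sup], `[`, character(1), j)
      cnt <- table(factor(chars, levels = DNA_BASES))
      alive <- names(cnt)[cnt >= c_min]
      if (length(alive) == 0L) {
        if (nchar(br$text) > 0L) done[[length(done) + 1L]] <-
          list(text = br$text, coverage = br$cov)
      } else {
        for (b in alive) {
          nxt[[length(nxt) + 1L]] <- list(
            text = paste0(br$text, b),
            cov = c(br$cov, as.numeric(cnt[[b]])),
            reads = sup[chars == b]
          )
        }
      }
    }
    branches <- nxt
    j <- j + 1L
  }
  done
}

#' Enrich an extension with the k-1 terminal characters of its node
#'
#' Prefixing an extension with the last `k-1` characters of the sequence it
#' extends guarantees that every k-mer spanning the node boundary is
#' indexable in the next iteration.
#'
#' @param node_text Sequence being extended (`nchar >= k - 1`).
#' @param e Extension (list with `text`, `coverage`, or a plain string).
#' @param k Seed length.
#' @param node_cov Optional per-position coverage of `node_text`.
#' @return List with enriched `text` and `coverage`.
#' @export
enrich_extension <- function(node_text, e, k, node_cov = NULL) {
  if (is.character(e)) e <- list(text = e, coverage = rep(0, nchar(e)))
  stopifnot(nchar(e$text) >= 1L)
  if (k == 1L) return(e)
  if (nchar(node_text) < k - 1L) {
    stop("node too short to enrich an extension (needs >= k-1 characters)",
      call. = FALSE)
  }
  pre <- substr(node_text, nchar(node_text) - k + 2L, nchar(node_text))
  pre_cov <- if (is.null(node_cov)) rep(0, k - 1L) else
    tail(as.numeric(node_cov), k - 1L)
  list(text = paste0(pre, e$text), coverage = c(pre_cov, e$coverage))
}

#' Add an enriched extension to the graph, detecting convergence
#'
#' The extension's k-mers are probed against the index of every node's
#' terminal k-mer (in left-to-right scan order; first verified hit wins). If
#' the extension overlaps an existing node's text perfectly and is fully
#' contained in it, the path converges: at relative offset 0 the parent is
#' linked directly; at offset `i < 0` an intermediate node holding the
#' extension's unmatched prefix is inserted; at `0 < i <= k-1` the parent's
#' length-`i` suffix (duplicated in the existing node) is pruned before
#' linking. Otherwise a fresh node is created. Only fresh nodes are novel
#' (eligible for further extension); convergences are not re-extended.
#'
#' @param g Extension graph.
#' @param parent Parent node id.
#' @param e Enriched extension (list with `text`, `coverage`).
#' @param k Seed length (must equal `g$k`).
#' @return List with the updated `graph`, the `child` node id, and `novel`.
#' @export
add_extension_node <- function(g, parent, e, k = g$k) {
  stopifnot(k == g$k)
  if (is.null(node_of(g, parent))) stop("parent node absent", call. = FALSE)
  kms <- kmers_of(e$text, k)
  for (j in seq_along(kms)) {
    for (cand in g$last_k[[kms[j]]]) {
      if (identical(cand, parent)) next
      txt2 <- node_of(g, cand)$text
      i <- (nchar(txt2) - k) - (j - 1L)
      if (i > k - 1L) next
      if (overlap_length(txt2, i, e$text) < k) next
      if (overlap_hamming(txt2, i, e$text) != 0L) next
      if (i == 0L) {
        g <- add_edge(g, parent, cand)
        return(list(graph = g, child = cand, novel = FALSE))
      }
      if (i > 0L) {
        # never prune the root: its prefix is the sub-starter itself
        if (identical(parent, g$root)) next
        pn <- node_of(g, parent)
        if (nchar(pn$text) <= i) next
        g <- unregister_last_kmer(g, parent)
        pn$text <- substr(pn$text, 1L, nchar(pn$text) - i)
        pn$cov <- pn$cov[seq_len(length(pn$cov) - i)]
        g$nodes[[as.character(parent)]] <- pn
        g <- register_last_kmer(g, parent)
        g <- add_edge(g, parent, cand)
        return(list(graph = g, child = cand, novel = FALSE))
      }
      # i < 0: intermediate node with the unmatched (enriched) prefix of e
      mid_len <- (k - 1L) - i
      mid <- list(text = substr(e$text, 1L, mid_len),
        cov = as.numeric(e$coverage[seq_len(mid_len)]), is_root = FALSE)
      mid_id <- g$next_id
      g$next_id <- g$next_id + 1L
      g$nodes[[as.character(mid_id)]] <- mid
      g <- register_last_kmer(g, mid_id)
      g <- add_edge(g, parent, mid_id)
      g <- add_edge(g, mid_id, cand)
      return(list(graph = g, child = cand, novel = FALSE))
    }
  }
  id <- g$next_id
  g$next_id <- g$next_id + 1L
  g$nodes[[as.character(id)]] <- list(text = e$text,
    cov = as.numeric(e$coverage), is_root = FALSE)
  g <- register_last_kmer(g, id)
  g <- add_edge(g, parent, id)
  list(graph = g, child = id, novel = TRUE)
}

#' Merge extensions that differ by a single substitution
#'
#' When enabled and the extensions are identical except at exactly one
#' position (a SNP), they are merged into a single extension carrying the
#' nucleotide of largest coverage at that position; otherwise the input is
#' returned unchanged. Branches stopped by coverage at different columns
#' are compared over their common length (the trimmed remainder is
#' re-derived by the next iteration). Used in sequence mode to extend
#' through heterozygous sites instead of stopping.
#'
#' @param extensions List of extensions (`text`, `coverage`).
#' @param enabled Is SNP merging on?
#' @return Possibly merged list of extensions.
#' @export
merge_snp_extensions <- function(extensions, enabled) {
  if (!enabled || length(extensions) < 2L) return(extensions)
  texts <- vapply(extensions, `[[`, character(1), "text")
  len <- min(nchar(texts))
  trimmed <- substr(texts, 1L, len)
  mats <- do.call(rbind, strsplit(trimmed, "", fixed = TRUE))
  diffpos <- which(apply(mats, 2, function(col) length(unique(col)) > 1L))
  if (length(diffpos) != 1L) return(extensions)
  p <- diffpos
  covs <- vapply(extensions, function(e) as.numeric(e$coverage[p]), numeric(1))
  win <- which.max(covs)
  cov_sum <- Reduce(`+`, lapply(extensions, function(e) {
    as.numeric(e$coverage[seq_len(len)])
  }))
  cov_sum[p] <- covs[win]
  list(list(text = trimmed[win], coverage = cov_sum))
}

# Longest common prefix of a character vector.
common_prefix <- function(texts) {
  if (length(texts) == 1L) return(texts)
  n <- min(nchar(texts))
  p <- 0L
  while (p < n) {
    ch <- substr(texts, p + 1L, p + 1L)
    if (length(unique(ch)) > 1L) break
    p <- p + 1L
  }
  substr(texts[1], 1L, p)
}

#' Run the iterative extension phase for a set of sub-starters
#'
#' Each sub-starter roots two one-sided graphs: a right graph on its text
#' and a left graph on its reverse complement. Per iteration the current
#' frontier texts are indexed, reads are mapped at `d = 0` (minimum overlap
#' `k`), error-corrected by voting at threshold `t`, and extensions are
#' computed per frontier node. In `"sequence"` mode a multi-extension event
#' stores only the longest common prefix of the extensions and stops that
#' path (unless SNP merging resolves it); in `"graph"` mode every branch
#' continues. The loop ends when the frontier empties or after
#' `max_iterations`; each iteration's index is discarded before the next is
#' built.
#'
#' @param substarters Character vector of sub-starter texts, or the tibble
#'   returned by [find_substarters()].
#' @param reads A read source (vector, tibble or file paths).
#' @param k Seed length.
#' @param c_min Minimum coverage for extension columns.
#' @param t Vote threshold for error correction.
#' @param max_iterations Iteration cap (`>= 0`).
#' @param mode `"sequence"` or `"graph"`.
#' @param snp_merge Merge single-substitution extension bundles?
#' @param frontier_cap Maximum frontier nodes per iteration (pathological
#'   blowup guard; logged when hit).
#' @param chunk_records Reads per streamed chunk.
#' @return List with `graphs` (per sub-starter: list of one-sided `right`
#'   and `left` extension graphs) and `iterations` performed.
#' @export
run_extension_phase <- function(substarters, reads, k, c_min, t,
                                max_iterations = 10L,
                                mode = c("sequence", "graph"),
                                snp_merge = FALSE, frontier_cap = 1000L,
                                chunk_records = 20000L) {
  mode <- match.arg(mode)
  if (is.data.frame(substarters)) {
    texts <- substarters$substarter
    covs <- substarters$coverage
  } else {
    texts <- substarters
    covs <- lapply(texts, function(x) rep(0, nchar(x)))
  }
  src <- read_source(reads)
  graphs <- lapply(seq_along(texts), function(i) {
    list(
      right = new_extension_graph(texts[i], covs[[i]], k),
      left = new_extension_graph(reverse_complement(texts[i]),
        rev(as.numeric(covs[[i]])), k)
    )
  })
  # frontier entries: sub-starter index, side, node id
  frontier <- list()
  for (i in seq_along(graphs)) {
    frontier[[length(frontier) + 1L]] <- list(sub = i, side = "right", id = 1L)
    frontier[[length(frontier) + 1L]] <- list(sub = i, side = "left", id = 1L)
  }
  iter <- 0L
  while (length(frontier) > 0L && iter < max_iterations) {
    if (length(frontier) > frontier_cap) {
      message(sprintf("frontier capped at %d nodes (had %d)",
        frontier_cap, length(frontier)))
      frontier <- frontier[seq_len(frontier_cap)]
    }
    tnames <- vapply(frontier, function(f) {
      sprintf("s%d.%s.n%d", f$sub, f$side, f$id)
    }, character(1))
    ttexts <- vapply(frontier, function(f) {
      node_of(graphs[[f$sub]][[f$side]], f$id)$text
    }, character(1))
    index <- build_kmer_index(setNames(ttexts, tnames), k)
    mapped <- map_reads(src, index, d = 0L, chunk_records = chunk_records)
    nxt <- list()
    for (fi in seq_along(frontier)) {
      f <- frontier[[fi]]
      m <- mapped[mapped$target == tnames[fi], , drop = FALSE]
      if (nrow(m) > 0L) {
        pu <- build_pileup(m)
        m <- correct_mapped_reads(m, pu, t = t, target = ttexts[fi],
          d = 0L, min_len = k)
      }
      exts <- compute_extensions(ttexts[fi], m, c_min)
      if (length(exts) == 0L) next
      g <- graphs[[f$sub]][[f$side]]
      stop_path <- FALSE
      if (mode == "sequence" && length(exts) > 1L) {
        exts <- merge_snp_extensions(exts, snp_merge)
        if (length(exts) > 1L) {
          p <- common_prefix(vapply(exts, `[[`, character(1), "text"))
          if (nchar(p) == 0L) { graphs[[f$sub]][[f$side]] <- g; next }
          cov_sum <- Reduce(`+`, lapply(exts, function(e) {
            as.numeric(e$coverage[seq_len(nchar(p))])
          }))
          exts <- list(list(text = p, coverage = cov_sum))
          stop_path <- TRUE
        }
      }
      node_cov <- node_of(g, f$id)$cov
      for (e in exts) {
        en <- enrich_extension(ttexts[fi], e, k, node_cov = node_cov)
        res <- add_extension_node(g, f$id, en, k)
        g <- res$graph
        if (res$novel && !stop_path) {
          nxt[[length(nxt) + 1L]] <- list(sub = f$sub, side = f$side,
            id = res$child)
        }
      }
      graphs[[f$sub]][[f$side]] <- g
    }
    frontier <- nxt
    iter <- iter + 1L
  }
  list(graphs = graphs, iterations = iter)
}

# ---------------------------------------------------------------------------
# Simplification.

node_ids <- function(g) as.integer(names(g$nodes))

out_edges <- function(g, id) g$edges$to[g$edges$from == id]
in_edges <- function(g, id) g$edges$from[g$edges$to == id]

#' Simplify an extension graph
#'
#' Applies, in order: (1) strip the first `k-1` (enrichment) characters of
#' every non-root node; (2) merge simple paths: a node with a sole successor
#' whose sole predecessor it is absorbs that successor; (3) factorize the
#' longest common prefix of all children of a node that have it as sole
#' predecessor into that node's suffix, and symmetrically the longest common
#' suffix of all parents with a sole successor into that node's prefix
#' (relocating branch points to the exact divergence position). Rules 2-3
#' repeat to fixpoint. Coverage values move with their characters;
#' factorized characters carry the element-wise sum of the branch coverages.
#' The multiset of spelled root-to-leaf strings is invariant.
#'
#' @param g One-sided extension graph.
#' @param k Seed length (defaults to the graph's).
#' @return The simplified graph (`stripped` flag set).
#' @export
simplify_graph <- function(g, k = g$k) {
  if (!isTRUE(g$stripped) && k > 1L) {
    for (nm in names(g$nodes)) {
      nd <- g$nodes[[nm]]
      if (isTRUE(nd$is_root)) next
      nd$text <- substr(nd$text, k, nchar(nd$text))
      nd$cov <- nd$cov[-seq_len(k - 1L)]
      g$nodes[[nm]] <- nd
    }
  }
  g$stripped <- TRUE
  g$last_k <- list()   # stale after stripping; not needed post-assembly
  repeat {
    changed <- FALSE
    # rule 2: merge simple paths
    repeat {
      merged <- FALSE
      for (a in node_ids(g)) {
        outs <- out_edges(g, a)
        if (length(outs) != 1L) next
        b <- outs
        if (b == a || b == g$root) next
        if (length(in_edges(g, b)) != 1L) next
        na <- node_of(g, a); nb <- node_of(g, b)
        na$text <- paste0(na$text, nb$text)
        na$cov <- c(na$cov, nb$cov)
        g$nodes[[as.character(a)]] <- na
        g$edges <- g$edges[!(g$edges$from == a & g$edges$to == b), , drop = FALSE]
        g$edges$from[g$edges$from == b] <- a
        g$nodes[[as.character(b)]] <- NULL
        g$edges <- unique(g$edges)
        merged <- TRUE
        changed <- TRUE
        break
      }
      if (!merged) break
    }
    # rule 3a: factorize common child prefixes into the parent's suffix
    for (a in node_ids(g)) {
      ch <- out_edges(g, a)
      if (length(ch) < 2L || a %in% ch) next
      if (!all(vapply(ch, function(b) length(in_edges(g, b)) == 1L, logical(1)))) next
      texts <- vapply(ch, function(b) node_of(g, b)$text, character(1))
      lcp <- common_prefix(texts)
      strip <- min(nchar(lcp), min(nchar(texts)) - 1L)
      if (strip < 1L) next
      pre_cov <- Reduce(`+`, lapply(ch, function(b) {
        as.numeric(node_of(g, b)$cov[seq_len(strip)])
      }))
      na <- node_of(g, a)
      na$text <- paste0(na$text, substr(texts[1], 1L, strip))
      na$cov <- c(na$cov, pre_cov)
      g$nodes[[as.character(a)]] <- na
      for (b in ch) {
        nb <- node_of(g, b)
        nb$text <- substr(nb$text, strip + 1L, nchar(nb$text))
        nb$cov <- nb$cov[-seq_len(strip)]
        g$nodes[[as.character(b)]] <- nb
      }
      changed <- TRUE
    }
    # rule 3b: factorize common parent suffixes into the child's prefix
    for (b in node_ids(g)) {
      if (b == g$root) next
      pa <- in_edges(g, b)
      if (length(pa) < 2L || b %in% pa || g$root %in% pa) next
      if (!all(vapply(pa, function(a) length(out_edges(g, a)) == 1L, logical(1)))) next
      texts <- vapply(pa, function(a) node_of(g, a)$text, character(1))
      rev_texts <- vapply(strsplit(texts, "", fixed = TRUE), function(ch2) {
        paste(rev(ch2), collapse = "")
      }, character(1))
      lcs <- common_prefix(rev_texts)
      strip <- min(nchar(lcs), min(nchar(texts)) - 1L)
      if (strip < 1L) next
      suf <- substr(texts[1], nchar(texts[1]) - strip + 1L, nchar(texts[1]))
      suf_cov <- Reduce(`+`, lapply(pa, function(a) {
        cv <- as.numeric(node_of(g, a)$cov)
        tail(cv, strip)
      }))
      nb <- node_of(g, b)
      nb$text <- paste0(suf, nb$text)
      nb$cov <- c(suf_cov, nb$cov)
      g$nodes[[as.character(b)]] <- nb
      for (a in pa) {
        na <- node_of(g, a)
        na$text <- substr(na$text, 1L, nchar(na$text) - strip)
        na$cov <- na$cov[seq_len(length(na$cov) - strip)]
        g$nodes[[as.character(a)]] <- na
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  g
}

# Pre-simplification invariant: every edge's child text begins with the
# parent's terminal k-1 characters (enrichment). Convergence links created
# with a non-zero relative offset are the documented exception.
edges_enriched_ok <- function(g) {
  k <- g$k
  if (k == 1L || isTRUE(g$stripped)) return(TRUE)
  for (r in seq_len(nrow(g$edges))) {
    pt <- node_of(g, g$edges$from[r])$text
    ct <- node_of(g, g$edges$to[r])$text
    if (substr(ct, 1L, k - 1L) !=
        substr(pt, nchar(pt) - k + 2L, nchar(pt))) return(FALSE)
  }
  TRUE
}

#' Spell all root-to-leaf strings of an extension graph
#'
#' Concatenates node texts along every root-to-leaf path, dropping the
#' `k-1` enrichment prefix of non-root nodes when the graph has not been
#' simplified yet. Used to assert that simplification preserves the
#' spelled sequence content.
#'
#' @param g One-sided extension graph.
#' @return Character vector (one spelled string per root-to-leaf path, in
#'   DFS order).
#' @export
spell_paths <- function(g) {
  strip <- if (isTRUE(g$stripped)) 0L else g$k - 1L
  out <- character(0)
  walk <- function(id, acc, seen) {
    nd <- node_of(g, id)
    txt <- nd$text
    if (!isTRUE(nd$is_root) && strip > 0L) txt <- substr(txt, strip + 1L, nchar(txt))
    acc <- paste0(acc, txt)
    outs <- setdiff(out_edges(g, id), seen)
    if (length(outs) == 0L) {
      out[[length(out) + 1L]] <<- acc
    } else {
      for (ch in outs) walk(ch, acc, c(seen, id))
    }
  }
  walk(g$root, "", integer(0))
  out
}
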