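# Sub-starter enumeration: find all maximal subsets of error-corrected mapped
# reads that admit a perfect consensus within Hamming distance d of the
# starter and cover every starter position at least c times. A starter is
# read coherent when it yields at least one such sub-starter.
#
# The production path is a single left-to-right sweep over reads sorted by
# alignment position: a read either extends an existing candidate subset,
# branches a new candidate from the members it agrees with, or opens a fresh
# candidate; candidates whose consensus drifts beyond d or whose coverage has
# irrecoverably fallen below c are pruned as the sweep passes them. Every
# candidate is by construction a set of pairwise-agreeing reads, so the final
# filtering step only has to re-check the starter-wide conditions. A
# power-set oracle with identical semantics is provided for testing.

# Two placed reads agree when their (possibly empty) overlap has zero
# mismatches.
reads_compatible <- function(text_a, off_a, text_b, off_b) {
  overlap_hamming(text_a, off_b - off_a, text_b) == 0L
}

# Order used everywhere reads are swept: offset, then text, then id.
order_mapped <- function(mapped) {
  mapped[order(mapped$offset, mapped$text, mapped$read_id), , drop = FALSE]
}

# Pairwise compatibility matrix for n mapped reads (n x n logical).
compat_matrix <- function(mapped) {
  n <- nrow(mapped)
  m <- matrix(TRUE, n, n)
  if (n < 2L) return(m)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      ok <- reads_compatible(mapped$text[a], mapped$offset[a],
        mapped$text[b], mapped$offset[b])
      m[a, b] <- ok; m[b, a] <- ok
    }
  }
  m
}

# Per-read coverage columns and characters restricted to the starter span
# [0, |s|). Returns list(cols = integer vector (1-based starter columns),
# chars = integer base codes).
starter_span_hits <- function(text, offset, s_len) {
  len <- nchar(text)
  j0 <- max(0L, -offset)                # 0-based read positions on starter
  j1 <- min(len, s_len - offset)
  if (j1 <= j0) return(list(cols = integer(0), base = integer(0)))
  cols <- (offset + j0):(offset + j1 - 1L) + 1L
  base <- match(strsplit(substr(text, j0 + 1L, j1), "", fixed = TRUE)[[1]],
    DNA_BASES)
  list(cols = cols, base = base)
}

#' Generate candidate read subsets by a position-ordered sweep
#'
#' Reads (sorted by offset, ties by text then id) are swept once; each read
#' is appended to every candidate subset all of whose members it agrees
#' with, branches a new candidate from the agreeing members of partially
#' compatible subsets, or opens a singleton. After each read at offset p,
#' candidates whose consensus already differs from the starter at more than
#' `d` positions, or whose coverage at a starter position before p has
#' fallen short of `c` (no later read can mend it), are removed. Candidate
#' subsets are sets of pairwise-agreeing reads by construction, so each
#' admits a perfect consensus.
#'
#' @param mapped Tibble of error-corrected mapped reads for one starter
#'   (columns `read_id`, `text`, `offset`).
#' @param s Starter sequence.
#' @param c_min Minimum per-position read coverage.
#' @param d Maximum substitutions between starter and consensus.
#' @return List of candidate subsets, each a list with `members` (row
#'   indices into the sorted read table), `cons`/`cov` (consensus base codes
#'   and coverage over the starter span) and `mismatches`. The sorted read
#'   table is attached as attribute `reads`, the peak number of simultaneous
#'   candidates as attribute `peak_candidates`.
#' @export
generate_candidate_subsets <- function(mapped, s, c_min, d) {
  s_len <- nchar(s)
  s_base <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  mapped <- order_mapped(mapped)
  n <- nrow(mapped)
  hits <- lapply(seq_len(n), function(i) {
    starter_span_hits(mapped$text[i], mapped$offset[i], s_len)
  })
  compat <- compat_matrix(mapped)
  cands <- list()     # each: members, cons (int, NA = uncovered), cov, mism
  keys <- character(0)
  peak <- 0L
  add_read <- function(cand, r) {
    h <- hits[[r]]
    if (length(h$cols) > 0L) {
      newpos <- h$cols[is.na(cand$cons[h$cols])]
      if (length(newpos) > 0L) {
        nb <- h$base[match(newpos, h$cols)]
        cand$cons[newpos] <- nb
        cand$mism <- cand$mism + sum(nb != s_base[newpos], na.rm = TRUE) +
          sum(is.na(nb))          # an N never matches the starter
      }
      cand$cov[h$cols] <- cand$cov[h$cols] + 1L
    }
    cand$members <- c(cand$members, r)
    cand
  }
  for (r in seq_len(n)) {
    placed <- FALSE
    fresh <- list()
    for (ci in seq_along(cands)) {
      mem <- cands[[ci]]$members
      ok <- compat[mem, r]
      if (all(ok)) {
        cands[[ci]] <- add_read(cands[[ci]], r)
        keys[ci] <- paste(cands[[ci]]$members, collapse = ",")
        placed <- TRUE
      } else if (any(ok)) {
        sub <- mem[ok]
        branch <- list(members = integer(0),
          cons = rep(NA_integer_, s_len), cov = integer(s_len), mism = 0L)
        for (m in sub) branch <- add_read(branch, m)
        branch <- add_read(branch, r)
        fresh[[length(fresh) + 1L]] <- branch
        placed <- TRUE
      }
    }
    if (!placed) {
      single <- list(members = integer(0),
        cons = rep(NA_integer_, s_len), cov = integer(s_len), mism = 0L)
      fresh[[length(fresh) + 1L]] <- add_read(single, r)
    }
    for (b in fresh) {
      key <- paste(b$members, collapse = ",")
      if (!key %in% keys) {
        cands[[length(cands) + 1L]] <- b
        keys <- c(keys, key)
      }
    }
    # prune: consensus drifted beyond d, or coverage before the current
    # offset can no longer reach c (later reads start at >= this offset)
    p <- mapped$offset[r]
    chk <- min(max(p, 0L), s_len)
    live <- vapply(cands, function(cd) {
      if (cd$mism > d) return(FALSE)
      chk == 0L || all(cd$cov[seq_len(chk)] >= c_min)
    }, logical(1))
    cands <- cands[live]
    keys <- keys[live]
    # drop candidates included in another candidate: any valid subset of a
    # pairwise-agreeing superset is non-maximal, so nothing is lost
    if (length(cands) > 1L) {
      sets <- lapply(cands, `[[`, "members")
      sizes <- lengths(sets)
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[a] &&
              (sizes[a] < sizes[b] ||
               (sizes[a] == sizes[b] && a > b && setequal(sets[[a]], sets[[b]]))) &&
              all(sets[[a]] %in% sets[[b]])) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cands <- cands[keep]
      keys <- keys[keep]
    }
    peak <- max(peak, length(cands))
  }
  structure(cands, reads = mapped, peak_candidates = peak)
}

#' Finalize sub-starters from candidate subsets
#'
#' Re-checks the three sub-starter conditions over the full starter span
#' (perfect consensus is structural; distance to the starter and coverage
#' at every position are verified here, including positions after the last
#' branch point which the sweep does not check), keeps only subsets maximal
#' under member inclusion, deduplicates identical consensuses, trims each
#' consensus to the starter's coordinate span, and caps the output
#' (preferring higher minimum coverage, ties broken lexicographically by
#' consensus).
#'
#' @param candidates Result of [generate_candidate_subsets()].
#' @param s Starter sequence.
#' @param c_min Minimum per-position coverage.
#' @param d Maximum substitutions to the starter.
#' @param cap Maximum number of sub-starters returned (default 100).
#' @return Tibble of sub-starters with columns `substarter` (consensus over
#'   the starter span), `distance`, `min_coverage`, `mean_coverage`,
#'   `n_reads`, and list-columns `coverage` (per-position counts) and
#'   `reads` (supporting read table, ordered by offset).
#' @export
finalize_substarters <- function(candidates, s, c_min, d, cap = 100L) {
  reads <- attr(candidates, "reads")
  s_len <- nchar(s)
  valid <- Filter(function(cd) {
    cd$mism <= d && length(cd$cov) == s_len && all(cd$cov >= c_min) &&
      !anyNA(cd$cons)
  }, candidates)
  if (length(valid) == 0L) return(empty_substarter_tbl())
  member_sets <- lapply(valid, function(cd) sort(cd$members))
  maximal <- rep(TRUE, length(valid))
  for (a in seq_along(valid)) {
    for (b in seq_along(valid)) {
      if (a != b && maximal[a] &&
          length(member_sets[[a]]) < length(member_sets[[b]]) &&
          all(member_sets[[a]] %in% member_sets[[b]])) {
        maximal[a] <- FALSE
        break
      }
    }
  }
  valid <- valid[maximal]
  cons_text <- vapply(valid, function(cd) {
    paste(DNA_BASES[cd$cons], collapse = "")
  }, character(1))
  dup <- duplicated(cons_text)
  valid <- valid[!dup]
  cons_text <- cons_text[!dup]
  tb <- tibble::tibble(
    substarter = cons_text,
    distance = vapply(valid, function(cd) as.integer(cd$mism), integer(1)),
    min_coverage = vapply(valid, function(cd) min(cd$cov), integer(1)),
    mean_coverage = vapply(valid, function(cd) mean(cd$cov), numeric(1)),
    n_reads = vapply(valid, function(cd) length(cd$members), integer(1)),
    coverage = lapply(valid, function(cd) cd$cov),
    reads = lapply(valid, function(cd) reads[sort(cd$members), , drop = FALSE])
  )
  tb <- tb[order(-tb$min_coverage, tb$substarter), , drop = FALSE]
  head(tb, cap)
}

empty_substarter_tbl <- function() {
  tibble::tibble(substarter = character(0), distance = integer(0),
    min_coverage = integer(0), mean_coverage = numeric(0),
    n_reads = integer(0), coverage = list(), reads = list())
}

#' Enumerate sub-starters (sweep + finalization)
#'
#' Convenience wrapper running [generate_candidate_subsets()] then
#' [finalize_substarters()].
#'
#' @inheritParams generate_candidate_subsets
#' @inheritParams finalize_substarters
#' @return See [finalize_substarters()]; the sweep's peak simultaneous
#'   candidate count is attached as attribute `peak_candidates`.
#' @export
find_substarters <- function(mapped, s, c_min, d, cap = 100L) {
  cands <- generate_candidate_subsets(mapped, s, c_min, d)
  out <- finalize_substarters(cands, s, c_min, d, cap = cap)
  attr(out, "peak_candidates") <- attr(cands, "peak_candidates")
  out
}

#' Brute-force sub-starter enumeration (testing oracle)
#'
#' Enumerates the power set of the mapped reads, keeps subsets that admit a
#' perfect consensus, whose consensus is within `d` of the starter and whose
#' coverage of every starter position is at least `c_min`, then keeps only
#' subsets maximal under inclusion. Exponential; refuses more than 15 reads.
#'
#' @inheritParams generate_candidate_subsets
#' @return Tibble shaped like [finalize_substarters()] output (uncapped),
#'   sorted like it.
#' @export
brute_force_substarters <- function(mapped, s, c_min, d) {
  n <- nrow(mapped)
  if (n > 15L) stop("brute-force oracle refuses more than 15 reads", call. = FALSE)
  if (n == 0L) return(empty_substarter_tbl())
  mapped <- order_mapped(mapped)
  s_len <- nchar(s)
  s_base <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  compat <- compat_matrix(mapped)
  hits <- lapply(seq_len(n), function(i) {
    starter_span_hits(mapped$text[i], mapped$offset[i], s_len)
  })
  masks <- seq_len(2^n - 1L)
  in_set <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
  valid_members <- list()
  for (mask in masks) {
    mem <- in_set(mask)
    if (length(mem) > 1L) {
      prs <- utils::combn(mem, 2L)
      if (!all(compat[t(prs)])) next
    }
    cons <- rep(NA_integer_, s_len)
    cov <- integer(s_len)
    for (m in mem) {
      h <- hits[[m]]
      if (length(h$cols) > 0L) {
        cons[h$cols] <- h$base
        cov[h$cols] <- cov[h$cols] + 1L
      }
    }
    if (any(cov < c_min) || anyNA(cons)) next
    if (sum(cons != s_base) > d) next
    valid_members[[length(valid_members) + 1L]] <- mem
  }
  if (length(valid_members) == 0L) return(empty_substarter_tbl())
  maximal <- rep(TRUE, length(valid_members))
  for (a in seq_along(valid_members)) {
    for (b in seq_along(valid_members)) {
      if (a != b && length(valid_members[[a]]) < length(valid_members[[b]]) &&
          all(valid_members[[a]] %in% valid_members[[b]])) {
        maximal[a] <- FALSE
        break
      }
    }
  }
  keep <- valid_members[maximal]
  rows <- lapply(keep, function(mem) {
    cons <- rep(NA_integer_, s_len); cov <- integer(s_len)
    for (m in mem) {
      h <- hits[[m]]
      cons[h$cols] <- h$base
      cov[h$cols] <- cov[h$cols] + 1L
    }
    tibble::tibble(
      substarter = paste(DNA_BASES[cons], collapse = ""),
      distance = sum(cons != s_base),
      min_coverage = min(cov),
      mean_coverage = mean(cov),
      n_reads = length(mem),
      coverage = list(cov),
      reads = list(mapped[mem, , drop = FALSE])
    )
  })
  tb <- dplyr::bind_rows(rows)
  tb <- tb[!duplicated(tb$substarter), , drop = FALSE]
  tb[order(-tb$min_coverage, tb$substarter), , drop = FALSE]
}

#' Is a starter read coherent?
#'
#' A starter is read coherent when it yields at least one sub-starter.
#'
#' @param substarters Sub-starter tibble for the starter.
#' @return Logical flag.
#' @export
is_read_coherent <- function(substarters) {
  nrow(substarters) > 0L
}
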