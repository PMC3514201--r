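# k-mer indexing of targets, streamed seed-and-verify read mapping,
# pileup construction and voting-based error correction.

#' Build a k-mer index over target sequences
#'
#' Every k-mer occurrence of every target is recorded as a (sequence, 0-based
#' position) couple; a k-mer occurring m times yields m couples. Lookup is by
#' hashed `match()` against the key vector, i.e. expected constant time.
#'
#' @param seqs Named character vector of target sequences.
#' @param k Seed length (`k >= 1`).
#' @return An object of class `kmer_index` with fields `k`, `seq_ids`,
#'   `seqs`, `keys` and `couples` (a list parallel to `keys`, each element a
#'   data frame with columns `sid` (1-based target index) and `pos`
#'   (0-based)).
#' @examples
#' build_kmer_index(c(s1 = "ATCA"), k = 3)
#' @export
build_kmer_index <- function(seqs, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  km <- character(0); sid <- integer(0); pos <- integer(0)
  for (s in seq_along(seqs)) {
    ks <- kmers_of(seqs[[s]], k)
    if (length(ks) == 0L) next
    km <- c(km, ks)
    sid <- c(sid, rep.int(s, length(ks)))
    pos <- c(pos, seq_along(ks) - 1L)
  }
  keys <- unique(km)
  grp <- match(km, keys)
  couples <- vector("list", length(keys))
  if (length(keys) > 0L) {
    ord <- order(grp)
    splits <- split(ord, grp[ord])
    for (g in seq_along(splits)) {
      rows <- splits[[g]]
      couples[[g]] <- data.frame(sid = sid[rows], pos = pos[rows])
    }
  }
  structure(
    list(k = k, seq_ids = names(seqs), seqs = unname(seqs),
         keys = keys, couples = couples),
    class = "kmer_index"
  )
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer Character scalar of length `index$k`.
#' @return Data frame of couples (`sid`, `pos`); empty for an absent k-mer.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  m <- match(kmer, index$keys)
  if (is.na(m)) data.frame(sid = integer(0), pos = integer(0)) else index$couples[[m]]
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d targets, %d distinct k-mers\n",
    x$k, length(x$seq_ids), length(x$keys)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Read sources: in-memory vectors or streamed FASTA/FASTQ files (gzip ok).

#' Normalise a read input into a read source
#'
#' @param reads Either a character vector of read sequences (optionally
#'   named with read ids), a tibble/data frame with columns `read_id` and
#'   `text`, or a character vector of FASTA/FASTQ file paths (detected by
#'   existing files).
#' @return A `read_source` object.
#' @export
read_source <- function(reads) {
  if (inherits(reads, "read_source")) return(reads)
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "text") %in% names(reads)))
    return(structure(list(type = "memory",
      texts = setNames(toupper(reads$text), reads$read_id)),
      class = "read_source"))
  }
  stopifnot(is.character(reads), length(reads) > 0L)
  if (all(file.exists(reads)) && is.null(names(reads))) {
    return(structure(list(type = "files", paths = reads), class = "read_source"))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  structure(list(type = "memory", texts = toupper(reads)), class = "read_source")
}

# Stream records of one FASTA/FASTQ file (possibly gzipped), invoking
# callback(ids, texts) per chunk. Handles multi-line FASTA. Returns a list
# with counts of records seen and malformed records skipped.
stream_sequence_file <- function(path, callback, chunk_records = 20000L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  first <- readLines(con, n = 1L)
  n_records <- 0L; n_skipped <- 0L
  if (length(first) == 0L) return(list(n_records = 0L, n_skipped = 0L))
  if (startsWith(first, "@")) {           # FASTQ: strict 4-line records
    pending <- first
    repeat {
      block <- c(pending, readLines(con, n = chunk_records * 4L - length(pending)))
      pending <- character(0)
      if (length(block) == 0L) break
      nrec <- length(block) %/% 4L
      if (nrec > 0L) {
        m <- matrix(block[seq_len(nrec * 4L)], nrow = 4L)
        ok <- startsWith(m[1, ], "@") & startsWith(m[3, ], "+")
        n_skipped <- n_skipped + sum(!ok)
        ids <- sub("^@", "", sub("\\s.*$", "", m[1, ok]))
        texts <- toupper(m[2, ok])
        n_records <- n_records + sum(ok)
        if (sum(ok) > 0L) callback(ids, texts)
      }
      rest <- length(block) - nrec * 4L
      if (rest > 0L) pending <- block[(nrec * 4L + 1L):length(block)]
      if (length(block) < chunk_records * 4L - 0L && rest == 0L) break
      if (length(block) < 4L) { n_skipped <- n_skipped + (rest > 0L); break }
    }
  } else if (startsWith(first, ">")) {    # FASTA: sequences may span lines
    carry <- first   # lines of the current (possibly incomplete) record
    repeat {
      lines <- readLines(con, n = chunk_records * 2L)
      eof <- length(lines) == 0L
      all_lines <- c(carry, lines)
      is_hdr <- startsWith(all_lines, ">")
      hdr_idx <- which(is_hdr)
      if (!eof) {
        last <- hdr_idx[length(hdr_idx)]
        carry <- all_lines[last:length(all_lines)]
        if (last == 1L) next   # one record spans the whole chunk; read on
        all_lines <- all_lines[seq_len(last - 1L)]
        is_hdr <- is_hdr[seq_len(last - 1L)]
        hdr_idx <- hdr_idx[-length(hdr_idx)]
      }
      grp <- cumsum(is_hdr)
      ids <- sub("^>", "", sub("\\s.*$", "", all_lines[hdr_idx]))
      texts <- rep("", length(ids))
      if (any(!is_hdr)) {
        sp <- split(all_lines[!is_hdr],
          factor(grp[!is_hdr], levels = seq_along(ids)))
        texts <- vapply(sp, paste, character(1), collapse = "")
      }
      texts <- toupper(unname(texts))
      n_records <- n_records + length(ids)
      if (length(ids) > 0L) callback(ids, texts)
      if (eof) break
    }
  } else {
    stop(sprintf("file '%s' is neither FASTA nor FASTQ", path), call. = FALSE)
  }
  list(n_records = n_records, n_skipped = n_skipped)
}

# ---------------------------------------------------------------------------

# Map one chunk of in-memory reads (ids, texts) against an index.
# Returns a tibble of accepted placements.
map_chunk <- function(ids, texts, index, d, min_overlap) {
  k <- index$k
  out <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") texts else reverse_complement(texts)
    lens <- nchar(oriented)
    keep <- which(lens >= k)
    if (length(keep) == 0L) next
    nk <- lens[keep] - k + 1L
    ridx <- rep.int(keep, nk)
    rpos <- unlist(lapply(nk, seq_len), use.names = FALSE)  # 1-based kmer start
    km <- substring(oriented[ridx], rpos, rpos + k - 1L)
    hit <- match(km, index$keys)
    hrows <- which(!is.na(hit))
    if (length(hrows) == 0L) next
    cpl <- index$couples[hit[hrows]]
    ncop <- vapply(cpl, nrow, integer(1))
    read_i <- rep.int(ridx[hrows], ncop)
    read_p <- rep.int(rpos[hrows], ncop) - 1L            # 0-based on read
    sid <- unlist(lapply(cpl, `[[`, "sid"), use.names = FALSE)
    tpos <- unlist(lapply(cpl, `[[`, "pos"), use.names = FALSE)
    offset <- tpos - read_p
    cand <- unique(data.frame(read_i = read_i, sid = sid, offset = offset))
    if (nrow(cand) == 0L) next
    mm <- integer(nrow(cand)); ok <- logical(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      tgt <- index$seqs[[cand$sid[j]]]
      rd <- oriented[cand$read_i[j]]
      if (overlap_length(tgt, cand$offset[j], rd) < min_overlap) next
      h <- overlap_hamming(tgt, cand$offset[j], rd)
      if (h <= d) { ok[j] <- TRUE; mm[j] <- h }
    }
    acc <- cand[ok, , drop = FALSE]
    if (nrow(acc) == 0L) next
    out[[strand]] <- tibble::tibble(
      target = index$seq_ids[acc$sid],
      read_id = ids[acc$read_i],
      text = oriented[acc$read_i],
      offset = as.integer(acc$offset),
      strand = strand,
      mismatches = as.integer(mm[ok])
    )
  }
  if (length(out) == 0L) {
    tibble::tibble(target = character(0), read_id = character(0),
      text = character(0), offset = integer(0), strand = character(0),
      mismatches = integer(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' Map reads to indexed targets by seed-and-verify
#'
#' Every k-mer of each read (and of its reverse complement) is used as a seed
#' against the index; each distinct (target, offset, strand) candidate is
#' verified once with the overlap-aware Hamming distance at threshold `d` and
#' a minimum overlap of `k` positions. Reads are processed chunk by chunk:
#' files are streamed record-by-record and unmapped reads are never retained,
#' so memory grows only with the number of accepted placements.
#'
#' @param reads A read source (see [read_source()]): in-memory reads or
#'   FASTA/FASTQ paths (gzip allowed).
#' @param index `kmer_index` built over the targets with the same `k`.
#' @param d Maximum substitutions for acceptance.
#' @param chunk_records Reads per streamed chunk.
#' @return A tibble of mapped reads with columns `target`, `read_id`, `text`
#'   (oriented to the target strand), `offset` (signed, 0-based), `strand`
#'   and `mismatches`, carrying attributes `n_records` (reads seen) and
#'   `n_skipped` (malformed records skipped with a warning).
#' @export
map_reads <- function(reads, index, d, chunk_records = 20000L) {
  stopifnot(inherits(index, "kmer_index"), d >= 0)
  src <- read_source(reads)
  acc <- list()
  n_records <- 0L; n_skipped <- 0L
  take <- function(ids, texts) {
    hit <- map_chunk(ids, texts, index, d, min_overlap = index$k)
    if (nrow(hit) > 0L) acc[[length(acc) + 1L]] <<- hit
  }
  if (src$type == "memory") {
    n_records <- length(src$texts)
    take(names(src$texts), unname(src$texts))
  } else {
    for (p in src$paths) {
      st <- stream_sequence_file(p, take, chunk_records = chunk_records)
      n_records <- n_records + st$n_records
      n_skipped <- n_skipped + st$n_skipped
    }
    if (n_skipped > 0L) {
      warning(sprintf("%d malformed read records skipped", n_skipped), call. = FALSE)
    }
  }
  res <- if (length(acc) == 0L) {
    tibble::tibble(target = character(0), read_id = character(0),
      text = character(0), offset = integer(0), strand = character(0),
      mismatches = integer(0))
  } else {
    dplyr::bind_rows(acc)
  }
  attr(res, "n_records") <- n_records
  attr(res, "n_skipped") <- n_skipped
  res
}

# ---------------------------------------------------------------------------

#' Build a per-position nucleotide pileup from mapped reads
#'
#' Tallies A/C/G/T counts at every offset covered by the mapped reads of one
#' target, including negative offsets and offsets past the target end. `N`
#' contributes no count.
#'
#' @param mapped Tibble of mapped reads for a single target (columns `text`,
#'   `offset`).
#' @return An object of class `pileup`: list with `origin` (smallest covered
#'   offset) and `counts` (4 x width integer matrix, rows A,C,G,T). Empty
#'   input yields a zero-width pileup.
#' @export
build_pileup <- function(mapped) {
  if (nrow(mapped) == 0L) {
    return(structure(list(origin = 0L,
      counts = matrix(0L, 4, 0, dimnames = list(DNA_BASES, NULL))),
      class = "pileup"))
  }
  lens <- nchar(mapped$text)
  origin <- min(mapped$offset)
  width <- max(mapped$offset + lens) - origin
  chars <- unlist(strsplit(mapped$text, "", fixed = TRUE), use.names = FALSE)
  cols <- unlist(lapply(seq_len(nrow(mapped)), function(i) {
    mapped$offset[i] - origin + seq_len(lens[i])
  }), use.names = FALSE)
  base_i <- match(chars, DNA_BASES)           # NA for N
  keep <- !is.na(base_i)
  lin <- (cols[keep] - 1L) * 4L + base_i[keep]
  counts <- matrix(tabulate(lin, nbins = 4L * width), nrow = 4L,
    dimnames = list(DNA_BASES, NULL))
  structure(list(origin = as.integer(origin), counts = counts), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> origin=%d, width=%d, total count=%d\n",
    x$origin, ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Tidy a pileup into one row per covered position
#'
#' @param x A `pileup`.
#' @param ... Unused.
#' @return Tibble with columns `offset`, `A`, `C`, `G`, `T`, `depth`.
#' @export
tidy.pileup <- function(x, ...) {
  w <- ncol(x$counts)
  tibble::tibble(
    offset = x$origin + seq_len(w) - 1L,
    A = x$counts["A", ], C = x$counts["C", ],
    G = x$counts["G", ], T = x$counts["T", ],
    depth = colSums(x$counts)
  )
}

#' Correct mapped reads by per-column voting
#'
#' Each read position (scanned left to right) is checked against the
#' original pileup: if the read's own nucleotide is seen at least `t` times
#' in its column, it is kept; otherwise, if exactly one other nucleotide
#' reaches `t`, the position is corrected to it; otherwise the read is
#' truncated immediately before the position. Votes are always taken from
#' the pre-correction pileup, so corrections do not cascade. Reads shorter
#' than `min_len` after truncation are dropped, as are reads that no longer
#' satisfy the mapping predicate at threshold `d` against their target.
#'
#' @param mapped Tibble of mapped reads for one target.
#' @param pileup Pileup built from these same reads ([build_pileup()]).
#' @param t Vote threshold (`t >= 1`).
#' @param target Target sequence (for re-verifying the mapping invariant).
#' @param d Maximum substitutions retained after correction.
#' @param min_len Minimum surviving read length (usually `k`).
#' @return Tibble shaped like `mapped` with corrected `text` and refreshed
#'   `mismatches`.
#' @export
correct_mapped_reads <- function(mapped, pileup, t, target, d, min_len = 1L) {
  stopifnot(t >= 1)
  if (nrow(mapped) == 0L) return(mapped)
  counts <- pileup$counts
  origin <- pileup$origin
  new_text <- character(nrow(mapped))
  keep <- logical(nrow(mapped))
  mism <- integer(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    chars <- strsplit(mapped$text[i], "", fixed = TRUE)[[1]]
    cols <- mapped$offset[i] - origin + seq_along(chars)
    own <- match(chars, DNA_BASES)
    cnt <- counts[, cols, drop = FALSE]
    own_cnt <- ifelse(is.na(own), 0L, cnt[cbind(own, seq_along(cols))])
    trunc_at <- length(chars) + 1L
    for (p in which(own_cnt < t)) {
      if (p >= trunc_at) break
      winners <- which(cnt[, p] >= t)
      winners <- winners[is.na(own[p]) | winners != own[p]]
      if (length(winners) == 1L) {
        chars[p] <- DNA_BASES[winners]
      } else {
        trunc_at <- p
        break
      }
    }
    chars <- chars[seq_len(trunc_at - 1L)]
    if (length(chars) < min_len) next
    txt <- paste(chars, collapse = "")
    h <- overlap_hamming(target, mapped$offset[i], txt)
    if (overlap_length(target, mapped$offset[i], txt) < min_len || h > d) next
    keep[i] <- TRUE
    new_text[i] <- txt
    mism[i] <- h
  }
  out <- mapped[keep, , drop = FALSE]
  out$text <- new_text[keep]
  out$mismatches <- mism[keep]
  out
}
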