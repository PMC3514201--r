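# Seeded simulators for shotgun reads and structured test cases: planted
# variant sites and repeats with distinct flanking contexts. All generators
# are pure functions of their parameters plus the seed, emulating
# Illumina-like substitution-only errors (no indels, no quality model, no
# pairing). Draws happen in a fixed order per read so datasets are stable.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate uniform shotgun reads from a reference
#'
#' Read start positions are uniform over the reference, strands are
#' equiprobable, and substitution errors are i.i.d. per base at
#' `error_rate` (an erroneous base is replaced by one of the three other
#' nucleotides uniformly). The number of reads is chosen so expected depth
#' approximates `coverage`.
#'
#' @param reference Reference sequence.
#' @param read_length Read length (`<= nchar(reference)`).
#' @param coverage Requested mean depth.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A `simulated_dataset`: list with `reference`, `reads` (tibble:
#'   `read_id`, `text`, `start` 0-based on the reference, `strand`,
#'   `n_errors`), `truth` (list of annotations) and `seed`.
#' @export
simulate_reads <- function(reference, read_length, coverage, error_rate, seed) {
  ref_len <- nchar(reference)
  if (read_length > ref_len) stop("read_length exceeds the reference length",
    call. = FALSE)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)",
    call. = FALSE)
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  n_reads <- max(1L, as.integer(round(coverage * ref_len / read_length)))
  with_seed(seed, {
    starts <- sample.int(ref_len - read_length + 1L, n_reads, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    texts <- substring(reference, starts + 1L, starts + read_length)
    n_err <- integer(n_reads)
    if (error_rate > 0) {
      for (i in seq_len(n_reads)) {
        hit <- which(runif(read_length) < error_rate)
        if (length(hit) > 0L) {
          ch <- strsplit(texts[i], "", fixed = TRUE)[[1]]
          for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
          texts[i] <- paste(ch, collapse = "")
          n_err[i] <- length(hit)
        }
      }
    }
    rc <- strands == "-"
    texts[rc] <- reverse_complement(texts[rc])
    structure(list(
      reference = reference,
      reads = tibble::tibble(
        read_id = sprintf("r%d", seq_len(n_reads)),
        text = texts, start = starts, strand = strands, n_errors = n_err),
      truth = list(),
      seed = seed
    ), class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> reference %d nt, %d reads (seed %s)\n",
    nchar(x$reference), nrow(x$reads), format(x$seed)))
  invisible(x)
}

#' Two biallelic sites on a starter, two error-free haplotypes
#'
#' Builds a random span carrying two variant sites and draws error-free
#' reads from exactly two haplotypes (alleles A-C and B-D) at the stated
#' per-haplotype depth. When the sites are farther apart than a read, no
#' read phases them; downstream sub-starter generation then reports all
#' four allele combinations. When they are closer than a read, only the two
#' phased haplotypes survive.
#'
#' @param span Length of the region (the starter is haplotype 1's sequence).
#' @param site_positions Two 0-based offsets within the span.
#' @param alleles List of two length-2 character vectors: alleles at site 1
#'   (`c(A, B)`) and at site 2 (`c(C, D)`).
#' @param read_length Read length.
#' @param depth_per_haplotype Exact per-position depth for each haplotype.
#' @param seed RNG seed.
#' @return A `simulated_dataset`; `truth` records the haplotypes, sites and
#'   the starter (haplotype 1).
#' @export
make_two_site_case <- function(span, site_positions, alleles, read_length,
                               depth_per_haplotype, seed) {
  stopifnot(length(site_positions) == 2L, length(alleles) == 2L)
  if (any(site_positions < 0L | site_positions >= span)) {
    stop("variant sites fall outside the span", call. = FALSE)
  }
  with_seed(seed, {
    base <- random_dna(span)
    ch <- strsplit(base, "", fixed = TRUE)[[1]]
    h1 <- ch; h1[site_positions + 1L] <- c(alleles[[1]][1], alleles[[2]][1])
    h2 <- ch; h2[site_positions + 1L] <- c(alleles[[1]][2], alleles[[2]][2])
    hap1 <- paste(h1, collapse = ""); hap2 <- paste(h2, collapse = "")
    tile <- function(hap, tag) {
      # depth_per_haplotype phase-staggered tilings; the first and last
      # windows are always present so the span edges reach full depth
      last <- span - read_length
      starts <- unlist(lapply(seq_len(depth_per_haplotype) - 1L, function(j) {
        ph <- floor(j * read_length / depth_per_haplotype)
        unique(c(0L, seq.int(ph, last, by = read_length), last))
      }))
      tibble::tibble(
        read_id = sprintf("%s_r%d", tag, seq_along(starts)),
        text = substring(hap, starts + 1L, starts + read_length),
        start = starts, strand = "+", n_errors = 0L)
    }
    reads <- dplyr::bind_rows(tile(hap1, "h1"), tile(hap2, "h2"))
    structure(list(
      reference = hap1,
      reads = reads,
      truth = list(starter = hap1, haplotypes = c(hap1, hap2),
        site_positions = site_positions, alleles = alleles,
        phaseable = abs(diff(site_positions)) < read_length),
      seed = seed
    ), class = "simulated_dataset")
  })
}

#' A repeated unit in n distinct flanking contexts
#'
#' Builds one reference containing `n_occurrences` exact copies of `unit`,
#' each wrapped in unique random flanks; using the unit as a starter, the
#' simplified extension graph should show one divergent branch per
#' occurrence on each side.
#'
#' @param unit Repeat unit sequence.
#' @param n_occurrences Number of copies (`>= 1`).
#' @param flank_length Length of each flank.
#' @param seed RNG seed.
#' @return A `simulated_dataset` (reads not yet drawn; pass `reference` to
#'   [simulate_reads()] or use the `truth` flanks directly). `truth` lists
#'   per-occurrence left/right flanks.
#' @export
make_repeat_case <- function(unit, n_occurrences, flank_length, seed) {
  stopifnot(n_occurrences >= 1L, flank_length >= 1L)
  with_seed(seed, {
    lefts <- random_dna(flank_length, n_occurrences)
    rights <- random_dna(flank_length, n_occurrences)
    if (anyDuplicated(c(lefts, rights))) {
      stop("generated flanks are not pairwise distinct; use a longer flank or another seed",
        call. = FALSE)
    }
    reference <- paste(paste0(lefts, unit, rights), collapse = "")
    structure(list(
      reference = reference,
      reads = tibble::tibble(read_id = character(0), text = character(0),
        start = integer(0), strand = character(0), n_errors = integer(0)),
      truth = list(unit = unit, left_flanks = lefts, right_flanks = rights),
      seed = seed
    ), class = "simulated_dataset")
  })
}

#' Write simulated reads to FASTA
#'
#' @param dataset A `simulated_dataset` (or any tibble with `read_id`,
#'   `text`).
#' @param path Output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(dataset, path) {
  reads <- if (inherits(dataset, "simulated_dataset")) dataset$reads else dataset
  lines <- character(2L * nrow(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
  lines[c(FALSE, TRUE)] <- reads$text
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}

#' Write simulated reads to FASTQ (uniform dummy qualities)
#'
#' @inheritParams write_reads_fasta
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(dataset, path) {
  reads <- if (inherits(dataset, "simulated_dataset")) dataset$reads else dataset
  lines <- character(4L * nrow(reads))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$text
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- strrep("I", nchar(reads$text))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}
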