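# Core alphabet operations: reverse complement, the overlap-aware Hamming
# distance, and the mapping predicate that everything else builds on.
#
# Conventions used throughout the package: sequences are plain upper-case
# character scalars over {A,C,G,T} (N tolerated in reads, never in starters);
# all coordinates are 0-based, offsets are signed, intervals are half-open.

DNA_BASES <- c("A", "C", "G", "T")
.RAW_N <- charToRaw("N")

#' Sanitize a DNA sequence
#'
#' Upper-cases the text and checks it against the permitted alphabet.
#'
#' @param x Character scalar.
#' @param allow_n Should `N` be tolerated? Reads may carry `N` (it never
#'   matches anything); starters may not.
#' @param what Label used in error messages.
#' @return The sanitized character scalar.
#' @export
sanitize_seq <- function(x, allow_n = FALSE, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  alphabet <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  bad <- which(!strsplit(x, "", fixed = TRUE)[[1]] %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s contains character '%s' outside {%s} at position %d",
      what, substr(x, bad[1], bad[1]), paste(alphabet, collapse = ","), bad[1]
    ), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of one or more DNA strings (`N` maps to
#' `N`). Vectorised; an involution.
#'
#' @param seq Character vector over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAC") # "GTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  comp <- chartr("ACGTN", "TGCAN", seq)
  bad <- grepl("[^ACGTN]", comp)
  if (any(bad)) {
    s <- comp[which(bad)[1]]
    pos <- regexpr("[^ACGTN]", s)[1]
    stop(sprintf("unknown character '%s' at position %d", substr(s, pos, pos), pos),
      call. = FALSE)
  }
  vapply(strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Overlap-aware Hamming distance
#'
#' Substitution count between `w2` placed at signed offset `i` on `w1`,
#' counting only the overlapped positions: characters of `w1` outside
#' `[0, nchar(w1))` are treated as absent and contribute nothing. With
#' `i = 0` and equal lengths this is the classical Hamming distance.
#' `N` matches nothing, including another `N`.
#'
#' @param w1 Target sequence (character scalar).
#' @param i Signed 0-based offset of `w2[0]` on `w1`.
#' @param w2 Placed sequence (character scalar).
#' @return Integer mismatch count (total function; zero when the overlap is
#'   empty).
#' @examples
#' overlap_hamming("ATTCGGA", -2L, "GAATGCG") # 1
#' @export
overlap_hamming <- function(w1, i, w2) {
  n1 <- nchar(w1)
  n2 <- nchar(w2)
  j0 <- max(0L, -i)                 # first overlapped position of w2
  j1 <- min(n2, n1 - i)             # one past last overlapped position
  if (j1 <= j0) return(0L)
  a <- charToRaw(substr(w1, i + j0 + 1L, i + j1))
  b <- charToRaw(substr(w2, j0 + 1L, j1))
  sum(a != b | a == .RAW_N | b == .RAW_N)
}

#' Number of overlapped positions for a placement
#'
#' @inheritParams overlap_hamming
#' @return Integer count of positions of `w2` that fall on `w1`.
#' @export
overlap_length <- function(w1, i, w2) {
  max(0L, min(nchar(w2), nchar(w1) - i) - max(0L, -i))
}

#' Mapping predicate
#'
#' A read `r` is mapped to `s` at offset `i` iff the overlap-aware Hamming
#' distance is at most `d` *and* at least `min_overlap` positions actually
#' overlap. The overlap guard prevents vacuous placements (a placement with
#' empty overlap has distance zero by definition); seed-driven mapping passes
#' `min_overlap = k` since a shared k-mer always overlaps by at least k.
#'
#' @param s Target sequence.
#' @param i Signed offset of `r[0]` on `s`.
#' @param r Read sequence.
#' @param d Maximum number of substitutions (`d >= 0`).
#' @param min_overlap Minimum overlapped positions required (default 1).
#' @return Logical flag.
#' @examples
#' is_mapped("ATTCGGA", -2L, "GAATGCG", d = 1) # TRUE
#' @export
is_mapped <- function(s, i, r, d, min_overlap = 1L) {
  stopifnot(d >= 0)
  overlap_length(s, i, r) >= min_overlap && overlap_hamming(s, i, r) <= d
}

# All k-mers of x as a character vector (empty when nchar(x) < k).
kmers_of <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

# Random DNA string(s) from an RNG already seeded by the caller.
random_dna <- function(n_char, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, n_char, replace = TRUE), collapse = "")
  }, character(1))
}
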