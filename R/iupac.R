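# IUPAC nucleotide codes as bit sets: A=1, C=2, G=4, T=8.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# inverse lookup: bit value (1..15) -> IUPAC letter
.BITS_CHAR <- character(15L)
.BITS_CHAR[.IUPAC_BITS] <- names(.IUPAC_BITS)

# per-code complement, e.g. R={A,G} -> Y={C,T}
.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.BIT_SIZE <- vapply(1:15, function(b) {
  sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

.GAP_CHARS <- c("-", ".")

#' Convert an IUPAC string to a vector of nucleotide bit sets
#'
#' Internal encoding used throughout: A=1, C=2, G=4, T=8, and every IUPAC
#' ambiguity code is the bitwise OR of the bases it denotes.
#'
#' @param x A single IUPAC string (A, C, G, T and ambiguity codes).
#' @return Integer vector of bit sets, one per character.
#' @keywords internal
iupac_bits <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- unique(chars[is.na(bits)])
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(bits)
}

bits_to_iupac <- function(bits) {
  paste(.BITS_CHAR[bits], collapse = "")
}

#' Degeneracy of an IUPAC primer
#'
#' The degeneracy of a degenerate oligonucleotide is the number of concrete
#' sequences it represents: the product over positions of the size of each
#' position's IUPAC code set (A/C/G/T count 1; R,Y,S,W,K,M count 2;
#' B,D,H,V count 3; N counts 4).
#'
#' @param primer IUPAC string.
#' @return Integer degeneracy (>= 1).
#' @examples
#' primer_degeneracy("CGGTAAYTCCAGCTCYAV")  # 12
#' primer_degeneracy("ACGT")                # 1
#' @export
primer_degeneracy <- function(primer) {
  bits <- iupac_bits(primer)
  as.integer(prod(.BIT_SIZE[bits]))
}

#' Expand a degenerate primer into its concrete sequences
#'
#' @param primer IUPAC string.
#' @return Character vector of all concrete A/C/G/T sequences the primer
#'   represents, sorted lexicographically; its length equals
#'   [primer_degeneracy()].
#' @examples
#' expand_primer("AY")  # "AC" "AT"
#' @export
expand_primer <- function(primer) {
  bits <- iupac_bits(primer)
  sets <- lapply(bits, function(b) {
    c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
  })
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Reverse complement of an IUPAC primer
#'
#' Reverses the sequence and complements each code set-wise
#' (A-T, C-G, R-Y, K-M, S and W self-complementary, B-V, D-H, N-N).
#'
#' @param primer IUPAC string.
#' @return IUPAC string of the reverse complement.
#' @examples
#' reverse_complement("AYTTRAAGDAATTGACGG")  # "CCGTCAATTHCTTYAART"
#' @export
reverse_complement <- function(primer) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  comp <- .IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("invalid IUPAC character(s): ",
         paste(unique(chars[is.na(comp)]), collapse = ", "), call. = FALSE)
  }
  paste(rev(unname(comp)), collapse = "")
}

#' GC-content range of a degenerate primer
#'
#' Minimum and maximum GC percentage over all concrete expansions, each
#' rounded to the nearest integer percent. A position contributes to the
#' minimum only if its code set is contained in \{G,C\}, and to the maximum
#' if it intersects \{G,C\}, so the range is computed without enumerating
#' expansions.
#'
#' @param primer IUPAC string, length > 0.
#' @return Named numeric vector `c(min = , max = )` in percent.
#' @examples
#' gc_range("TTAAARVGYTCGTAGTYG")  # 28 50
#' gc_range("TTGTACACACCGCCC")     # 60 60
#' @export
gc_range <- function(primer) {
  bits <- iupac_bits(primer)
  if (length(bits) == 0L) stop("empty primer", call. = FALSE)
  # A|T bits = 9, C|G bits = 6
  min_gc <- sum(bitwAnd(bits, 9L) == 0L)   # set entirely within {G,C}
  max_gc <- sum(bitwAnd(bits, 6L) > 0L)    # set intersects {G,C}
  n <- length(bits)
  c(min = round(100 * min_gc / n), max = round(100 * max_gc / n))
}

#' Melting-temperature range of a degenerate primer (basic GC formula)
#'
#' Applies the basic salt-adjusted formula
#' \deqn{T_m = 64.9 + 41 (n_{GC} - 16.4) / N}
#' to every concrete expansion and returns the minimum and maximum, rounded
#' to one decimal. Because the formula is monotone in the GC count, only the
#' extreme GC counts are evaluated. The formula is conventionally valid for
#' oligomers of at least 14 bases; shorter input is an error.
#'
#' @param primer IUPAC string of length >= 14.
#' @return Named numeric vector `c(min = , max = )` in degrees Celsius.
#' @examples
#' tm_range("GCCAGCAVCYGCGGTAAY")  # 50.3 57.2
#' @export
tm_range <- function(primer) {
  bits <- iupac_bits(primer)
  n <- length(bits)
  if (n < 14L) {
    stop("basic Tm formula requires length >= 14 (got ", n, ")",
         call. = FALSE)
  }
  min_gc <- sum(bitwAnd(bits, 9L) == 0L)
  max_gc <- sum(bitwAnd(bits, 6L) > 0L)
  tm <- function(ngc) round(64.9 + 41 * (ngc - 16.4) / n, 1)
  c(min = tm(min_gc), max = tm(max_gc))
}

#' Trim terminal N positions from a primer
#'
#' A maximum-coverage search can legitimately return an oligomer whose
#' terminal position is N (matching all four bases); such a base adds
#' degeneracy without adding specificity, and a shorter primer omitting it
#' is often preferable (the 17-mer variants of some published 18S primers
#' arise this way).
#'
#' @param primer IUPAC string.
#' @return The primer with leading and trailing runs of `N` removed.
#' @export
trim_terminal_n <- function(primer) {
  sub("N+$", "", sub("^N+", "", toupper(primer)))
}
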