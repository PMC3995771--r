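# Degenerate-oligomer maximum-coverage search over alignment windows.
#
# The search objective: among all IUPAC oligomers of fixed length L with
# degeneracy <= D, find one matching the largest number of database
# sequences at a given window. Key structural fact used by the exact
# search: any oligo's matched variant set S satisfies
# degeneracy(per-position union of S) <= degeneracy(oligo), so an optimal
# solution is always the per-position union of some variant subset --
# the exact search enumerates subsets (DFS with degeneracy pruning)
# rather than all 15^L oligomers.

#' Tabulate window variants of a trimmed alignment
#'
#' Counts the concrete (gap-free, unambiguous) L-mers observed at a window
#' of the trimmed alignment. Sequences showing a gap or an ambiguity code
#' anywhere in the window are excluded from the variant table and counted
#' separately: a primer cannot be scored against an ambiguous template
#' without inflating coverage.
#'
#' @param trimmed A `trimmed_alignment` (or `aligned_db`).
#' @param window_start 1-based start column of the window.
#' @param length Window length in columns.
#' @return A `window_variants` list: `window_start`, `length`, `variants`
#'   (named integer vector, decreasing counts), `excluded_count`,
#'   `n_total`.
#' @export
window_variants <- function(trimmed, window_start, length) {
  db <- if (inherits(trimmed, "trimmed_alignment")) trimmed$db else trimmed
  stopifnot(inherits(db, "aligned_db"))
  aln_len <- if (base::length(db$id)) nchar(db$seq[1L]) else 0L
  if (window_start < 1L || window_start + length - 1L > aln_len) {
    stop("window [", window_start, ", ", window_start + length - 1L,
         "] out of alignment range 1..", aln_len, call. = FALSE)
  }
  w <- substr(db$seq, window_start, window_start + length - 1L)
  clean <- !grepl("[^ACGT]", w)
  counts <- table(w[clean])
  counts <- sort(counts, decreasing = TRUE)
  variants <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(window_start = as.integer(window_start), length = as.integer(length),
         variants = variants, excluded_count = sum(!clean),
         n_total = base::length(db$id)),
    class = "window_variants"
  )
}

# variants (named counts) -> L x k integer matrix of base bits
.variant_bits <- function(variants) {
  L <- nchar(names(variants)[1L])
  matrix(vapply(names(variants), iupac_bits, integer(L)), nrow = L)
}

# number of variants (columns of vb) whose per-position bases are contained
# in the oligo's per-position bit sets
.contained_count <- function(union_bits, vb, counts) {
  ok <- colSums(bitwAnd(vb, union_bits) == vb) == nrow(vb)
  sum(counts[ok])
}

.deg_of_bits <- function(bits) prod(.BIT_SIZE[bits])

# Exact maximizer: DFS over variant subsets ordered by decreasing count,
# pruning on the degeneracy bound and on an optimistic coverage bound.
.exact_best <- function(vb, counts, max_degeneracy) {
  k <- ncol(vb)
  best <- list(score = -1L, deg = Inf, oligo = NULL)
  consider <- function(union_bits) {
    deg <- .deg_of_bits(union_bits)
    if (deg > max_degeneracy) return(invisible())
    score <- .contained_count(union_bits, vb, counts)
    oligo <- bits_to_iupac(union_bits)
    better <- score > best$score ||
      (score == best$score && (deg < best$deg ||
        (deg == best$deg && !is.null(best$oligo) && oligo < best$oligo)))
    if (better) best <<- list(score = score, deg = deg, oligo = oligo)
    invisible()
  }
  dfs <- function(i, union_bits, remaining) {
    if (i > k) return(invisible())
    # optimistic bound: even absorbing all remaining counts cannot beat best
    if (.contained_count(union_bits, vb, counts) + remaining < best$score) {
      return(invisible())
    }
    # include variant i
    nb <- bitwOr(union_bits, vb[, i])
    if (.deg_of_bits(nb) <= max_degeneracy) {
      consider(nb)
      dfs(i + 1L, nb, remaining - counts[i])
    }
    # exclude variant i
    dfs(i + 1L, union_bits, remaining - counts[i])
    invisible()
  }
  consider(vb[, 1L])
  dfs(1L, rep(0L, nrow(vb)), sum(counts))
  best
}

# Greedy heuristic for large variant tables: seed with the most frequent
# variant, repeatedly merge the variant giving the largest coverage gain
# whose merged per-position sets keep the degeneracy within bound, then
# re-score against all variants (a merged oligo may absorb unmerged ones).
.greedy_best <- function(vb, counts, max_degeneracy, max_candidates = 64L) {
  k <- ncol(vb)
  cand <- seq_len(min(k, max_candidates))
  union_bits <- vb[, 1L]
  merged <- c(1L)
  repeat {
    cur_score <- .contained_count(union_bits, vb, counts)
    best_gain <- 0L
    best_j <- NA_integer_
    best_deg <- Inf
    best_oligo <- NULL
    for (j in setdiff(cand, merged)) {
      nb <- bitwOr(union_bits, vb[, j])
      deg <- .deg_of_bits(nb)
      if (deg > max_degeneracy) next
      gain <- .contained_count(nb, vb, counts) - cur_score
      if (gain <= 0L) next
      oligo <- bits_to_iupac(nb)
      if (gain > best_gain ||
          (gain == best_gain && (deg < best_deg ||
            (deg == best_deg && oligo < best_oligo)))) {
        best_gain <- gain; best_j <- j; best_deg <- deg; best_oligo <- oligo
      }
    }
    if (is.na(best_j)) break
    union_bits <- bitwOr(union_bits, vb[, best_j])
    merged <- c(merged, best_j)
  }
  list(score = .contained_count(union_bits, vb, counts),
       deg = .deg_of_bits(union_bits),
       oligo = bits_to_iupac(union_bits))
}

#' Best degenerate oligomer for a window variant table
#'
#' Finds an IUPAC oligomer with degeneracy at most `max_degeneracy` that
#' matches as many database sequences as possible at the window. For small
#' variant tables (up to `exact_max_variants` distinct variants) the result
#' is the exact maximum-coverage solution (subset enumeration with
#' degeneracy pruning); larger tables use a greedy merge heuristic seeded
#' with the most frequent variant. The matched count is always at least the
#' count of the single most frequent variant. Ties are broken by lower
#' degeneracy, then lexicographic oligomer order.
#'
#' @param table A `window_variants` object.
#' @param max_degeneracy Positive integer degeneracy bound.
#' @param exact_max_variants Use the exact search when the number of
#'   distinct variants is at most this (default 12).
#' @return A `degenerate_oligo` list (`sequence`, `degeneracy`,
#'   `window_start`, `matched_count`, `n_total`, `excluded_count`), or
#'   `NULL` if the variant table is empty (no gap-free unambiguous window).
#' @export
best_degenerate_oligo <- function(table, max_degeneracy,
                                  exact_max_variants = 12L) {
  stopifnot(inherits(table, "window_variants"), max_degeneracy >= 1)
  counts <- table$variants
  if (length(counts) == 0L) return(NULL)
  vb <- .variant_bits(counts)
  res <- if (length(counts) <= exact_max_variants) {
    .exact_best(vb, unname(counts), max_degeneracy)
  } else {
    .greedy_best(vb, unname(counts), max_degeneracy)
  }
  structure(
    list(sequence = res$oligo, degeneracy = as.integer(res$deg),
         window_start = table$window_start,
         matched_count = as.integer(res$score),
         n_total = table$n_total, excluded_count = table$excluded_count),
    class = "degenerate_oligo"
  )
}

#' @export
print.degenerate_oligo <- function(x, ...) {
  cat(sprintf("degenerate_oligo %s (deg %d) at column %d: %d/%d matched\n",
              x$sequence, x$degeneracy, x$window_start, x$matched_count,
              x$n_total))
  invisible(x)
}

#' Scan an alignment for the best degenerate oligomer at every window
#'
#' Runs the maximum-coverage oligomer search at every window start of the
#' trimmed alignment and reports, per window, the best oligomer, its
#' degeneracy, the number and fraction of sequences matched, and the
#' entropy of the window's start column. This is the per-position
#' coverage/entropy profile from which conserved primer sites are picked.
#'
#' @param trimmed A `trimmed_alignment`.
#' @param length Oligomer length in bases (default 18).
#' @param max_degeneracy Degeneracy bound (default 12).
#' @param reference_map Optional `reference_map` built on the *original*
#'   (untrimmed) alignment; adds a `reference_position` column via the
#'   trimmed alignment's `kept_columns`.
#' @param ... Passed to [best_degenerate_oligo()].
#' @return A data frame of class `primer_scan` with columns `window_start`,
#'   `reference_position` (if a map is given), `oligo`, `degeneracy`,
#'   `matched_count`, `fraction`, `entropy`; per-column entropies of the
#'   whole trimmed alignment are attached as attribute `column_entropy`.
#' @export
scan_alignment <- function(trimmed, length = 18L, max_degeneracy = 12L,
                           reference_map = NULL, ...) {
  stopifnot(inherits(trimmed, "trimmed_alignment"))
  aln_len <- nchar(trimmed$db$seq[1L])
  if (length > aln_len) stop("window length exceeds alignment length",
                             call. = FALSE)
  n <- base::length(trimmed$db$id)
  starts <- seq_len(aln_len - length + 1L)
  ent <- suppressWarnings(column_entropy(trimmed))
  rows <- lapply(starts, function(s) {
    wv <- window_variants(trimmed, s, length)
    bo <- best_degenerate_oligo(wv, max_degeneracy, ...)
    if (is.null(bo)) {
      data.frame(window_start = s, oligo = NA_character_,
                 degeneracy = NA_integer_, matched_count = 0L,
                 fraction = 0, entropy = ent[s],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(window_start = s, oligo = bo$sequence,
                 degeneracy = bo$degeneracy,
                 matched_count = bo$matched_count,
                 fraction = bo$matched_count / n, entropy = ent[s],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_map)) {
    refpos <- as.integer(reference_map)[trimmed$kept_columns[out$window_start]]
    out <- cbind(out[, "window_start", drop = FALSE],
                 reference_position = refpos,
                 out[, setdiff(names(out), "window_start"), drop = FALSE])
  }
  attr(out, "column_entropy") <- ent
  attr(out, "params") <- list(length = length,
                              max_degeneracy = max_degeneracy)
  class(out) <- c("primer_scan", "data.frame")
  out
}
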