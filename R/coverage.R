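# Ambiguity-aware primer matching against ungapped template sequences.
#
# Matching rule (strict set containment): at every offset the template
# base's IUPAC set must be a subset of the primer base's set. A concrete
# template base matches iff it is in the primer's set; a template ambiguity
# code matches only if its whole set is contained, so a template N never
# matches anything but a primer N. Zero mismatches, full primer length.

#' Does a primer match a template at a given position?
#'
#' @param primer IUPAC string.
#' @param sequence Ungapped template string (may contain ambiguity codes).
#' @param position 1-based template position of the primer's 5' end.
#' @return `TRUE` iff the primer matches exactly (subset rule, no
#'   mismatches) over its full length.
#' @examples
#' matches_at("AY", "GACT", 2)  # TRUE  (Y = {C,T} contains C)
#' matches_at("AY", "GAGT", 2)  # FALSE (G not in {C,T})
#' @export
matches_at <- function(primer, sequence, position) {
  pb <- iupac_bits(primer)
  L <- length(pb)
  n <- nchar(sequence)
  if (position < 1L || position + L - 1L > n) {
    stop("window [", position, ", ", position + L - 1L,
         "] out of sequence range 1..", n, call. = FALSE)
  }
  tb <- iupac_bits(substr(sequence, position, position + L - 1L))
  all(bitwAnd(tb, pb) == tb)
}

# all 5'-most template positions where the primer (bit vector) matches a
# template (bit vector); subset rule, vectorized over offsets
.match_positions <- function(primer_bits, template_bits) {
  L <- length(primer_bits)
  n <- length(template_bits)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    tb <- template_bits[j:(n - L + j)]
    ok <- ok & (bitwAnd(tb, primer_bits[j]) == tb) & tb > 0L
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

# template string -> bits, with gaps/invalid chars encoded as 0 (never match)
.template_bits <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  bits[is.na(bits)] <- 0L
  unname(bits)
}

#' Find primer binding sites in a database
#'
#' Locates all exact full-length matches of a degenerate primer on the
#' ungapped database sequences under the strict set-containment rule.
#' Forward-strand sites report matches of the primer itself; with
#' `search_both_strands = TRUE`, reverse-strand sites report matches of the
#' primer's reverse complement, with `start` the 5'-most template
#' coordinate of the binding footprint.
#'
#' @param primer IUPAC string.
#' @param db An `aligned_db` (sequences are degapped internally) or a named
#'   character vector of ungapped sequences.
#' @param search_both_strands Also search the reverse strand?
#' @param primer_id Label recorded in the output (default the sequence).
#' @return Data frame with columns `record_id`, `start`, `strand`
#'   (`"forward"`/`"reverse"`), `primer_id`.
#' @export
find_binding_sites <- function(primer, db, search_both_strands = FALSE,
                               primer_id = primer) {
  seqs <- if (inherits(db, "aligned_db") ||
              inherits(db, "trimmed_alignment")) {
    ungapped_sequences(db)
  } else {
    stopifnot(is.character(db), !is.null(names(db)))
    db
  }
  pb <- iupac_bits(primer)
  rcb <- if (search_both_strands) iupac_bits(reverse_complement(primer))
  rows <- lapply(seq_along(seqs), function(i) {
    tb <- .template_bits(seqs[[i]])
    fwd <- .match_positions(pb, tb)
    out <- if (length(fwd)) {
      data.frame(record_id = names(seqs)[i], start = fwd,
                 strand = "forward", primer_id = primer_id,
                 stringsAsFactors = FALSE)
    } else NULL
    if (search_both_strands) {
      rev <- .match_positions(rcb, tb)
      if (length(rev)) {
        out <- rbind(out, data.frame(
          record_id = names(seqs)[i], start = rev, strand = "reverse",
          primer_id = primer_id, stringsAsFactors = FALSE))
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(record_id = character(0), start = integer(0),
                      strand = character(0), primer_id = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tabulate primer coverage per taxon
#'
#' Counts, for each taxon label at a chosen rank depth, how many database
#' records are perfectly matched by the primer (at least one forward-strand
#' binding site; no mismatches, no partial matches). Records whose taxonomy
#' does not reach the requested depth are pooled in an `"unclassified"`
#' bin.
#'
#' @param primer IUPAC string.
#' @param db An `aligned_db`.
#' @param rank_depth 1-based taxonomy rank to group by (1 = root rank).
#' @param primer_id Label attached to the result.
#' @return A `coverage_profile` data frame: `taxon`, `matched`, `total`,
#'   `percent`, with attribute `primer_id`.
#' @export
coverage_by_taxon <- function(primer, db, rank_depth = 2L,
                              primer_id = primer) {
  stopifnot(inherits(db, "aligned_db"), rank_depth >= 1L)
  n <- length(db$id)
  if (n == 0L) {
    out <- data.frame(taxon = character(0), matched = integer(0),
                      total = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "primer_id") <- primer_id
    class(out) <- c("coverage_profile", "data.frame")
    return(out)
  }
  sites <- find_binding_sites(primer, db, search_both_strands = FALSE,
                              primer_id = primer_id)
  matched_ids <- unique(sites$record_id)
  labels <- vapply(db$taxonomy, function(tax) {
    if (length(tax) >= rank_depth) tax[[rank_depth]] else "unclassified"
  }, character(1))
  taxa <- sort(unique(labels))
  rows <- lapply(taxa, function(t) {
    ids <- db$id[labels == t]
    m <- sum(ids %in% matched_ids)
    data.frame(taxon = t, matched = m, total = length(ids),
               percent = 100 * m / length(ids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "primer_id") <- primer_id
  class(out) <- c("coverage_profile", "data.frame")
  out
}
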