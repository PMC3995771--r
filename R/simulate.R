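# Error-free amplicon read simulation.
#
# An amplicon spans from the 5' end of the forward primer footprint to the
# 3'-most template base of the reverse primer footprint, inclusive: reads
# include primer-covered template. Reads are taken from the template's own
# bases (a degenerate primer site contributes whatever expansion the
# template actually carries), with no error model.

#' Simulate error-free reads for a primer pair
#'
#' For every record carrying a forward-primer site 5' of a reverse-primer
#' footprint, extracts the amplicon and simulates reads of the requested
#' layout. The forward read starts at the forward primer's 5' position; the
#' paired reverse read is the reverse complement of the template segment
#' ending at the reverse footprint's 3'-most base. Reads are truncated at
#' the amplicon boundary when the amplicon is shorter than the read length.
#' The `fused` string is the comparison key used for uniqueness analyses:
#' the single read for single-end layouts; for paired layouts, the merged
#' amplicon when the two reads overlap (amplicon shorter than twice the
#' read length — error-free overlap merging reconstitutes the template
#' exactly), otherwise the concatenation of forward and reverse read.
#'
#' When a record has several binding sites, the 5'-most forward site and
#' the 3'-most compatible reverse site are used (the dominant PCR product);
#' multiplicities are recorded in the `skipped`/`multi_site` attributes.
#'
#' @param db An `aligned_db` (or named character vector of ungapped
#'   sequences).
#' @param fwd_primer,rev_primer IUPAC strings; the reverse primer is given
#'   in its own 5'->3' orientation (it binds where its reverse complement
#'   occurs in the template).
#' @param read_length Read length in bases, including primer bases.
#' @param paired Simulate a read pair (default) or a single forward read.
#' @return An `amplicon_set` data frame: `record_id`, `amplicon_length`,
#'   `fwd_read`, `rev_read` (`NA` for single-end), `fused`. Attributes:
#'   `skipped` (data frame of record_id, reason), `layout`, `primers`.
#' @export
simulate_amplicons <- function(db, fwd_primer, rev_primer,
                               read_length = 250L, paired = TRUE) {
  seqs <- if (inherits(db, "aligned_db") ||
              inherits(db, "trimmed_alignment")) {
    ungapped_sequences(db)
  } else {
    stopifnot(is.character(db), !is.null(names(db)))
    db
  }
  fb <- iupac_bits(fwd_primer)
  rb <- iupac_bits(reverse_complement(rev_primer))
  len_r <- length(rb)
  rows <- vector("list", length(seqs))
  skipped <- list()
  multi <- character(0)
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    tb <- .template_bits(seqs[[i]])
    fwd <- .match_positions(fb, tb)
    rev <- .match_positions(rb, tb)
    if (!length(fwd) || !length(rev)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(record_id = id,
                   reason = if (!length(fwd)) "no_forward_site"
                            else "no_reverse_site",
                   stringsAsFactors = FALSE)
      next
    }
    if (length(fwd) > 1L || length(rev) > 1L) multi <- c(multi, id)
    f <- min(fwd)
    rc <- rev[rev > f]
    if (!length(rc)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(record_id = id, reason = "reverse_site_upstream",
                   stringsAsFactors = FALSE)
      next
    }
    r_end <- max(rc) + len_r - 1L
    amplicon <- substr(seqs[[i]], f, r_end)
    amplen <- r_end - f + 1L
    fwd_read <- substr(amplicon, 1L, min(read_length, amplen))
    if (paired) {
      rev_read <- reverse_complement(
        substr(amplicon, max(1L, amplen - read_length + 1L), amplen))
      fused <- if (amplen < 2L * read_length) amplicon
               else paste0(fwd_read, rev_read)
    } else {
      rev_read <- NA_character_
      fused <- fwd_read
    }
    rows[[i]] <- data.frame(record_id = id, amplicon_length = amplen,
                            fwd_read = fwd_read, rev_read = rev_read,
                            fused = fused, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(record_id = character(0), amplicon_length = integer(0),
                      fwd_read = character(0), rev_read = character(0),
                      fused = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(record_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  attr(out, "multi_site") <- multi
  attr(out, "layout") <- list(read_length = as.integer(read_length),
                              paired = paired)
  attr(out, "primers") <- c(fwd = fwd_primer, rev = rev_primer)
  class(out) <- c("amplicon_set", "data.frame")
  out
}

#' Ratio of unique amplicons to unique near-full-length sequences
#'
#' A proxy for the phylogenetic resolution a primer pair and read layout
#' retain: the number of distinct fused read sequences divided by the
#' number of distinct near-full-length sequences (the ungapped subsequence
#' between two reference coordinates) among the same records. A ratio of 1
#' means the reads distinguish every sequence the full-length region
#' distinguishes.
#'
#' @param amplicons An `amplicon_set` from [simulate_amplicons()].
#' @param db The `aligned_db` the amplicons came from.
#' @param reference_id Record whose ungapped coordinates define the region.
#' @param region Length-2 integer vector, reference positions
#'   (start, end) of the near-full-length comparison region.
#' @return Fraction (distinct amplicons / distinct full-length), with
#'   attribute `counts`; `NA` with a warning if no record yields a
#'   full-length key.
#' @export
unique_ratio <- function(amplicons, db, reference_id, region) {
  stopifnot(inherits(amplicons, "amplicon_set"), inherits(db, "aligned_db"),
            length(region) == 2L, region[1L] <= region[2L])
  refmap <- build_reference_map(db, reference_id)
  pos <- as.integer(refmap)
  c1 <- which(!is.na(pos) & pos >= region[1L])[1L]
  c2 <- rev(which(!is.na(pos) & pos <= region[2L]))[1L]
  if (is.na(c1) || is.na(c2) || c1 > c2) {
    stop("region [", region[1L], ", ", region[2L],
         "] not defined on reference ", reference_id, call. = FALSE)
  }
  idx <- match(amplicons$record_id, db$id)
  full <- .degap(substr(db$seq[idx], c1, c2))
  full <- full[nzchar(full)]
  if (!length(full)) {
    warning("no full-length sequences in region; ratio undefined")
    return(NA_real_)
  }
  n_amp <- length(unique(amplicons$fused))
  n_full <- length(unique(full))
  structure(n_amp / n_full,
            counts = c(unique_amplicons = n_amp, unique_fulllength = n_full))
}
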