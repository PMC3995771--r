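#' Construct an aligned reference database
#'
#' An `aligned_db` holds equal-length gapped sequences with SILVA-style
#' taxonomy paths (ordered root-to-leaf rank labels; an empty path means
#' "unclassified"). Both `-` and `.` are recognized as gap characters and
#' `U` is normalized to `T` on construction.
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of gapped sequences (equal lengths).
#' @param taxonomy List of character vectors (root-to-leaf rank labels),
#'   one per record; defaults to all-unclassified.
#' @return An object of class `aligned_db`.
#' @export
aligned_db <- function(id, seq, taxonomy = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  if (length(id) != length(seq)) {
    stop("id and seq must have equal length", call. = FALSE)
  }
  w <- nchar(seq)
  if (length(seq) > 1L && length(unique(w)) != 1L) {
    stop("aligned sequences must all have the same length (got lengths ",
         paste(unique(w), collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("duplicate record ids", call. = FALSE)
  if (is.null(taxonomy)) taxonomy <- rep(list(character(0)), length(id))
  stopifnot(length(taxonomy) == length(id))
  structure(
    list(id = id, seq = seq, taxonomy = taxonomy),
    class = "aligned_db"
  )
}

#' @export
print.aligned_db <- function(x, ...) {
  cat("aligned_db:", length(x$id), "records, alignment length",
      nchar(x$seq[1L]), "\n")
  n <- min(3L, length(x$id))
  for (i in seq_len(n)) {
    tax <- if (length(x$taxonomy[[i]])) {
      paste(x$taxonomy[[i]], collapse = ";")
    } else "unclassified"
    cat(sprintf("  %s  [%s]\n", x$id[i], tax))
  }
  if (length(x$id) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.aligned_db <- function(x) length(x$id)

#' Subset an aligned database by index or record id
#' @param x An `aligned_db`.
#' @param i Integer/logical indices or character ids.
#' @param ... Unused.
#' @export
`[.aligned_db` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$id)
    if (anyNA(idx)) {
      stop("unknown record id(s): ", paste(i[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    i <- idx
  }
  aligned_db(x$id[i], x$seq[i], x$taxonomy[i])
}

#' Read a gapped FASTA file with embedded taxonomy
#'
#' Parses aligned FASTA in the SILVA "SSU Ref" dialect: the header carries
#' the record id up to the first whitespace and a separator-delimited
#' taxonomy path in the remainder. `U` is normalized to `T`; `-` and `.`
#' are both kept as gap characters.
#'
#' @param path FASTA file path.
#' @param taxonomy_separator Separator between rank labels (default `;`).
#' @param taxonomy_table Optional two-column data frame (id, taxstring) used
#'   as taxonomy source instead of the headers.
#' @return An [aligned_db()].
#' @export
read_aligned_fasta <- function(path, taxonomy_separator = ";",
                               taxonomy_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  taxstring <- ifelse(grepl("\\s", headers),
                      sub("^\\S+\\s+", "", headers), "")
  if (!is.null(taxonomy_table)) {
    m <- match(id, as.character(taxonomy_table[[1L]]))
    taxstring <- ifelse(is.na(m), "", as.character(taxonomy_table[[2L]])[m])
  }
  taxonomy <- lapply(taxstring, function(s) {
    if (!nzchar(s)) return(character(0))
    parts <- trimws(strsplit(s, taxonomy_separator, fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
  })
  aligned_db(id, as.character(set), taxonomy)
}

#' Write an aligned database to gapped FASTA
#'
#' Inverse of [read_aligned_fasta()]: taxonomy is embedded in the header
#' after the id, rank labels joined by the separator.
#'
#' @param db An `aligned_db`.
#' @param path Output file path.
#' @param taxonomy_separator Separator between rank labels.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(db, path, taxonomy_separator = ";") {
  stopifnot(inherits(db, "aligned_db"))
  taxstring <- vapply(db$taxonomy, paste, "", collapse = taxonomy_separator)
  headers <- ifelse(nzchar(taxstring), paste(db$id, taxstring), db$id)
  set <- Biostrings::BStringSet(db$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# n_records x alignment_length character matrix
.db_matrix <- function(db) {
  matrix(unlist(strsplit(db$seq, "", fixed = TRUE), use.names = FALSE),
         nrow = length(db$id), byrow = TRUE)
}

.is_gap <- function(chars) chars == "-" | chars == "."

#' Trim an alignment to well-covered columns
#'
#' Keeps exactly the columns whose fraction of non-gap characters is at
#' least `coverage_threshold`, preserving column order and recording the
#' original 1-based indices of the kept columns (so positions can be mapped
#' back to the untrimmed alignment).
#'
#' @param db An `aligned_db`.
#' @param coverage_threshold Fraction in (0, 1]; default 0.9, i.e. keep
#'   positions represented by 90% of the sequences.
#' @return A `trimmed_alignment`: list with elements `db` (trimmed
#'   `aligned_db`), `kept_columns` (integer), `coverage_threshold`.
#' @export
trim_alignment <- function(db, coverage_threshold = 0.9) {
  stopifnot(inherits(db, "aligned_db"))
  if (!(coverage_threshold > 0 && coverage_threshold <= 1)) {
    stop("coverage_threshold must be in (0, 1]", call. = FALSE)
  }
  m <- .db_matrix(db)
  nongap_frac <- colMeans(!.is_gap(m))
  kept <- which(nongap_frac >= coverage_threshold)
  seqs <- if (length(kept)) {
    apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  } else {
    rep("", length(db$id))
  }
  trimmed <- if (length(kept)) {
    aligned_db(db$id, seqs, db$taxonomy)
  } else {
    structure(list(id = db$id, seq = seqs, taxonomy = db$taxonomy),
              class = "aligned_db")
  }
  structure(
    list(db = trimmed, kept_columns = as.integer(kept),
         coverage_threshold = coverage_threshold),
    class = "trimmed_alignment"
  )
}

#' @export
print.trimmed_alignment <- function(x, ...) {
  cat("trimmed_alignment:", length(x$db$id), "records,",
      length(x$kept_columns), "columns kept (threshold",
      x$coverage_threshold, ")\n")
  invisible(x)
}

#' Shannon entropy of alignment columns
#'
#' Entropy in bits of the A/C/G/T frequency distribution at each requested
#' column. Gaps and ambiguity codes are excluded from the frequency counts.
#' A column with no countable bases yields `NA` with a warning (undefined
#' value); a column with a single distinct base yields 0.
#'
#' @param db An `aligned_db` or `trimmed_alignment`.
#' @param columns Integer column indices; default all columns.
#' @return Numeric vector of entropies in bits, in `[0, 2]` (or `NA`).
#' @export
column_entropy <- function(db, columns = NULL) {
  if (inherits(db, "trimmed_alignment")) db <- db$db
  stopifnot(inherits(db, "aligned_db"))
  m <- .db_matrix(db)
  if (is.null(columns)) columns <- seq_len(ncol(m))
  if (any(columns < 1L | columns > ncol(m))) {
    stop("column index out of range", call. = FALSE)
  }
  vapply(columns, function(j) {
    col <- m[, j]
    counts <- c(sum(col == "A"), sum(col == "C"),
                sum(col == "G"), sum(col == "T"))
    total <- sum(counts)
    if (total == 0L) {
      warning("column ", j, " has no countable bases; entropy undefined")
      return(NA_real_)
    }
    p <- counts[counts > 0L] / total
    -sum(p * log2(p))
  }, numeric(1))
}

#' Map alignment columns to ungapped positions of a reference record
#'
#' For a named reference sequence in the database, gives for every alignment
#' column the 1-based position in the ungapped reference (the cumulative
#' count of non-gap reference characters up to that column), or `NA` where
#' the reference itself has a gap. Standard practice for reporting primer
#' positions in the coordinates of a well-known gene (e.g. the
#' *S. cerevisiae* 18S rRNA gene).
#'
#' @param db An `aligned_db`.
#' @param reference_id Id of the reference record.
#' @return A `reference_map`: integer vector (length = alignment length)
#'   with `NA` at reference gap columns, plus attribute `reference_id`.
#' @export
build_reference_map <- function(db, reference_id) {
  stopifnot(inherits(db, "aligned_db"))
  i <- match(reference_id, db$id)
  if (is.na(i)) stop("unknown reference id: ", reference_id, call. = FALSE)
  chars <- strsplit(db$seq[i], "", fixed = TRUE)[[1L]]
  nongap <- !.is_gap(chars)
  pos <- cumsum(nongap)
  pos[!nongap] <- NA_integer_
  structure(as.integer(pos), reference_id = reference_id,
            class = "reference_map")
}

# ungapped sequences of a db (character vector, names = ids)
.degap <- function(seqs) {
  gsub("[-.]", "", seqs)
}

#' Ungapped sequences of a database
#' @param db An `aligned_db` or `trimmed_alignment`.
#' @return Named character vector of ungapped sequences.
#' @export
ungapped_sequences <- function(db) {
  if (inherits(db, "trimmed_alignment")) db <- db$db
  stopifnot(inherits(db, "aligned_db"))
  stats::setNames(.degap(db$seq), db$id)
}
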