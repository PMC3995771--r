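# Leave-self-out best-hit benchmark of simulated reads.
#
# The search engine is internal and self-contained: an 11-mer prefilter
# selects candidate subjects, which are then scored by gapped local
# alignment with blastn-like constants (match +2, mismatch -3, gap open 5,
# gap extend 2). E-values follow the Karlin-Altschul form
# E = m * n * 2^(-bitscore), with bitscore = (lambda*S - ln K) / ln 2 and
# the published gapped constants for this scoring scheme
# (lambda = 0.625, K = 0.41). These are a documented stand-in for BLASTN,
# not a claim of bit-compatibility; rankings, not absolute e-values, drive
# the benchmark.

.SEARCH_LAMBDA <- 0.625
.SEARCH_K <- 0.41

#' Combine e-values of a read pair
#'
#' The combined score of a multi-read query is the arithmetic mean of the
#' per-read log10 e-values (roughly equivalent to averaging bit scores).
#' Lower is better.
#'
#' @param evalues Numeric vector of positive e-values.
#' @return Mean of `log10(evalues)`.
#' @examples
#' combine_evalues(c(1e-10, 1e-4))  # -7
#' @export
combine_evalues <- function(evalues) {
  if (!length(evalues) || any(evalues <= 0)) {
    stop("e-values must be positive", call. = FALSE)
  }
  mean(log10(evalues))
}

#' Sample benchmark query records
#'
#' Uniform sample without replacement from the records eligible as
#' benchmark queries: optionally only records with fully defined taxonomy
#' (path reaching the database's maximum rank depth) and only records
#' carrying a binding site (either strand) for every primer in
#' `require_matched_by`.
#'
#' @param db An `aligned_db`.
#' @param n Number of queries.
#' @param require_full_taxonomy Restrict to records with full-depth
#'   taxonomy.
#' @param require_matched_by Character vector of IUPAC primers that must
#'   all have a binding site on the record.
#' @param seed Integer seed; the sample is reproducible.
#' @return An `aligned_db` of the sampled records.
#' @export
sample_queries <- function(db, n, require_full_taxonomy = TRUE,
                           require_matched_by = NULL, seed = 1L) {
  stopifnot(inherits(db, "aligned_db"))
  eligible <- rep(TRUE, length(db$id))
  if (require_full_taxonomy) {
    depth <- max(lengths(db$taxonomy))
    eligible <- eligible & lengths(db$taxonomy) == depth
  }
  if (!is.null(require_matched_by)) {
    for (p in require_matched_by) {
      sites <- find_binding_sites(p, db, search_both_strands = TRUE)
      eligible <- eligible & db$id %in% sites$record_id
    }
  }
  pool <- which(eligible)
  if (length(pool) < n) {
    stop("eligible pool (", length(pool), ") smaller than n = ", n,
         call. = FALSE)
  }
  set.seed(seed)
  db[sort(sample(pool, n))]
}

#' Build a k-mer search index over a database
#'
#' @param db An `aligned_db` (or named character vector of ungapped
#'   sequences).
#' @param k K-mer length for the candidate prefilter (default 11).
#' @return A `search_index` used by [search_best_hit()].
#' @export
build_search_index <- function(db, k = 11L) {
  seqs <- if (inherits(db, "aligned_db")) ungapped_sequences(db) else db
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  kmer_map <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- unique(substring(s, starts, starts + k - 1L))
    for (km in kmers) {
      kmer_map[[km]] <- c(kmer_map[[km]], i)
    }
  }
  structure(
    list(seqs = seqs, ids = names(seqs), k = as.integer(k),
         kmer_map = kmer_map, total_length = sum(nchar(seqs)),
         subjects = Biostrings::DNAStringSet(seqs),
         submat = Biostrings::nucleotideSubstitutionMatrix(
           match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA")),
    class = "search_index"
  )
}

.candidate_subjects <- function(index, read) {
  n <- nchar(read)
  k <- index$k
  if (n < k) return(seq_along(index$seqs))
  starts <- seq_len(n - k + 1L)
  # both strands: a read may be reverse-complement oriented wrt the database
  kmers <- unique(c(substring(read, starts, starts + k - 1L),
                    substring(reverse_complement(read), starts,
                              starts + k - 1L)))
  idx <- unlist(lapply(kmers, function(km) index$kmer_map[[km]]),
                use.names = FALSE)
  sort(unique(idx))
}

# gapped local alignment of one read against many subjects in one call
# (the subjects go in as patterns, which lets Biostrings vectorize; local
# alignment scores and aligned-column statistics are orientation-symmetric)
.align_many <- function(read, subjects_dna, total_length, submat) {
  read_length <- nchar(read)
  aln <- Biostrings::pairwiseAlignment(
    pattern = subjects_dna, subject = Biostrings::DNAString(read),
    type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2)
  s <- Biostrings::score(aln)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ni <- Biostrings::nindel(aln)
  gap_cols <- Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  aln_len <- nm + nmm + gap_cols
  identity <- ifelse(aln_len > 0L, nm / aln_len, 0)
  # read bases consumed by the local alignment (the read is "subject" here)
  aligned_read <- BiocGenerics::end(Biostrings::subject(aln)) -
    BiocGenerics::start(Biostrings::subject(aln)) + 1L
  bit <- (.SEARCH_LAMBDA * s - log(.SEARCH_K)) / log(2)
  evalue <- read_length * total_length * 2^(-bit)
  data.frame(score = s, identity = identity,
             aligned_fraction = aligned_read / read_length,
             evalue = evalue)
}

# strand-aware: a read has one orientation with respect to an
# orientation-normalized database, so the strand is resolved per read: the
# read is aligned as given against all candidates, and only if no candidate
# passes is the reverse complement tried (reverse reads of a pair are
# reverse-complement oriented and always take this branch)
.align_many_2strand <- function(read, subjects_dna, total_length, submat,
                                min_identity, min_read_coverage,
                                max_evalue) {
  passes <- function(x) {
    x$aligned_fraction >= min_read_coverage & x$identity >= min_identity &
      x$evalue <= max_evalue
  }
  f <- .align_many(read, subjects_dna, total_length, submat)
  f$pass <- passes(f)
  if (any(f$pass)) return(f)
  r <- .align_many(reverse_complement(read), subjects_dna, total_length,
                   submat)
  r$pass <- passes(r)
  if (any(r$pass)) return(r)
  use_r <- r$score > f$score
  f[use_r, ] <- r[use_r, ]
  f
}

#' Best database hit for a query's read(s)
#'
#' Searches the reads of one query against a database: an exact k-mer
#' prefilter proposes candidate subjects, each candidate is scored by
#' gapped local alignment per read (both strands are tried, since reverse
#' reads are reverse-complement oriented with respect to the database), and
#' a candidate passes only if *every*
#' read aligns with at least `min_read_coverage` of its length, at least
#' `min_identity` identity over the aligned columns, and e-value at most
#' `max_evalue`. Among passing subjects the one with the lowest combined
#' score ([combine_evalues()] of the per-read e-values; for a single read,
#' its log10 e-value) wins; ties break by higher mean identity, then
#' lexicographic subject id. Subjects in `exclude` (typically the query's
#' own id, for leave-self-out benchmarking) are never returned.
#'
#' @param reads Character vector of 1 (single-end) or 2 (paired) reads.
#' @param index A `search_index` from [build_search_index()].
#' @param min_identity Minimum identity over aligned columns (default
#'   0.99).
#' @param min_read_coverage Minimum aligned fraction of each read's length
#'   (default 0.95).
#' @param max_evalue Maximum per-read e-value (default 1e-5).
#' @param exclude Character vector of subject ids to exclude.
#' @param prefilter Use the k-mer prefilter (default) or score every
#'   subject exhaustively.
#' @return A list (`subject_id`, `combined_score`, `identity`, `evalues`,
#'   `aligned_fractions`), or `NULL` if no subject passes.
#' @export
search_best_hit <- function(reads, index, min_identity = 0.99,
                            min_read_coverage = 0.95, max_evalue = 1e-5,
                            exclude = character(0), prefilter = TRUE) {
  stopifnot(inherits(index, "search_index"), length(reads) >= 1L)
  cand <- if (prefilter) {
    sort(unique(unlist(lapply(reads, .candidate_subjects, index = index))))
  } else {
    seq_along(index$seqs)
  }
  cand <- cand[!(index$ids[cand] %in% exclude)]
  if (!length(cand)) return(NULL)
  per_read <- lapply(reads, .align_many_2strand,
                     subjects_dna = index$subjects[cand],
                     total_length = index$total_length,
                     submat = index$submat, min_identity = min_identity,
                     min_read_coverage = min_read_coverage,
                     max_evalue = max_evalue)
  pass_all <- Reduce(`&`, lapply(per_read, `[[`, "pass"))
  if (!any(pass_all)) return(NULL)
  ev_mat <- do.call(cbind, lapply(per_read, `[[`, "evalue"))
  id_mat <- do.call(cbind, lapply(per_read, `[[`, "identity"))
  af_mat <- do.call(cbind, lapply(per_read, `[[`, "aligned_fraction"))
  combined <- rowMeans(log10(ev_mat))
  mean_id <- rowMeans(id_mat)
  ids <- index$ids[cand]
  ord <- order(!pass_all, combined, -mean_id, ids)[1L]
  list(subject_id = ids[ord], combined_score = combined[ord],
       identity = mean_id[ord], evalues = ev_mat[ord, ],
       aligned_fractions = af_mat[ord, ])
}

#' Classify query-vs-hit taxonomic agreement
#'
#' Compares two root-to-leaf taxonomy paths. The query must be annotated to
#' full depth (species = last rank, genus = second-to-last). A hit not
#' annotated at least to family depth (two ranks above species) is
#' excluded from accuracy statistics.
#'
#' @param query_taxonomy,hit_taxonomy Character vectors of rank labels,
#'   root to leaf.
#' @return One of `"species"`, `"genus"`, `"above_genus"`,
#'   `"misassigned"`, `"excluded_hit_unannotated"`.
#' @export
assess_agreement <- function(query_taxonomy, hit_taxonomy) {
  d <- length(query_taxonomy)
  stopifnot(d >= 3L)
  if (length(hit_taxonomy) < d - 2L) return("excluded_hit_unannotated")
  eq_through <- function(depth) {
    length(hit_taxonomy) >= depth &&
      identical(query_taxonomy[seq_len(depth)], hit_taxonomy[seq_len(depth)])
  }
  if (eq_through(d)) return("species")
  if (eq_through(d - 1L)) return("genus")
  if (eq_through(d - 2L)) return("above_genus")
  "misassigned"
}

#' Gap-aware distance between two aligned full-length sequences
#'
#' Pairwise distance on the original gapped alignment, with the gap
#' conventions of one-gap distance calculators: terminal gaps are
#' disregarded (comparison restricted to the columns between the first and
#' last position where both sequences have bases); columns where both
#' sequences are gapped are skipped; a maximal run of columns where exactly
#' one sequence is gapped counts as a single difference and a single
#' compared unit; base-base columns count one unit each and one difference
#' if mismatched. Distance = differences / compared units. With gap runs
#' collapsed this way the measure is symmetric with zero self-distance but
#' is not guaranteed to satisfy the triangle inequality.
#'
#' @param aligned_a,aligned_b Gapped strings of equal length.
#' @return Distance in `[0, 1]`, or `NA` with a warning if no columns are
#'   comparable.
#' @examples
#' full_length_distance("AC-GT", "ACCGT")  # 0.2 (1 gap event / 5 units)
#' @export
full_length_distance <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal gapped length", call. = FALSE)
  }
  ga <- .is_gap(a)
  gb <- .is_gap(b)
  both_base <- !ga & !gb
  if (!any(both_base)) {
    warning("no columns where both sequences have bases; ",
            "distance undefined")
    return(NA_real_)
  }
  span <- range(which(both_base))
  keep <- seq(span[1L], span[2L])
  a <- a[keep]; b <- b[keep]; ga <- ga[keep]; gb <- gb[keep]
  # drop both-gap columns entirely (transparent: they do not break a run)
  use <- !(ga & gb)
  a <- a[use]; b <- b[use]; ga <- ga[use]; gb <- gb[use]
  state <- ifelse(!ga & !gb, 0L, ifelse(ga, 1L, 2L))
  r <- rle(state)
  gap_runs <- sum(r$values != 0L)
  bb <- state == 0L
  mismatches <- sum(a[bb] != b[bb])
  units <- sum(bb) + gap_runs
  (mismatches + gap_runs) / units
}

#' Run the full taxonomic assignment benchmark
#'
#' End-to-end pipeline: sample query records (fully annotated and matched
#' by both primers), simulate error-free reads for the requested layout,
#' search each query's reads against the whole database with the query's
#' own record excluded, stratify the taxonomic agreement of the best hit,
#' and compute the gap-aware full-length distance between query and hit.
#'
#' @param db An `aligned_db` (the reference database).
#' @param fwd_primer,rev_primer IUPAC primer pair.
#' @param read_length Read length in bases.
#' @param paired Paired-end layout?
#' @param n_queries Number of query records to sample.
#' @param min_identity,min_read_coverage,max_evalue Hit acceptance
#'   thresholds (defaults 0.99, 0.95, 1e-5).
#' @param seed Integer seed for query sampling (the only stochastic step).
#' @param index Optional pre-built [build_search_index()] of `db`.
#' @return A `benchmark_result` list: `assignments` (query_id, hit_id,
#'   combined_score, identity, category), `distances` (query_id, hit_id,
#'   distance), `accuracy` (category fractions among non-excluded
#'   assignments, cumulative at species -> genus -> above_genus), and
#'   `params`.
#' @export
run_benchmark <- function(db, fwd_primer, rev_primer, read_length = 250L,
                          paired = TRUE, n_queries = 100L,
                          min_identity = 0.99, min_read_coverage = 0.95,
                          max_evalue = 1e-5, seed = 1L, index = NULL) {
  stopifnot(inherits(db, "aligned_db"))
  queries <- sample_queries(
    db, n_queries, require_full_taxonomy = TRUE,
    require_matched_by = c(fwd_primer, reverse_complement(rev_primer)),
    seed = seed)
  amp <- simulate_amplicons(queries, fwd_primer, rev_primer,
                            read_length = read_length, paired = paired)
  if (is.null(index)) index <- build_search_index(db)
  tax_of <- function(id) db$taxonomy[[match(id, db$id)]]
  aligned_of <- function(id) db$seq[match(id, db$id)]
  assignments <- vector("list", nrow(amp))
  distances <- vector("list", nrow(amp))
  for (i in seq_len(nrow(amp))) {
    qid <- amp$record_id[i]
    reads <- if (paired) c(amp$fwd_read[i], amp$rev_read[i])
             else amp$fwd_read[i]
    hit <- search_best_hit(reads, index, min_identity = min_identity,
                           min_read_coverage = min_read_coverage,
                           max_evalue = max_evalue, exclude = qid)
    if (is.null(hit)) {
      assignments[[i]] <- data.frame(
        query_id = qid, hit_id = NA_character_, combined_score = NA_real_,
        identity = NA_real_, category = "no_hit", stringsAsFactors = FALSE)
    } else {
      cat_ <- assess_agreement(tax_of(qid), tax_of(hit$subject_id))
      assignments[[i]] <- data.frame(
        query_id = qid, hit_id = hit$subject_id,
        combined_score = hit$combined_score, identity = hit$identity,
        category = cat_, stringsAsFactors = FALSE)
      distances[[i]] <- data.frame(
        query_id = qid, hit_id = hit$subject_id,
        distance = full_length_distance(aligned_of(qid),
                                        aligned_of(hit$subject_id)),
        stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, assignments)
  distances <- if (any(!vapply(distances, is.null, logical(1)))) {
    do.call(rbind, distances)
  } else {
    data.frame(query_id = character(0), hit_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  }
  assessed <- assignments$category %in%
    c("species", "genus", "above_genus", "misassigned")
  n_assessed <- sum(assessed)
  frac <- function(cats) {
    if (n_assessed == 0L) return(NA_real_)
    sum(assignments$category[assessed] %in% cats) / n_assessed
  }
  accuracy <- data.frame(
    level = c("species", "genus", "above_genus", "misassigned"),
    fraction = c(frac("species"), frac("genus"), frac("above_genus"),
                 frac("misassigned")),
    cumulative = c(frac("species"), frac(c("species", "genus")),
                   frac(c("species", "genus", "above_genus")), NA_real_),
    stringsAsFactors = FALSE)
  structure(
    list(assignments = assignments, distances = distances,
         accuracy = accuracy,
         n_assessed = n_assessed,
         n_excluded = sum(assignments$category == "excluded_hit_unannotated"),
         n_no_hit = sum(assignments$category == "no_hit"),
         n_amplified = nrow(amp),
         params = list(fwd = fwd_primer, rev = rev_primer,
                       read_length = read_length, paired = paired,
                       n_queries = n_queries, min_identity = min_identity,
                       min_read_coverage = min_read_coverage,
                       max_evalue = max_evalue, seed = seed)),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("benchmark_result: %s / %s, %s%d bp, %d queries\n",
              p$fwd, p$rev, if (p$paired) "2x" else "1x", p$read_length,
              p$n_queries))
  cat(sprintf("  assessed %d, excluded (hit unannotated) %d, no hit %d\n",
              x$n_assessed, x$n_excluded, x$n_no_hit))
  print(x$accuracy)
  invisible(x)
}
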