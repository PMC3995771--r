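# Synthetic SILVA-like aligned reference databases with known ground truth.
#
# A root sequence is evolved down a fixed-fan-out taxonomy tree. The
# alignment is built on a single master coordinate system: each region
# block carries a quota of reserved columns that are gaps in the root;
# insertion events fill a run of reserved columns for one lineage,
# deletion events turn real columns into gaps, so all records stay aligned
# without recomputation. Substitutions are uniform Jukes-Cantor-style
# replacements; indel lengths are geometric with mean 2. Planted IUPAC
# motifs are overwritten after evolution, one concrete expansion sampled
# per record, so recovering the degenerate consensus is nontrivial.

.RANK_LETTERS <- c("k", "p", "c", "o", "f", "g", "s")

#' Specify a synthetic reference database
#'
#' @param n_taxa_per_rank Integer vector of tree fan-outs, root rank to
#'   species (e.g. `c(5, 4, 5)` = 5 top-rank taxa x 4 genera x 5 species).
#' @param seqs_per_species Records generated per species.
#' @param region_blocks Data frame with columns `length` (bases),
#'   `subst_rate` (per-branch per-site substitution probability) and
#'   `indel_rate` (per-branch per-site indel event probability), one row
#'   per alternating conserved/variable block.
#' @param planted_sites Optional list of `list(motif = <IUPAC string>,
#'   block = <block index>)`: motifs overwritten into every record at a
#'   fixed position inside the block.
#' @param seed Integer seed; generation is fully deterministic.
#' @param rank_scale Optional numeric vector, one multiplier per tree level
#'   (ranks root to species, plus one final level for records within a
#'   species), scaling the per-branch rates so that divergence can differ
#'   between deep and shallow branches. Default all 1.
#' @param ins_capacity Fraction of extra reserved (insertion) columns per
#'   block (default 0.15).
#' @return A `synthetic_db_spec`.
#' @export
synthetic_db_spec <- function(n_taxa_per_rank, seqs_per_species,
                              region_blocks, planted_sites = list(),
                              seed = 1L, rank_scale = NULL,
                              ins_capacity = 0.15) {
  stopifnot(all(n_taxa_per_rank >= 1L), seqs_per_species >= 1L,
            is.data.frame(region_blocks),
            all(c("length", "subst_rate", "indel_rate") %in%
                  names(region_blocks)),
            all(region_blocks$subst_rate >= 0 & region_blocks$subst_rate < 1),
            all(region_blocks$indel_rate >= 0 & region_blocks$indel_rate < 1))
  n_levels <- length(n_taxa_per_rank) + 1L
  if (is.null(rank_scale)) rank_scale <- rep(1, n_levels)
  stopifnot(length(rank_scale) == n_levels, all(rank_scale >= 0))
  for (ps in planted_sites) {
    stopifnot(is.list(ps), !is.null(ps$motif), !is.null(ps$block),
              ps$block >= 1L, ps$block <= nrow(region_blocks),
              nchar(ps$motif) <= region_blocks$length[ps$block])
  }
  structure(
    list(n_taxa_per_rank = as.integer(n_taxa_per_rank),
         seqs_per_species = as.integer(seqs_per_species),
         region_blocks = region_blocks, planted_sites = planted_sites,
         seed = as.integer(seed), rank_scale = rank_scale,
         ins_capacity = ins_capacity),
    class = "synthetic_db_spec"
  )
}

.rank_labels <- function(depth) {
  if (depth <= length(.RANK_LETTERS)) {
    utils::tail(.RANK_LETTERS, depth)
  } else {
    c(paste0("r", seq_len(depth - length(.RANK_LETTERS))), .RANK_LETTERS)
  }
}

# one child sequence from a parent, per-block rates scaled by `scale`
.evolve_branch <- function(seq_chars, block_of, blocks, scale) {
  bases <- c("A", "C", "G", "T")
  for (b in seq_len(nrow(blocks))) {
    cols <- which(block_of == b)
    nongap <- cols[seq_chars[cols] != "-"]
    # substitutions
    p_sub <- blocks$subst_rate[b] * scale
    if (p_sub > 0 && length(nongap)) {
      hit <- nongap[stats::runif(length(nongap)) < p_sub]
      for (j in hit) {
        seq_chars[j] <- sample(setdiff(bases, seq_chars[j]), 1L)
      }
    }
    # indels
    p_indel <- blocks$indel_rate[b] * scale
    if (p_indel > 0 && length(nongap)) {
      n_events <- stats::rbinom(1L, length(nongap), p_indel)
      for (e in seq_len(n_events)) {
        g <- stats::rgeom(1L, 0.5) + 1L
        if (stats::runif(1L) < 0.5) {
          # deletion: gap out a run of currently non-gap columns
          ng <- cols[seq_chars[cols] != "-"]
          if (!length(ng)) next
          s <- sample(length(ng), 1L)
          seq_chars[ng[s:min(length(ng), s + g - 1L)]] <- "-"
        } else {
          # insertion: fill a run of currently-gap (reserved) columns
          gp <- cols[seq_chars[cols] == "-"]
          if (!length(gp)) next
          s <- sample(length(gp), 1L)
          fill <- gp[s:min(length(gp), s + g - 1L)]
          seq_chars[fill] <- sample(bases, length(fill), replace = TRUE)
        }
      }
    }
  }
  seq_chars
}

#' Generate a synthetic aligned reference database
#'
#' Draws a root sequence, evolves it down the taxonomy tree defined by the
#' spec, pads everything into one gapped coordinate system, overwrites any
#' planted primer-site motifs (one concrete expansion per record), and
#' attaches synthetic taxonomy paths (labels like `"k1;p2;...;s5"`).
#'
#' @param spec A [synthetic_db_spec()].
#' @return A list of class `synthetic_db`: `db` (an [aligned_db()]) and
#'   `truth` (list: `taxonomy` data frame, `sites` data frame with the
#'   per-record planted-site coordinates, `block_columns` mapping columns
#'   to blocks, `spec`).
#' @export
generate_synthetic_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_db_spec"))
  set.seed(spec$seed)
  blocks <- spec$region_blocks
  bases <- c("A", "C", "G", "T")

  # master coordinate system: real + reserved columns per block
  block_of <- integer(0)
  is_reserved <- logical(0)
  for (b in seq_len(nrow(blocks))) {
    n_real <- blocks$length[b]
    n_res <- ceiling(n_real * spec$ins_capacity)
    res_flags <- c(rep(FALSE, n_real), rep(TRUE, n_res))
    res_flags <- sample(res_flags)
    block_of <- c(block_of, rep(b, n_real + n_res))
    is_reserved <- c(is_reserved, res_flags)
  }
  total <- length(block_of)
  root <- character(total)
  root[!is_reserved] <- sample(bases, sum(!is_reserved), replace = TRUE)
  root[is_reserved] <- "-"

  depth <- length(spec$n_taxa_per_rank)
  letters_ <- .rank_labels(depth)
  counters <- integer(depth)

  records <- list()
  taxonomies <- list()
  recurse <- function(seq_chars, level, path) {
    if (level > depth) {
      # records within a species
      for (r in seq_len(spec$seqs_per_species)) {
        child <- .evolve_branch(seq_chars, block_of, blocks,
                                spec$rank_scale[depth + 1L])
        id <- sprintf("%s_r%d", paste(path, collapse = "."), r)
        records[[length(records) + 1L]] <<- child
        taxonomies[[length(taxonomies) + 1L]] <<-
          list(id = id, path = path)
      }
      return(invisible())
    }
    for (tx in seq_len(spec$n_taxa_per_rank[level])) {
      counters[level] <<- counters[level] + 1L
      label <- paste0(letters_[level], counters[level])
      child <- .evolve_branch(seq_chars, block_of, blocks,
                              spec$rank_scale[level])
      recurse(child, level + 1L, c(path, label))
    }
    invisible()
  }
  recurse(root, 1L, character(0))

  ids <- vapply(taxonomies, function(t) t$id, character(1))
  tax_paths <- lapply(taxonomies, function(t) t$path)

  # plant motifs: fixed column window per site, fresh expansion per record
  sites <- list()
  for (si in seq_along(spec$planted_sites)) {
    ps <- spec$planted_sites[[si]]
    motif_bits <- iupac_bits(ps$motif)
    L <- length(motif_bits)
    real_cols <- which(block_of == ps$block & !is_reserved)
    offset <- if (length(real_cols) > L) {
      sample(length(real_cols) - L, 1L)
    } else 1L
    cols <- real_cols[offset:(offset + L - 1L)]
    for (i in seq_along(records)) {
      expansion <- vapply(motif_bits, function(bb) {
        sample(bases[bitwAnd(bb, c(1L, 2L, 4L, 8L)) > 0L], 1L)
      }, character(1))
      records[[i]][cols] <- expansion
      ungapped_start <- sum(records[[i]][seq_len(cols[1L] - 1L)] != "-") + 1L
      sites[[length(sites) + 1L]] <- data.frame(
        record_id = ids[i], motif = ps$motif, motif_index = si,
        column_start = cols[1L], ungapped_start = ungapped_start,
        stringsAsFactors = FALSE)
    }
  }

  seqs <- vapply(records, paste, "", collapse = "")
  db <- aligned_db(ids, seqs, tax_paths)
  truth <- list(
    taxonomy = data.frame(
      record_id = ids,
      taxonomy = vapply(tax_paths, paste, "", collapse = ";"),
      stringsAsFactors = FALSE),
    sites = if (length(sites)) do.call(rbind, sites) else
      data.frame(record_id = character(0), motif = character(0),
                 motif_index = integer(0), column_start = integer(0),
                 ungapped_start = integer(0), stringsAsFactors = FALSE),
    block_columns = data.frame(column = seq_len(total), block = block_of,
                               reserved = is_reserved),
    spec = spec)
  structure(list(db = db, truth = truth), class = "synthetic_db")
}

#' @export
print.synthetic_db <- function(x, ...) {
  cat("synthetic_db:", length(x$db$id), "records,",
      nchar(x$db$seq[1L]), "columns,",
      nrow(x$truth$sites), "planted site entries\n")
  invisible(x)
}

#' Serialize synthetic ground truth to a TSV-shaped data frame
#'
#' One row per record: its taxonomy path and, for each planted motif, the
#' ungapped start coordinate of the planted site.
#'
#' @param truth The `truth` element of a [generate_synthetic_db()] result
#'   (or the `synthetic_db` itself).
#' @param path Optional file path; when given, the table is written as TSV.
#' @return The report data frame, invisibly when written to file.
#' @export
truth_report <- function(truth, path = NULL) {
  if (inherits(truth, "synthetic_db")) truth <- truth$truth
  out <- truth$taxonomy
  if (nrow(truth$sites)) {
    for (si in unique(truth$sites$motif_index)) {
      ss <- truth$sites[truth$sites$motif_index == si, ]
      col <- stats::setNames(ss$ungapped_start, ss$record_id)
      out[[paste0("site", si, "_start")]] <-
        unname(col[out$record_id])
    }
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
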