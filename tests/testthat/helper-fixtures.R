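# Shared fixtures and independent oracles, built in code at test time.

# small aligned db from bare sequences
make_db <- function(seqs, taxonomy = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  aligned_db(ids, seqs, taxonomy)
}

# random gapped alignment (characters incl. gaps), n records x len columns
random_alignment <- function(n, len, gap_prob = 0.1, seed = 1) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), len,
                                    replace = TRUE,
                                    prob = c(rep((1 - gap_prob) / 4, 4),
                                             gap_prob)),
                             collapse = ""))
  make_db(seqs)
}

# brute-force Shannon entropy of one column (independent of the package's
# counting code path)
oracle_entropy <- function(db, column) {
  chars <- vapply(db$seq, function(s) substr(s, column, column), "")
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (!length(chars)) return(NA_real_)
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# exact maximum-coverage oligo score by flat enumeration of all variant
# subsets (any optimal oligo is the per-position union of the variants it
# covers, so subset enumeration is exhaustive); independent of the DFS in
# the package
oracle_best_score <- function(variants, max_degeneracy) {
  iupac_sizes <- c(A = 1, C = 1, G = 1, T = 1)
  bits_of <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vb <- vapply(strsplit(names(variants), ""),
               function(ch) unname(bits_of[ch]),
               integer(nchar(names(variants)[1])))
  vb <- matrix(vb, nrow = nchar(names(variants)[1]))
  counts <- unname(variants)
  k <- ncol(vb)
  n_bits <- function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
  best <- 0
  for (mask in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    if (!length(members)) next
    u <- Reduce(bitwOr, lapply(members, function(j) vb[, j]))
    deg <- prod(vapply(u, n_bits, numeric(1)))
    if (deg > max_degeneracy) next
    contained <- vapply(seq_len(k), function(j) {
      all(bitwAnd(vb[, j], u) == vb[, j])
    }, logical(1))
    best <- max(best, sum(counts[contained]))
  }
  best
}

# random IUPAC primer with bounded degeneracy (for arithmetic properties)
random_primer <- function(len, max_deg = 64, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  repeat {
    p <- paste(sample(codes, len, replace = TRUE,
                      prob = c(rep(0.2, 4), rep(0.03, 10), 0.02)),
               collapse = "")
    if (primer_degeneracy(p) <= max_deg) return(p)
  }
}

# the genus-separated benchmark fixture: conserved/variable architecture,
# low-degeneracy planted primer sites, branch lengths shaped so that
# between-genus full-length distance exceeds 5% while within-species stays
# below 0.5%
benchmark_fixture <- function(seed = 7) {
  blocks <- data.frame(length = c(100, 400, 100, 400, 100),
                       subst_rate = c(0.005, 0.05, 0.005, 0.05, 0.005),
                       indel_rate = c(0, 0.005, 0, 0.005, 0))
  fwd <- "GTGCCAGCMGCCGCGGTA"
  rev_site <- "ATTAGATACCCYGGTAGT"
  spec <- synthetic_db_spec(
    c(3, 3, 3), 3, blocks,
    planted_sites = list(list(motif = fwd, block = 1),
                         list(motif = rev_site, block = 5)),
    seed = seed, rank_scale = c(3, 0.8, 0.08, 0.01))
  gen <- generate_synthetic_db(spec)
  list(db = gen$db, truth = gen$truth, fwd = fwd,
       rev = reverse_complement(rev_site))
}

# small fast db for benchmark plumbing tests (2 families x 2 genera x
# 2 species x 2 records)
small_benchmark_fixture <- function(seed = 3) {
  blocks <- data.frame(length = c(60, 150, 60, 150, 60),
                       subst_rate = c(0.005, 0.05, 0.005, 0.05, 0.005),
                       indel_rate = c(0, 0.005, 0, 0.005, 0))
  fwd <- "GTGCCAGCMGCCGCGGTA"
  rev_site <- "ATTAGATACCCYGGTAGT"
  spec <- synthetic_db_spec(
    c(2, 2, 2), 2, blocks,
    planted_sites = list(list(motif = fwd, block = 1),
                         list(motif = rev_site, block = 5)),
    seed = seed, rank_scale = c(3, 0.8, 0.08, 0.01))
  gen <- generate_synthetic_db(spec)
  list(db = gen$db, truth = gen$truth, fwd = fwd,
       rev = reverse_complement(rev_site))
}

# mean gap-aware distance between two groups of record indices
mean_group_distance <- function(db, idx_pairs) {
  mean(vapply(idx_pairs, function(p) {
    full_length_distance(db$seq[p[1]], db$seq[p[2]])
  }, numeric(1)))
}
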