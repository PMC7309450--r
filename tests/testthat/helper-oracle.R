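# Independent oracles and fixture builders used across the suite.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_records <- function(n_contigs, len_range = c(50, 200), with_n = FALSE) {
  alphabet <- c("A", "C", "G", "T", if (with_n) "N")
  data.frame(
    id = sprintf("c%03d", seq_len(n_contigs)),
    sequence = vapply(seq_len(n_contigs), function(i) {
      rand_dna(sample(seq(len_range[1], len_range[2]), 1), alphabet)
    }, character(1))
  )
}

# String reverse complement independent of the package (Biostrings).
oracle_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Naive string-dictionary canonical k-mer counting: every ACGT-only window
# keyed by min(window, rc(window)) in lexicographic order.
oracle_profile <- function(seqs, k) {
  windows <- unlist(lapply(toupper(seqs), function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }))
  windows <- windows[!grepl("[^ACGT]", windows)]
  if (length(windows) == 0) return(stats::setNames(integer(0), character(0)))
  rcw <- oracle_rc(windows)
  canon <- ifelse(windows <= rcw, windows, rcw)
  tab <- table(canon)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Named count vector (k-mer string -> count) from a kmer_profile.
profile_as_named_counts <- function(p) {
  stats::setNames(as.integer(p$counts), decode_kmer(p$codes, p$k))
}

reverse_complement_records <- function(records) {
  records$sequence <- reverse_complement(records$sequence)
  records
}

# Random unrooted tree with strictly positive branch lengths and its
# (additive) cophenetic distance matrix.
rand_additive_matrix <- function(n_tips) {
  tree <- ape::rtree(n_tips, rooted = FALSE)
  tree$edge.length <- runif(length(tree$edge.length), 0.1, 2)
  D <- cophenetic(tree)
  labs <- sort(rownames(D))
  list(tree = tree, D = D[labs, labs])
}

# Labelled Euclidean distance matrix from a point configuration.
dist_matrix_from_points <- function(X) {
  D <- as.matrix(dist(X))
  labs <- sprintf("s%02d", seq_len(nrow(D)))
  dimnames(D) <- list(labs, labs)
  D
}

# Exact two-sided rank-sum p by full enumeration of rank assignments.
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(N, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

small_sim_config <- function(seed = 1, mutation_rate = 0.01,
                             n_samples = 3, source_length = 20000,
                             contigs = 10, contig_length = c(500, 1500)) {
  simulation_config(
    seed = seed, n_sources = 2, source_length = source_length,
    groups = list(
      list(label = "groupA", n_samples = n_samples, weights = c(1, 0)),
      list(label = "groupB", n_samples = n_samples, weights = c(0, 1))),
    contigs_per_sample = contigs, contig_length = contig_length,
    mutation_rate = mutation_rate)
}
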