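#' Reverse complement of DNA sequences
#'
#' Complements every base (A<->T, C<->G) and reverses the sequence, i.e.
#' reads it on the opposite strand. Vectorised over `seq`. Lowercase input is
#' folded to uppercase first.
#'
#' @param seq character vector of sequences over the alphabet {A,C,G,T}.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAC") # "GTT"
#' reverse_complement("ACGT") # its own reverse complement
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    kfc_error("sequence contains characters outside {A,C,G,T}",
              "kfc_invalid_alphabet")
  }
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

BASES <- c("A", "C", "G", "T")

check_k <- function(k) {
  if (length(k) != 1 || is.na(k) || k != as.integer(k) || k < 1 || k > 26) {
    kfc_error("k must be a single integer in [1, 26]", "kfc_unsupported_k")
  }
  as.integer(k)
}

#' Encode a k-mer as an integer code
#'
#' 2-bit packing with A=0, C=1, G=2, T=3, leftmost base most significant:
#' a bijection from length-k ACGT strings onto `[0, 4^k)` whose numeric order
#' equals lexicographic order. Codes are returned as doubles; they are exact
#' because k is capped at 26 (2k <= 52 mantissa bits).
#'
#' @param kmer character vector of k-mers (all of length `k`, alphabet ACGT).
#' @param k k-mer length, integer in \[1, 26\].
#' @return numeric vector of codes in `[0, 4^k)`.
#' @examples
#' encode_kmer("ACG", 3) # 6
#' @seealso [decode_kmer()], [canonical_code()]
#' @export
encode_kmer <- function(kmer, k) {
  k <- check_k(k)
  kmer <- toupper(kmer)
  if (any(nchar(kmer) != k)) {
    kfc_error("k-mer length does not match k", "kfc_invalid_alphabet")
  }
  vapply(kmer, function(w) {
    d <- match(strsplit(w, "", fixed = TRUE)[[1]], BASES) - 1
    if (anyNA(d)) {
      kfc_error("k-mer contains characters outside {A,C,G,T}",
                "kfc_invalid_alphabet")
    }
    sum(d * 4^((k - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decode an integer code back to a k-mer string
#'
#' Inverse of [encode_kmer()].
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @export
decode_kmer <- function(code, k) {
  k <- check_k(k)
  vapply(code, function(cd) {
    out <- character(k)
    for (i in k:1) {
      out[i] <- BASES[cd %% 4 + 1]
      cd <- cd %/% 4
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical code of a k-mer
#'
#' The smaller of the codes of a k-mer and of its reverse complement
#' (the Mash convention). Counting under canonical codes makes profiles
#' independent of contig strand.
#'
#' @inheritParams encode_kmer
#' @return numeric vector of canonical codes.
#' @examples
#' canonical_code("CGT", 3) # 6, the code of its reverse complement "ACG"
#' @export
canonical_code <- function(kmer, k) {
  pmin(encode_kmer(kmer, k), encode_kmer(reverse_complement(kmer), k))
}

new_kmer_profile <- function(k, codes, counts, total, sample_id = "") {
  structure(
    list(k = as.integer(k), codes = as.numeric(codes),
         counts = as.numeric(counts), total = as.numeric(total),
         sample_id = as.character(sample_id)),
    class = "kmer_profile"
  )
}

#' Build a k-mer profile from named counts
#'
#' Convenience constructor for small, hand-specified profiles: names of
#' `counts` are k-mer strings, which are canonicalised and merged.
#'
#' @param counts named numeric vector; names are k-mers, values are counts.
#' @param k k-mer length (default: nchar of the first name).
#' @param sample_id sample label.
#' @return a `kmer_profile`.
#' @examples
#' kmer_profile(c(ACG = 4, GTA = 2))
#' @export
kmer_profile <- function(counts, k = nchar(names(counts)[1]), sample_id = "") {
  k <- check_k(k)
  stopifnot(length(counts) > 0, !is.null(names(counts)), all(counts > 0))
  codes <- canonical_code(names(counts), k)
  agg <- tapply(as.numeric(counts), codes, sum)
  new_kmer_profile(k, as.numeric(names(agg)), as.numeric(agg),
                   sum(counts), sample_id)
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile: sample '%s', k = %d\n", x$sample_id, x$k))
  cat(sprintf("  %d distinct canonical k-mers, %s windows counted\n",
              length(x$codes), format(x$total, big.mark = ",")))
  invisible(x)
}

# Uppercase a sequence and map IUPAC ambiguity codes other than ACGT to N.
# Returns list(seq, n_substituted).
clean_sequence <- function(seq) {
  seq <- toupper(seq)
  n_sub <- sum(vapply(seq, function(s) {
    lengths(regmatches(s, gregexpr("[^ACGTN]", s)))
  }, integer(1)))
  if (n_sub > 0) seq <- gsub("[^ACGTN]", "N", seq)
  list(seq = seq, n_substituted = n_sub)
}

#' Profile a single sequence
#'
#' Counts every length-k window made solely of A/C/G/T under its canonical
#' code; windows containing N (or any other ambiguity code, which is treated
#' as N) are skipped. A sequence shorter than k yields an empty profile.
#'
#' @param seq a single DNA string (A/C/G/T/N, case-insensitive; other IUPAC
#'   codes are treated as N).
#' @param k k-mer length, integer in \[1, 26\].
#' @param sample_id optional sample label.
#' @return a `kmer_profile` with `total` = number of counted windows.
#' @examples
#' profile_sequence("ACGTACGT", 3)
#' @export
profile_sequence <- function(seq, k, sample_id = "") {
  stopifnot(length(seq) == 1)
  profile_sample(data.frame(id = "seq1", sequence = seq), k, sample_id)
}

#' Profile a sample's contig set
#'
#' Sums [profile_sequence()] over all contigs of one sample: counts are
#' merged by canonical code and `total` is the number of counted windows
#' across contigs. Raw counts are stored rather than frequencies; cosine
#' distance is invariant to positive scaling, so nothing is lost, and
#' [profile_frequencies()] exports normalised values.
#'
#' @param records contig records: a data.frame with columns `id` and
#'   `sequence` (as returned by [read_fasta()]).
#' @param k k-mer length, integer in \[1, 26\].
#' @param sample_id sample label stored in the profile.
#' @return a `kmer_profile`.
#' @export
profile_sample <- function(records, k, sample_id = "") {
  k <- check_k(k)
  if (is.null(records) || nrow(records) == 0) {
    return(new_kmer_profile(k, numeric(0), numeric(0), 0, sample_id))
  }
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  cl <- clean_sequence(records$sequence)
  res <- count_kmers_cpp(cl$seq, k)
  new_kmer_profile(k, res$codes, res$counts, res$total, sample_id)
}

#' Export a profile as a k-mer/count table
#'
#' @param p a `kmer_profile`.
#' @return data.frame with columns `kmer` (canonical k-mer string), `count`,
#'   and `frequency` (= count / total).
#' @export
profile_frequencies <- function(p) {
  stopifnot(inherits(p, "kmer_profile"))
  data.frame(
    kmer = decode_kmer(p$codes, p$k),
    count = p$counts,
    frequency = if (p$total > 0) p$counts / p$total else numeric(length(p$counts))
  )
}

#' Write / read a profile as 2-column TSV
#'
#' Text interchange format: canonical k-mer string and count, tab-separated,
#' sorted by code, with a `#` header line carrying k, total and sample id.
#'
#' @param p a `kmer_profile`.
#' @param path file path.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns a `kmer_profile`.
#' @export
write_profile_tsv <- function(p, path) {
  stopifnot(inherits(p, "kmer_profile"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("#kmercosine profile\tk=%d\ttotal=%.0f\tsample=%s",
                     p$k, p$total, p$sample_id), con, sep = "\n")
  if (length(p$codes) > 0) {
    writeLines(sprintf("%s\t%.0f", decode_kmer(p$codes, p$k), p$counts),
               con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#kmercosine profile")) {
    kfc_error("not a kmercosine profile TSV", "kfc_malformed_file")
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  k <- as.integer(sub("^k=", "", hdr[2]))
  sample_id <- sub("^sample=", "", hdr[4])
  body <- lines[-1]
  if (length(body) == 0) {
    return(new_kmer_profile(k, numeric(0), numeric(0), 0, sample_id))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  kmers <- vapply(parts, `[`, character(1), 1)
  counts <- as.numeric(vapply(parts, `[`, character(1), 2))
  codes <- encode_kmer(kmers, k)
  ord <- order(codes)
  new_kmer_profile(k, codes[ord], counts[ord], sum(counts), sample_id)
}

PROFILE_CACHE_MAGIC <- "KFCPROF1"

#' Binary profile cache
#'
#' Compact cache for reuse across runs (e.g. a k sweep): magic bytes, k,
#' number of entries, total, sample id, then sorted code/count pairs as
#' doubles. Not an interchange format; see [write_profile_tsv()] for text.
#'
#' @param p a `kmer_profile`.
#' @param path file path.
#' @return `write_profile_cache` returns `path` invisibly;
#'   `read_profile_cache` returns a `kmer_profile`.
#' @export
write_profile_cache <- function(p, path) {
  stopifnot(inherits(p, "kmer_profile"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(PROFILE_CACHE_MAGIC), con)
  writeBin(c(p$k, length(p$codes)), con, size = 4)
  writeBin(p$total, con, size = 8)
  id_raw <- charToRaw(p$sample_id)
  writeBin(length(id_raw), con, size = 4)
  writeBin(id_raw, con)
  writeBin(p$codes, con, size = 8)
  writeBin(p$counts, con, size = 8)
  invisible(path)
}

#' @rdname write_profile_cache
#' @export
read_profile_cache <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(PROFILE_CACHE_MAGIC)))
  if (!identical(magic, PROFILE_CACHE_MAGIC)) {
    kfc_error("not a kmercosine profile cache", "kfc_malformed_file")
  }
  hdr <- readBin(con, "integer", 2, size = 4)
  total <- readBin(con, "double", 1, size = 8)
  id_len <- readBin(con, "integer", 1, size = 4)
  sample_id <- if (id_len > 0) rawToChar(readBin(con, "raw", id_len)) else ""
  codes <- readBin(con, "double", hdr[2], size = 8)
  counts <- readBin(con, "double", hdr[2], size = 8)
  new_kmer_profile(hdr[1], codes, counts, total, sample_id)
}
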