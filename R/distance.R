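#' Cosine distance between two k-mer profiles
#'
#' `1 - dot(p, q) / (||p|| * ||q||)` over the full sparse count vectors,
#' summing the dot product over the shared canonical codes. The value is
#' clamped to \[0, 1\] against floating-point drift. Cosine distance is
#' invariant to positive scaling of either vector, so raw counts and
#' normalised frequencies give identical results.
#'
#' @param p,q `kmer_profile` objects with equal `k` and positive totals.
#' @return a single number in \[0, 1\].
#' @examples
#' p <- kmer_profile(c(ACG = 4, GTA = 2))
#' q <- kmer_profile(c(ACG = 2, GTA = 4))
#' cosine_distance(p, q) # 1 - 16/20 = 0.2
#' @export
cosine_distance <- function(p, q) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  if (p$k != q$k) {
    kfc_error(sprintf("profiles have different k (%d vs %d)", p$k, q$k),
              "kfc_k_mismatch")
  }
  if (p$total <= 0 || q$total <= 0) {
    kfc_error("cannot compute cosine distance of an empty profile",
              "kfc_empty_profile")
  }
  # parallel count vectors (same support, proportional counts) are at
  # distance exactly 0; catching this exactly matters for the self- and
  # strand-flip cases, where rounding in the general formula would leave
  # an O(1e-16) residue
  if (length(p$codes) == length(q$codes) &&
      all(p$codes == q$codes) &&
      isTRUE(all(p$counts * q$counts[1] == q$counts * p$counts[1]))) {
    return(0)
  }
  dot <- sparse_dot_cpp(p$codes, p$counts, q$codes, q$counts)
  d <- 1 - dot / sqrt(sum(p$counts^2) * sum(q$counts^2))
  min(max(d, 0), 1)
}

#' Pairwise cosine distance matrix
#'
#' Computes the upper triangle of all pairwise [cosine_distance()] values and
#' mirrors it: the result is a symmetric labelled matrix with zero diagonal,
#' the hub object every downstream analysis consumes.
#'
#' @param profiles list of `kmer_profile` objects with equal `k` and unique,
#'   non-empty `sample_id`s.
#' @return n x n numeric matrix with sample ids as dimnames.
#' @export
pairwise_distance_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  labels <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(labels) || any(labels == "")) {
    kfc_error("profiles must carry unique, non-empty sample_ids",
              "kfc_duplicate_label")
  }
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- cosine_distance(profiles[[i]], profiles[[j]])
    }
  }
  D
}

# Check DistanceMatrix invariants; returns the matrix invisibly.
validate_distance_matrix <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 2 ||
      is.null(rownames(D)) || !identical(rownames(D), colnames(D)) ||
      anyDuplicated(rownames(D))) {
    kfc_error("distance matrix must be square with matching unique labels",
              "kfc_invalid_matrix")
  }
  if (anyNA(D) || any(!is.finite(D))) {
    kfc_error("distance matrix contains NA or non-finite values",
              "kfc_invalid_matrix")
  }
  if (max(abs(D - t(D))) > tol) {
    kfc_error("distance matrix is not symmetric", "kfc_invalid_matrix")
  }
  if (max(abs(diag(D))) > tol) {
    kfc_error("distance matrix has a non-zero diagonal", "kfc_invalid_matrix")
  }
  invisible(D)
}
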