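#' Read assembled contigs from a FASTA file
#'
#' Reads plain or gzip-compressed FASTA (via [Biostrings::readDNAStringSet()];
#' compression is detected from the file content, not the extension). The
#' header token up to the first whitespace becomes the contig id, multi-line
#' sequences are concatenated, and sequences are folded to uppercase. IUPAC
#' ambiguity codes other than A/C/G/T are mapped to N and the number of
#' substitutions is reported with a message.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    kfc_error(paste("file not found:", path), "kfc_io_error")
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) kfc_error(paste("malformed FASTA:", conditionMessage(e)),
                                  "kfc_malformed_fasta")
  )
  if (length(set) == 0) {
    kfc_error("FASTA file contains no records", "kfc_malformed_fasta")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    kfc_error(paste("duplicate contig ids:",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "kfc_duplicate_id")
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    kfc_error("FASTA contains empty sequences", "kfc_malformed_fasta")
  }
  cl <- clean_sequence(seqs)
  if (cl$n_substituted > 0) {
    message(sprintf("%s: %d ambiguous base(s) mapped to N",
                    basename(path), cl$n_substituted))
  }
  data.frame(id = ids, sequence = unname(cl$seq))
}

#' Write a distance matrix to file
#'
#' Two dialects: relaxed PHYLIP square (first line: n; one whitespace-
#' delimited row per sample, label first; labels may not contain whitespace)
#' and labelled TSV (header row and first column carry the labels). Values
#' are rendered with a fixed number of decimals and `\n` line endings, so
#' identical matrices always produce byte-identical files.
#'
#' @param D symmetric labelled distance matrix.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"phylip"`.
#' @param precision decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip"),
                                  precision = 6) {
  format <- match.arg(format)
  validate_distance_matrix(D)
  labels <- rownames(D)
  fmt <- paste0("%.", precision, "f")
  con <- file(path, "wb")
  on.exit(close(con))
  rows <- apply(D, 1, function(v) paste(sprintf(fmt, v), collapse = "\t"))
  if (format == "phylip") {
    if (any(grepl("\\s", labels)) || any(nchar(labels) > 64)) {
      kfc_error("PHYLIP labels may not contain whitespace or exceed 64 characters",
                "kfc_invalid_label")
    }
    writeLines(as.character(nrow(D)), con, sep = "\n")
    rows <- apply(D, 1, function(v) paste(sprintf(fmt, v), collapse = " "))
    writeLines(paste(labels, rows), con, sep = "\n")
  } else {
    writeLines(paste(c("", labels), collapse = "\t"), con, sep = "\n")
    writeLines(paste(labels, rows, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a distance matrix from file
#'
#' Accepts the two dialects written by [write_distance_matrix()];
#' `format = "auto"` (default) recognises PHYLIP by a single integer on the
#' first line. The matrix is validated -- NA entries, a diagonal off zero by
#' more than `tol`, or asymmetry beyond `tol` are errors -- then exactly
#' symmetrised by averaging. Entries slightly outside \[0, 1\] (within 1e-6,
#' as from rounding) are clamped with a warning.
#'
#' @param path input file path.
#' @param format `"auto"`, `"tsv"`, or `"phylip"`.
#' @param tol symmetry / diagonal tolerance (default 1e-9).
#' @return symmetric labelled distance matrix.
#' @export
read_distance_matrix <- function(path, format = c("auto", "tsv", "phylip"),
                                 tol = 1e-9) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    kfc_error(paste("file not found:", path), "kfc_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) kfc_error("empty distance matrix file", "kfc_invalid_matrix")
  if (format == "auto") {
    format <- if (grepl("^\\s*[0-9]+\\s*$", lines[1])) "phylip" else "tsv"
  }
  if (format == "phylip") {
    n <- as.integer(trimws(lines[1]))
    body <- lines[-1]
    if (length(body) != n) kfc_error("PHYLIP row count mismatch", "kfc_invalid_matrix")
    parts <- strsplit(trimws(body), "\\s+")
    labels <- vapply(parts, `[`, character(1), 1)
    vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  } else {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    labels_h <- header[-1]
    body <- lines[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    labels <- vapply(parts, `[`, character(1), 1)
    if (!identical(labels, labels_h)) {
      kfc_error("TSV row labels do not match header labels", "kfc_invalid_matrix")
    }
    vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  }
  n <- length(labels)
  if (any(lengths(vals) != n)) {
    kfc_error("ragged distance matrix", "kfc_invalid_matrix")
  }
  D <- do.call(rbind, vals)
  dimnames(D) <- list(labels, labels)
  if (anyNA(D)) kfc_error("distance matrix contains NaN/NA", "kfc_invalid_matrix")
  if (max(abs(diag(D))) > tol) {
    kfc_error("distance matrix has a non-zero diagonal", "kfc_invalid_matrix")
  }
  if (max(abs(D - t(D))) > tol) {
    kfc_error("distance matrix asymmetric beyond tolerance", "kfc_invalid_matrix")
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  clampable <- (D > 1 & D <= 1 + 1e-6) | (D < 0 & D >= -1e-6)
  if (any(clampable)) {
    kfc_warning(sprintf("%d entries slightly outside [0, 1] clamped",
                        sum(clampable)), "kfc_clamped_values")
    D[D > 1 & clampable] <- 1
    D[D < 0 & clampable] <- 0
  }
  validate_distance_matrix(D, tol = tol)
  D
}

#' Read / write a sample-to-group map
#'
#' Two-column TSV (`sample_id`, `group`); a header line is detected (first
#' field equal to `sample`, `sample_id` or `#sample`) and skipped.
#'
#' @param path file path.
#' @return `read_group_map` returns a named character vector (names are
#'   sample ids); `write_group_map` returns `path` invisibly.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) {
    kfc_error(paste("file not found:", path), "kfc_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    kfc_error("group map must have 2 tab-separated columns", "kfc_malformed_file")
  }
  if (tolower(sub("^#", "", parts[[1]][1])) %in% c("sample", "sample_id")) {
    parts <- parts[-1]
  }
  ids <- vapply(parts, `[`, character(1), 1)
  grp <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(ids)) {
    kfc_error("duplicate sample ids in group map", "kfc_duplicate_id")
  }
  stats::setNames(grp, ids)
}

#' @rdname read_group_map
#' @param groups named character vector (sample id -> group).
#' @export
write_group_map <- function(groups, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("sample_id\tgroup", con, sep = "\n")
  writeLines(paste(names(groups), groups, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read / write a sample manifest
#'
#' Two-column TSV (`sample_id`, FASTA path); relative paths are resolved
#' against the manifest's directory. Every referenced file must exist.
#'
#' @param path manifest file path.
#' @return `read_manifest` returns a data.frame with columns `sample_id`
#'   and `path`; `write_manifest` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    kfc_error(paste("file not found:", path), "kfc_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    kfc_error("manifest must have 2 tab-separated columns", "kfc_malformed_file")
  }
  if (tolower(sub("^#", "", parts[[1]][1])) %in% c("sample", "sample_id")) {
    parts <- parts[-1]
  }
  ids <- vapply(parts, `[`, character(1), 1)
  paths <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(ids)) {
    kfc_error("duplicate sample ids in manifest", "kfc_duplicate_id")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(normalizePath(path)), paths[rel])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    kfc_error(paste("manifest references missing files:",
                    paste(missing, collapse = ", ")), "kfc_io_error")
  }
  data.frame(sample_id = ids, path = paths)
}

#' @rdname read_manifest
#' @param manifest data.frame with columns `sample_id` and `path`.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("sample_id\tpath", con, sep = "\n")
  writeLines(paste(manifest$sample_id, manifest$path, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Profile every sample in a manifest
#'
#' Reads each FASTA and counts canonical k-mers. With `cache_dir` set,
#' profiles are cached in the binary format keyed by (file md5, k), so a
#' k sweep re-reads each FASTA only once per k.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param k k-mer length.
#' @param cache_dir optional directory for binary profile caches.
#' @return list of `kmer_profile` objects, one per manifest row.
#' @export
profiles_from_manifest <- function(manifest, k, cache_dir = NULL) {
  k <- check_k(k)
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$path[i]
    id <- manifest$sample_id[i]
    cache <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      cache <- file.path(cache_dir,
                         sprintf("%s_k%d.kfc", tools::md5sum(f), k))
      if (file.exists(cache)) {
        p <- read_profile_cache(cache)
        p$sample_id <- id
        return(p)
      }
    }
    p <- profile_sample(read_fasta(f), k, sample_id = id)
    if (!is.null(cache)) write_profile_cache(p, cache)
    p
  })
}
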