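#' Configuration for the grouped-contig simulator
#'
#' Describes a synthetic study: `n_sources` random source genomes (uniform
#' ACGT), groups of samples that draw contigs from the sources according to
#' per-group mixture weights, and a substitution-only mutation model. The
#' defaults emulate the structure the downstream analyses assume -- two
#' groups of samples from distinct source material with small divergence:
#' 2 sources of 200 kb, 2 groups of 5 samples with disjoint single-source
#' mixtures, 50 contigs of 1-5 kb per sample, substitution rate 0.01.
#'
#' @param seed integer seed; all randomness derives from it, and per-sample
#'   substreams are derived from (seed, sample index) so adding a sample
#'   never perturbs earlier ones.
#' @param n_sources number of source genomes (>= 0).
#' @param source_length length of each source in bases.
#' @param groups list of groups, each a list with `label`, `n_samples`, and
#'   `weights` (mixture over sources: non-negative, summing to 1).
#' @param contigs_per_sample contigs drawn per sample.
#' @param contig_length length-2 vector (min, max) of contig lengths;
#'   max must not exceed `source_length`.
#' @param mutation_rate per-base substitution probability in \[0, 0.5).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_sources = 2,
                              source_length = 200000,
                              groups = NULL,
                              contigs_per_sample = 50,
                              contig_length = c(1000, 5000),
                              mutation_rate = 0.01) {
  if (is.null(groups)) {
    # disjoint single-source mixtures, cycling over sources
    groups <- lapply(1:2, function(g) {
      w <- rep(0, n_sources)
      w[(g - 1) %% n_sources + 1] <- 1
      list(label = paste0("group", LETTERS[g]), n_samples = 5, weights = w)
    })
  }
  stopifnot(length(seed) == 1, seed == as.integer(seed),
            n_sources >= 0, source_length >= 1,
            contigs_per_sample >= 1,
            length(contig_length) == 2,
            contig_length[1] >= 1, contig_length[1] <= contig_length[2],
            contig_length[2] <= source_length,
            mutation_rate >= 0, mutation_rate < 0.5,
            length(groups) >= 1)
  for (g in groups) {
    stopifnot(is.character(g$label), g$n_samples >= 1,
              length(g$weights) == n_sources, all(g$weights >= 0))
    if (n_sources > 0) stopifnot(abs(sum(g$weights) - 1) < 1e-9)
  }
  structure(list(seed = as.integer(seed), n_sources = as.integer(n_sources),
                 source_length = as.integer(source_length), groups = groups,
                 contigs_per_sample = as.integer(contigs_per_sample),
                 contig_length = as.integer(contig_length),
                 mutation_rate = mutation_rate),
            class = "sim_config")
}

# Deterministic substream seed for (seed, index); stays below 2^31.
sub_seed <- function(seed, idx) {
  as.integer(((seed %% 104729) * 1103515245 + idx * 999331 + 7) %% 2147483647)
}

random_dna <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

#' Simulate source genomes
#'
#' Independent uniform-ACGT sequences of `source_length` bases, drawn from
#' the seeded generator; the same config always yields identical sources.
#'
#' @param config a `sim_config`.
#' @return character vector of `n_sources` DNA strings.
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sources == 0) return(character(0))
  set.seed(sub_seed(config$seed, 0))
  vapply(seq_len(config$n_sources), function(i) random_dna(config$source_length),
         character(1))
}

#' Mutate a sequence by independent substitutions
#'
#' Each base is substituted, independently with probability `rate`, by one
#' of the other three bases (uniformly). Length is preserved; no indels.
#' Uses the current RNG state.
#'
#' @param seq a DNA string over ACGT.
#' @param rate substitution probability in \[0, 0.5).
#' @return mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 0.5)
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    idx <- match(chars[hit], BASES)
    offset <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- BASES[(idx - 1 + offset) %% 4 + 1]
  }
  paste(chars, collapse = "")
}

write_fasta <- function(ids, seqs, path, width = 80) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con, sep = "\n")
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Simulate a grouped contig dataset
#'
#' For every sample: draw `contigs_per_sample` contigs by (1) picking a
#' source genome by the sample's group mixture weights, (2) excising a
#' uniform-random substring with length uniform in `contig_length`,
#' (3) applying [mutate_sequence()], and (4) reverse-complementing with
#' probability 1/2 (random assembly strand). One FASTA file is written per
#' sample, plus `manifest.tsv` and `groups.tsv`. Output is byte-identical
#' across runs with the same config.
#'
#' @param config a `sim_config`.
#' @param out_dir writable output directory (created if needed).
#' @return list with `manifest` (data.frame: `sample_id`, `path`), `groups`
#'   (named character vector), and the file paths `manifest_path`,
#'   `groups_path`.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sources <- simulate_sources(config)
  stopifnot(length(sources) >= 1)
  lens <- config$contig_length
  sample_idx <- 0
  ids <- character(0)
  paths <- character(0)
  grp <- character(0)
  for (g in config$groups) {
    for (s in seq_len(g$n_samples)) {
      sample_idx <- sample_idx + 1
      set.seed(sub_seed(config$seed, sample_idx))
      id <- sprintf("%s_s%02d", gsub("\\s+", "_", g$label), s)
      src <- sample.int(config$n_sources, config$contigs_per_sample,
                        replace = TRUE, prob = g$weights)
      contigs <- vapply(seq_len(config$contigs_per_sample), function(ci) {
        len <- if (lens[1] == lens[2]) lens[1] else
          sample(seq(lens[1], lens[2]), 1)
        start <- sample.int(config$source_length - len + 1, 1)
        ctg <- substr(sources[src[ci]], start, start + len - 1)
        ctg <- mutate_sequence(ctg, config$mutation_rate)
        if (runif(1) < 0.5) ctg <- reverse_complement(ctg)
        ctg
      }, character(1))
      fp <- file.path(out_dir, paste0(id, ".fasta"))
      write_fasta(sprintf("%s_contig%03d", id,
                          seq_len(config$contigs_per_sample)), contigs, fp)
      ids <- c(ids, id)
      paths <- c(paths, fp)
      grp <- c(grp, g$label)
    }
  }
  manifest <- data.frame(sample_id = ids, path = paths)
  groups <- stats::setNames(grp, ids)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  groups_path <- file.path(out_dir, "groups.tsv")
  write_manifest(manifest, manifest_path)
  write_group_map(groups, groups_path)
  list(manifest = manifest, groups = groups,
       manifest_path = manifest_path, groups_path = groups_path)
}
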