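#' Principal coordinates analysis (classical metric MDS)
#'
#' Embeds samples in a low-dimensional Euclidean space that preserves the
#' input distances as well as possible: Gower double-centering
#' `B = -1/2 J D^2 J` followed by a symmetric eigendecomposition (via
#' [stats::cmdscale()]); coordinates are eigenvectors scaled by the square
#' roots of their eigenvalues. For Euclidean-embeddable input the full-rank
#' coordinates reproduce the distances exactly.
#'
#' Cosine distance is not guaranteed Euclidean, so negative eigenvalues can
#' occur; they are excluded from the coordinates and from the
#' proportion-explained denominator (which is the sum of positive
#' eigenvalues), and their magnitudes are reported in
#' `negative_eigenvalues`. Axis signs are fixed by forcing the coordinate of
#' largest absolute value on each axis to be positive, so plots are
#' reproducible across platforms.
#'
#' @param D symmetric labelled distance matrix, n >= 3.
#' @param n_axes maximum number of axes to retain (default `n - 1`; fewer
#'   are returned when fewer eigenvalues are positive).
#' @return an object of class `kfc_pcoa`: list with `labels`, `coordinates`
#'   (n x m matrix, zero-mean columns), `eigenvalues` (positive, descending),
#'   `proportion_explained`, and `negative_eigenvalues` (magnitudes).
#' @export
pcoa <- function(D, n_axes = nrow(D) - 1) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) kfc_error("PCoA needs at least 3 samples", "kfc_too_few_samples")
  stopifnot(n_axes >= 1, n_axes <= n - 1)
  fit <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  m <- min(length(pos), n_axes, ncol(fit$points))
  coords <- fit$points[, seq_len(m), drop = FALSE]
  # reproducible axis orientation
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(labels = rownames(D),
         coordinates = coords,
         eigenvalues = eig[seq_len(m)],
         proportion_explained = eig[seq_len(m)] / sum(eig[pos]),
         negative_eigenvalues = abs(eig[eig < 0])),
    class = "kfc_pcoa"
  )
}

#' @export
print.kfc_pcoa <- function(x, ...) {
  cat(sprintf("PCoA of %d samples, %d retained axes\n",
              length(x$labels), ncol(x$coordinates)))
  pe <- paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", ")
  cat("  variance explained:", pe, "\n")
  if (length(x$negative_eigenvalues) > 0) {
    cat(sprintf("  %d negative eigenvalues (max magnitude %.3g) excluded\n",
                length(x$negative_eigenvalues),
                max(x$negative_eigenvalues)))
  }
  invisible(x)
}

#' Write PCoA coordinates and eigenvalues as TSV
#'
#' One row per sample: label, then coordinates; eigenvalues and proportions
#' explained are appended as `#`-prefixed trailer lines.
#'
#' @param res a `kfc_pcoa` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pcoa_tsv <- function(res, path) {
  stopifnot(inherits(res, "kfc_pcoa"))
  con <- file(path, "wb")
  on.exit(close(con))
  axes <- colnames(res$coordinates)
  writeLines(paste(c("sample", axes), collapse = "\t"), con, sep = "\n")
  for (i in seq_along(res$labels)) {
    writeLines(paste(c(res$labels[i],
                       sprintf("%.6f", res$coordinates[i, ])),
                     collapse = "\t"), con, sep = "\n")
  }
  writeLines(paste(c("#eigenvalue",
                     sprintf("%.6g", res$eigenvalues)), collapse = "\t"),
             con, sep = "\n")
  writeLines(paste(c("#proportion_explained",
                     sprintf("%.6f", res$proportion_explained)),
                   collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Scatter plot of the first two PCoA axes
#'
#' Base-graphics helper: one point per sample, axes annotated with the
#' percentage of variance explained, optionally coloured by group.
#'
#' @param res a `kfc_pcoa` object with at least 2 axes.
#' @param groups optional named character vector mapping sample id to group.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot_pcoa <- function(res, groups = NULL, ...) {
  stopifnot(inherits(res, "kfc_pcoa"), ncol(res$coordinates) >= 2)
  xy <- res$coordinates[, 1:2]
  pe <- 100 * res$proportion_explained[1:2]
  col <- 1
  if (!is.null(groups)) {
    g <- factor(groups[res$labels])
    col <- as.integer(g)
  }
  graphics::plot(xy, col = col, pch = 19,
                 xlab = sprintf("PCo1 (%.1f%%)", pe[1]),
                 ylab = sprintf("PCo2 (%.1f%%)", pe[2]), ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(g),
                     col = seq_along(levels(g)), pch = 19, bty = "n")
  }
  invisible(xy)
}
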