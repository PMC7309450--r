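#' Select within- or between-group distances
#'
#' Pulls the distance values that feed the group comparisons out of a
#' distance matrix: within-mode returns `d(i, j)` for all unordered pairs
#' `i < j` inside group `g1`; between-mode returns `d(i, j)` for all pairs
#' with `i` in `g1` and `j` in `g2`. Diagonal entries are never included.
#'
#' @param D symmetric labelled distance matrix.
#' @param groups named character vector mapping every matrix label to a
#'   group (see [read_group_map()]).
#' @param mode `"within"` or `"between"`.
#' @param g1 group label.
#' @param g2 second group label (between-mode only).
#' @return numeric vector of distances (possibly empty, with a warning, for
#'   a within-mode group of size < 2).
#' @export
select_distances <- function(D, groups, mode = c("within", "between"),
                             g1, g2 = NULL) {
  mode <- match.arg(mode)
  validate_distance_matrix(D)
  labels <- rownames(D)
  missing <- setdiff(labels, names(groups))
  if (length(missing) > 0) {
    kfc_error(paste("samples missing from group map:",
                    paste(missing, collapse = ", ")), "kfc_missing_group")
  }
  grp <- groups[labels]
  check_group <- function(g) {
    if (!g %in% grp) kfc_error(paste("unknown group:", g), "kfc_missing_group")
  }
  check_group(g1)
  if (mode == "within") {
    members <- which(grp == g1)
    if (length(members) < 2) {
      kfc_warning(sprintf("group '%s' has fewer than 2 samples; no within-group pairs", g1),
                  "kfc_empty_selection")
      return(numeric(0))
    }
    pairs <- combn(members, 2)
    return(D[cbind(pairs[1, ], pairs[2, ])])
  }
  stopifnot(!is.null(g2))
  check_group(g2)
  i <- which(grp == g1)
  j <- which(grp == g2)
  as.vector(D[i, j, drop = FALSE])
}

#' Two-sample rank-sum (Mann-Whitney U) test
#'
#' Two-sided Mann-Whitney U test on pooled midranks. The p-value is exact
#' (from the null permutation distribution of U) when `n1 + n2 <= 12` and
#' the pooled data contain no ties; otherwise the normal approximation with
#' tie correction and continuity correction is used. `U` is the statistic
#' for `x`: the number of (x, y) pairs with x > y (ties counted 1/2).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return object of class `kfc_ranksum`: list with `U`, `z`,
#'   `p_two_sided`, `n1`, `n2`, `method` ("exact" or
#'   "normal-approximation").
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(c(x, y))) kfc_error("NA values in input", "kfc_degenerate_data")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    kfc_error("all values identical across both samples; rank-sum p undefined",
              "kfc_degenerate_data")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    kfc_error("zero variance in rank distribution", "kfc_degenerate_data")
  }
  cc <- if (U == mu) 0 else sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(sigma2)

  if (N <= 12 && !has_ties) {
    p_lo <- pwilcox(U, n1, n2)
    p_hi <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(U = U, z = z, p_two_sided = p, n1 = n1, n2 = n2,
                 method = method),
            class = "kfc_ranksum")
}

#' @export
print.kfc_ranksum <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %g, z = %.3f, n = (%d, %d)\n",
              x$method, x$U, x$z, x$n1, x$n2))
  cat(sprintf("  two-sided p = %.4g %s\n", x$p_two_sided,
              significance_stars(x$p_two_sided)))
  invisible(x)
}

#' Omnibus normality test (skewness + kurtosis)
#'
#' D'Agostino-Pearson omnibus test: the sample skewness and kurtosis are
#' each transformed to an approximate standard normal deviate
#' (D'Agostino 1970; Anscombe & Glynn 1983) and
#' `K^2 = Z_skew^2 + Z_kurt^2` is referred to a chi-squared distribution
#' with 2 degrees of freedom. Small p-values reject normality; the group
#' comparisons here fall back to rank-sum tests when distances fail this
#' test.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K^2) and `p_value`.
#' @export
normality_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) {
    kfc_error("normality test needs at least 8 observations",
              "kfc_insufficient_data")
  }
  if (var(x) == 0) {
    kfc_error("zero variance; normality test undefined", "kfc_degenerate_data")
  }
  m <- function(p) mean((x - mean(x))^p)
  # skewness deviate (D'Agostino)
  g1 <- m(3) / m(2)^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis deviate (Anscombe-Glynn)
  b2 <- m(4) / m(2)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xs * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * A)) - term2) / sqrt(2 / (9 * A))

  K2 <- z_skew^2 + z_kurt^2
  list(statistic = K2, p_value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Mean and standard error of a set of distances
#'
#' @param values numeric vector, non-empty.
#' @param label description of the set (e.g. `"leaf vs shoot"`).
#' @return one-row data.frame with `label`, `mean`, `sem` (= sd / sqrt(n),
#'   with the n-1 denominator sd; 0 when n = 1), and `n`.
#' @export
group_summary <- function(values, label = "") {
  if (length(values) == 0) {
    kfc_error("cannot summarise an empty selection", "kfc_empty_selection")
  }
  n <- length(values)
  data.frame(label = label, mean = mean(values),
             sem = if (n == 1) 0 else sd(values) / sqrt(n), n = n)
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Rank-sum comparison of distance sets for all group pairs
#'
#' For every unordered pair of groups, compares distance distributions with
#' [rank_sum_test()] and summarises each side as mean +/- SEM. Two feeds are
#' available: `"between-vs-within"` (default) tests the between-group
#' distances of the pair against the pooled within-group distances of its
#' two groups; `"between-vs-between"` tests the between-group distance sets
#' of every pair of group pairs against each other. Pairwise distances share
#' samples and are therefore not independent; p-values are reported without
#' correction for that dependence, as is conventional for this style of
#' analysis, and should be read as descriptive. No multiple-testing
#' adjustment is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param D symmetric labelled distance matrix.
#' @param groups named character vector mapping sample id to group.
#' @param mode `"between-vs-within"` or `"between-vs-between"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per comparison: `set1`, `set2`, `n1`,
#'   `n2`, `mean1`, `sem1`, `mean2`, `sem2`, `U`, `z`, `p`, `stars`,
#'   `method`.
#' @export
compare_groups <- function(D, groups,
                           mode = c("between-vs-within", "between-vs-between"),
                           adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  validate_distance_matrix(D)
  glev <- sort(unique(groups[rownames(D)]))
  if (length(glev) < 2) {
    kfc_error("need at least 2 groups to compare", "kfc_missing_group")
  }
  sets <- list()   # named list of distance vectors to compare pairwise
  if (mode == "between-vs-within") {
    rows <- list()
    pairs <- combn(glev, 2)
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      between <- select_distances(D, groups, "between", g1, g2)
      within <- suppressWarnings(c(
        select_distances(D, groups, "within", g1),
        select_distances(D, groups, "within", g2)))
      rows[[p]] <- build_comparison_row(
        between, within,
        sprintf("between %s|%s", g1, g2),
        sprintf("within %s+%s", g1, g2))
    }
    out <- do.call(rbind, rows)
  } else {
    pairs <- combn(glev, 2)
    labs <- apply(pairs, 2, paste, collapse = "|")
    for (p in seq_len(ncol(pairs))) {
      sets[[labs[p]]] <- select_distances(D, groups, "between",
                                          pairs[1, p], pairs[2, p])
    }
    if (length(sets) < 2) {
      kfc_error("between-vs-between mode needs at least 3 groups",
                "kfc_missing_group")
    }
    pp <- combn(length(sets), 2)
    rows <- lapply(seq_len(ncol(pp)), function(q) {
      i <- pp[1, q]; j <- pp[2, q]
      build_comparison_row(sets[[i]], sets[[j]],
                           paste("between", names(sets)[i]),
                           paste("between", names(sets)[j]))
    })
    out <- do.call(rbind, rows)
  }
  if (adjust == "BH") {
    out$p <- p.adjust(out$p, method = "BH")
    out$stars <- significance_stars(out$p)
  }
  rownames(out) <- NULL
  out
}

build_comparison_row <- function(v1, v2, lab1, lab2) {
  rs <- rank_sum_test(v1, v2)
  s1 <- group_summary(v1, lab1)
  s2 <- group_summary(v2, lab2)
  data.frame(set1 = lab1, set2 = lab2, n1 = rs$n1, n2 = rs$n2,
             mean1 = s1$mean, sem1 = s1$sem, mean2 = s2$mean, sem2 = s2$sem,
             U = rs$U, z = rs$z, p = rs$p_two_sided,
             stars = significance_stars(rs$p_two_sided), method = rs$method)
}

#' Write a group-comparison table as TSV
#'
#' @param tab data.frame from [compare_groups()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(tab, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.6g", v))
  writeLines(paste(names(tab), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(tab, sep = "\t")), con, sep = "\n")
  invisible(path)
}
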