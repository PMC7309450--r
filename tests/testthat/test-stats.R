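grouped_fixture <- function(sizes, seed = 3) {
  set.seed(seed)
  n <- sum(sizes)
  labs <- sprintf("s%02d", seq_len(n))
  D <- matrix(runif(n * n, 0.1, 0.9), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  groups <- stats::setNames(rep(names(sizes), sizes), labs)
  list(D = D, groups = groups)
}

test_that("select_distances returns the right pair sets", {
  fix <- grouped_fixture(c(A = 2, B = 2))
  wA <- select_distances(fix$D, fix$groups, "within", "A")
  expect_equal(wA, fix$D["s01", "s02"])
  btw <- select_distances(fix$D, fix$groups, "between", "A", "B")
  expect_length(btw, 4)
  expect_setequal(btw, as.vector(fix$D[1:2, 3:4]))

  # leaf-stage (11) vs shoot-stage (10) sized groups
  fix2 <- grouped_fixture(c(leaf = 11, shoot = 10))
  expect_length(select_distances(fix2$D, fix2$groups, "between", "leaf", "shoot"),
                110)
  expect_length(select_distances(fix2$D, fix2$groups, "within", "leaf"), 55)
  expect_length(select_distances(fix2$D, fix2$groups, "within", "shoot"), 45)

  expect_error(select_distances(fix$D, fix$groups, "within", "nope"),
               class = "kfc_missing_group")
  fix1 <- grouped_fixture(c(A = 1, B = 3))
  expect_warning(v <- select_distances(fix1$D, fix1$groups, "within", "A"),
                 class = "kfc_empty_selection")
  expect_length(v, 0)
})

test_that("rank-sum test matches full enumeration when exact", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$U, 0)
  expect_equal(rs$p_two_sided, 2 / 6)
  expect_equal(rs$method, "exact")

  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = rep %% 3 - 1)
    rs <- rank_sum_test(x, y)
    expect_equal(rs$method, "exact")
    expect_equal(rs$p_two_sided, enumerate_ranksum_p(x, y),
                 info = paste("replicate", rep))
  }
})

test_that("rank-sum test is symmetric and rank-based", {
  set.seed(41)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  a <- rank_sum_test(x, y)
  b <- rank_sum_test(y, x)
  expect_equal(a$p_two_sided, b$p_two_sided)
  expect_equal(b$U, a$n1 * a$n2 - a$U)
  # invariance under strictly monotone transform of the pooled data
  mono <- rank_sum_test(exp(x), exp(y))
  expect_equal(mono$U, a$U)
  expect_equal(mono$p_two_sided, a$p_two_sided)
  expect_gte(a$U, 0)
  expect_lte(a$U, a$n1 * a$n2)
})

test_that("normal approximation tracks the exact p for small samples", {
  set.seed(51)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.8)
    exact <- rank_sum_test(x, y)
    expect_equal(exact$method, "exact")
    approx_p <- min(1, 2 * pnorm(-abs(exact$z)))
    expect_lt(abs(exact$p_two_sided - approx_p), 0.02)
  }
})

test_that("ties route to the tie-corrected normal approximation", {
  rs <- rank_sum_test(c(1, 2, 2), c(2, 3, 4))
  expect_equal(rs$method, "normal-approximation")
  expect_gte(rs$p_two_sided, 0)
  expect_lte(rs$p_two_sided, 1)
  # identical pooled samples: centred U, p = 1
  rs2 <- rank_sum_test(c(1, 2, 5), c(1, 2, 5))
  expect_equal(rs2$U, rs2$n1 * rs2$n2 / 2)
  expect_equal(rs2$p_two_sided, 1)
  expect_error(rank_sum_test(c(1, 1), c(1, 1)), class = "kfc_degenerate_data")
})

test_that("omnibus normality test matches the reference implementation", {
  # frozen reference values (scipy.stats.normaltest)
  x1 <- c(0.12, 0.25, 0.31, 0.47, 0.52, 0.58, 0.61, 0.66, 0.74, 0.79,
          0.85, 0.92, 1.05, 1.21, 1.38, 1.77, 2.3, 3.1, 4.2, 6.9)
  r1 <- normality_test(x1)
  expect_equal(r1$statistic, 23.9777653989791, tolerance = 1e-10)
  expect_equal(r1$p_value, 6.212900514470264e-06, tolerance = 1e-9)

  x2 <- (1:15) / 8
  r2 <- normality_test(x2)
  expect_equal(r2$statistic, 2.9384896815241635, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.2300991811166841, tolerance = 1e-9)

  # heavily bimodal sample rejects normality
  set.seed(61)
  xb <- c(rnorm(20, 0, 0.01), rnorm(20, 10, 0.01))
  expect_lt(normality_test(xb)$p_value, 0.01)

  expect_error(normality_test(rep(1, 10)), class = "kfc_degenerate_data")
  expect_error(normality_test(rnorm(5)), class = "kfc_insufficient_data")
})

test_that("normality p-values are roughly uniform under the null", {
  set.seed(71)
  p <- replicate(400, normality_test(rnorm(60))$p_value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group_summary computes mean and SEM", {
  s <- group_summary(c(0.2, 0.4), "pair")
  expect_equal(s$mean, 0.3)
  expect_equal(s$sem, 0.1)
  s1 <- group_summary(0.5)
  expect_equal(s1$mean, 0.5)
  expect_equal(s1$sem, 0)
  x <- runif(9)
  expect_equal(group_summary(sample(x))$mean, group_summary(x)$mean)
  expect_error(group_summary(numeric(0)), class = "kfc_empty_selection")
})

test_that("significance stars follow the p < 0.001 convention", {
  expect_equal(significance_stars(c(5e-4, 5e-3, 0.04, 0.2)),
               c("***", "**", "*", "ns"))
})

test_that("compare_groups assembles the full comparison table", {
  fix <- grouped_fixture(c(A = 5, B = 5, C = 4), seed = 8)
  tab <- compare_groups(fix$D, fix$groups)
  expect_equal(nrow(tab), 3) # AB, AC, BC
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_equal(tab$n1[1], 25)           # 5 x 5 between
  expect_equal(tab$n2[1], 10 + 10)      # pooled within
  expect_equal(tab$stars, significance_stars(tab$p))

  tab2 <- compare_groups(fix$D, fix$groups, mode = "between-vs-between")
  expect_equal(nrow(tab2), choose(3, 2))
  expect_true(all(startsWith(tab2$set1, "between")))

  tab3 <- compare_groups(fix$D, fix$groups, adjust = "BH")
  expect_true(all(tab3$p >= tab$p - 1e-12))
})
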