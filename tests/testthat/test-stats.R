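# From-scratch enumeration oracles, independent of the implementations.

# two-sided Fisher p by rational enumeration over the first cell
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  as_ <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, as_) * choose(r2, c1 - as_) / choose(n, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# exact two-sided Mann-Whitney by enumerating all group assignments
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  m <- length(pooled)
  combos <- utils::combn(m, n)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- n * (m - n) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided Wilcoxon signed rank by enumerating sign patterns
wsr_oracle <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

test_that("Fisher's exact test reproduces the frailty-table p-values of 1", {
  expect_equal(fisher_exact_2x2(rbind(c(4, 5), c(5, 7)))$p_value, 1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(3, 6), c(3, 9)))$p_value, 1,
               tolerance = 1e-12)
})

test_that("Fisher's exact test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252,
               tolerance = 1e-12)
  set.seed(14)
  for (k in 1:25) {
    tab <- matrix(stats::rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("Fisher p is invariant to transposition and row swaps, probabilities sum to 1", {
  tab <- rbind(c(7, 2), c(3, 8))
  p <- fisher_exact_2x2(tab)$p_value
  expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p, tolerance = 1e-12)

  r1 <- 9; r2 <- 11; c1 <- 8
  supp <- max(0, c1 - r2):min(r1, c1)
  expect_equal(sum(stats::dhyper(supp, r1, r2, c1)), 1, tolerance = 1e-12)

  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(3, 9))), "degenerate")
  expect_error(fisher_exact_2x2(rbind(c(1.5, 2), c(3, 9))), "integer")
})

test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "mann_whitney_exact")

  set.seed(5)
  for (k in 1:12) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- round(stats::rnorm(nx), 3); y <- round(stats::rnorm(ny, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney(x, y)$p_value, mw_oracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("identical samples give p ~ 1; exact and approximate agree", {
  x <- c(1, 5, 9, 13, 2.5)
  expect_gte(mann_whitney(x, x)$p_value, 0.99)

  set.seed(6)
  x <- stats::rnorm(10); y <- stats::rnorm(10, 0.6)
  p_ex <- mann_whitney(x, y, exact_threshold = 20)$p_value
  p_ap <- mann_whitney(x, y, exact_threshold = 0)$p_value
  expect_lt(abs(p_ex - p_ap), 0.02)
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("Wilcoxon signed rank matches sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25, tolerance = 1e-12)

  set.seed(8)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    pre <- round(stats::rnorm(n), 3)
    post <- round(pre + stats::rnorm(n, 0.3), 3)
    d <- post - pre
    if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 wsr_oracle(pre, post), tolerance = 1e-9)
  }
})

test_that("Wilcoxon conventions: zeros dropped, sign-flip symmetry, Pratt variant", {
  pre <- c(1, 2, 3, 4, 5)
  expect_error(wilcoxon_signed_rank(pre, pre), "all differences zero")

  post <- pre + c(1, -2, 3, -4, 5)
  p1 <- wilcoxon_signed_rank(pre, post)$p_value
  p2 <- wilcoxon_signed_rank(post, pre)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)

  # zeros are dropped before ranking: n reflects non-zero differences only
  post2 <- pre + c(0, 0, 1, 2, 3)
  expect_equal(wilcoxon_signed_rank(pre, post2)$n1, 3L)

  pr <- wilcoxon_signed_rank(pre, post2, zeros = "pratt")
  expect_equal(pr$method, "wilcoxon_pratt_normal")
  expect_gt(pr$p_value, 0); expect_lte(pr$p_value, 1)
})

test_that("ICC matches a hand-computed ANOVA decomposition", {
  m <- matrix(c(9, 6, 8, 7, 10, 6, 8, 8), nrow = 4)  # subjects x raters
  # hand decomposition
  n <- 4; k <- 2
  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  mse <- (sum((m - g)^2) - k * sum((rowMeans(m) - g)^2) -
            n * sum((colMeans(m) - g)^2)) / ((n - 1) * (k - 1))
  icc2_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc3_hand <- (msr - mse) / (msr + (k - 1) * mse)

  expect_equal(icc_single(m, "ICC2")$icc, icc2_hand, tolerance = 1e-9)
  expect_equal(icc_single(m, "ICC3")$icc, icc3_hand, tolerance = 1e-9)

  dup <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_single(dup)$icc, 1, tolerance = 1e-12)
  expect_error(icc_single(matrix(3, 4, 2)), "between-subject variance")
  expect_error(icc_single(matrix(1:3, 3, 1)), "at least 2")
})
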