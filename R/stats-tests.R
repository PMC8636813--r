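#' Nonparametric tests used for cohort comparisons
#'
#' The comparison layer is two-tailed throughout, with significance at
#' alpha = 0.05 by default: Fisher's exact test for 2x2 categorical
#' contrasts, the independent-samples Mann-Whitney U test between groups,
#' and the Wilcoxon signed-rank test for paired (pre/post) contrasts.
#' Every function returns a one-row `vm_test` tibble with the statistic,
#' the two-sided p-value, a method tag and the group sizes.
#'
#' @name cohort_tests
NULL

new_vm_test <- function(statistic, p, method, n1, n2 = NA_integer_) {
  out <- tibble(
    statistic = statistic, p_value = p, method = method,
    n1 = as.integer(n1), n2 = as.integer(n2)
  )
  class(out) <- c("vm_test", class(out))
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the standard "sum of no-more-likely tables" rule: with
#' margins fixed, the p-value is the total hypergeometric probability of
#' all tables whose probability does not exceed that of the observed table
#' (likelihood comparison with 1e-12 relative tolerance).
#'
#' @param table 2x2 matrix of non-negative integer counts; both row and
#'   both column margins must be positive.
#' @return A `vm_test` tibble; `statistic` is the observed `[1,1]` count.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must hold non-negative integer counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: a zero margin leaves nothing to test.")
  }
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  new_vm_test(a, p, "fisher_exact_2x2", r1 + r2)
}

#' Mann-Whitney U test (independent samples)
#'
#' Exact permutation p-value when the pooled sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Two-sided.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_threshold Pooled-size crossover from exact to approximate
#'   (default 20).
#' @return A `vm_test` tibble; `statistic` is U for `x`.
#' @export
mann_whitney <- function(x, y, exact_threshold = 20) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_threshold && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  new_vm_test(unname(ht$statistic), ht$p.value,
              if (use_exact) "mann_whitney_exact" else "mann_whitney_normal",
              length(x), length(y))
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Differences are `post - pre`; zero differences are dropped before
#' ranking (the classical convention; the Pratt variant, which ranks zeros
#' and then discards their ranks, is available via `zeros = "pratt"`).
#' Exact p when the number of non-zero differences is at most
#' `exact_threshold` and their magnitudes are tie-free, else the normal
#' approximation with tie and continuity corrections. Two-sided.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param exact_threshold Exact/approximate crossover (default 25).
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return A `vm_test` tibble; `statistic` is W+ (sum of ranks of positive
#'   differences).
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_threshold = 25,
                                 zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  if (length(pre) != length(post) || length(pre) == 0L) {
    abort("`pre` and `post` must be non-empty and of equal length.")
  }
  d <- post - pre
  nz <- d[d != 0]
  if (length(nz) == 0L) abort("all differences zero: the test is undefined.")

  if (zeros == "drop") {
    ties <- anyDuplicated(abs(nz)) > 0
    use_exact <- length(nz) <= exact_threshold && !ties
    ht <- suppressWarnings(
      wilcox.test(post, pre, paired = TRUE, exact = use_exact, correct = TRUE)
    )
    return(new_vm_test(unname(ht$statistic), ht$p.value,
                       if (use_exact) "wilcoxon_exact" else "wilcoxon_normal",
                       length(nz)))
  }

  # Pratt: rank |d| including zeros, then drop the zero ranks; normal
  # approximation with zero and tie corrections.
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n <- length(d)
  n0 <- sum(d == 0)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  tie_tab <- table(r[d != 0])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_vm_test(w_pos, p, "wilcoxon_pratt_normal", length(nz))
}

#' Intraclass correlation for repeated measurements
#'
#' Single-measurement ICC from the two-way ANOVA decomposition of a
#' subjects-by-raters matrix: `"ICC2"` (two-way random effects, absolute
#' agreement, ICC(2,1)) or `"ICC3"` (two-way mixed, consistency, ICC(3,1)).
#'
#' @param measurements Numeric matrix, subjects in rows (>= 2), repeated
#'   measurements/raters in columns (>= 2), no missing values.
#' @param type `"ICC2"` (default) or `"ICC3"`.
#' @return A one-row tibble with the estimate and the ANOVA mean squares.
#' @export
icc_single <- function(measurements, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  m <- as.matrix(measurements)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 subjects and 2 repeated measurements.")
  }
  if (anyNA(m)) abort("missing values are not supported.")
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  if (var(rm_) < 1e-24) {
    abort("zero between-subject variance: ICC is undefined.")
  }
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- if (type == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  tibble(type = type, icc = est, msr = msr, msc = msc, mse = mse,
         n_subjects = n, n_raters = k)
}
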