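#' Build a group-comparison table
#'
#' Renders the study-style comparison layout from any cohort tibble: per
#' group mean and SD for each measure, plus a two-sided p-value per
#' contrast — Mann-Whitney for independent groupings, Wilcoxon signed rank
#' for pre/post contrasts within subject, and Fisher's exact test when the
#' measure is binary and the grouping has two levels. Significance is
#' flagged at `alpha` (default 0.05); no multiple-testing correction is
#' applied (the `n_tests` attribute carries the comparison count so users
#' can apply their own).
#'
#' @param data Cohort tibble, one row per subject (or subject x timepoint).
#' @param measures Character vector of measure columns (numeric, or
#'   logical/binary for Fisher contrasts).
#' @param group Grouping column for independent comparisons; all pairwise
#'   contrasts are tested.
#' @param paired_by Subject-id column; when given together with
#'   `timepoint`, contrasts are pre/post Wilcoxon tests within each level
#'   of `group` (or over everyone when `group` is `NULL`).
#' @param timepoint Timepoint column with exactly two levels (pre/post
#'   order taken as `c("pre", "post")` when present, else sorted).
#' @param alpha Significance level.
#' @return A `vm_comparison` tibble: one row per measure x contrast with
#'   per-side mean/sd/n, the formatted `mean ± SD` summaries, `p_value`,
#'   `method` and `significant`.
#' @export
build_comparison_table <- function(data, measures, group = NULL,
                                   paired_by = NULL, timepoint = NULL,
                                   alpha = 0.05) {
  data <- as_tibble(data)
  missing_m <- setdiff(measures, names(data))
  if (length(missing_m) > 0) {
    abort(sprintf("measure column(s) not in data: %s.",
                  paste(missing_m, collapse = ", ")))
  }
  out <- if (!is.null(paired_by)) {
    paired_comparison(data, measures, group, paired_by, timepoint)
  } else {
    independent_comparison(data, measures, group)
  }
  out <- dplyr::mutate(out, significant = .data$p_value < alpha)
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("vm_comparison", class(out))
  out
}

fmt_ms <- function(m, s) sprintf("%.3f ± %.3f", m, s)

summarise_side <- function(v, measure, grp_label) {
  if (anyNA(v) || length(v) == 0L) {
    abort(sprintf("measure '%s' is missing or incomplete for group '%s'.",
                  measure, grp_label))
  }
  list(mean = mean(v), sd = sd(v), n = length(v))
}

independent_comparison <- function(data, measures, group) {
  if (is.null(group)) abort("independent comparisons need a `group` column.")
  if (!group %in% names(data)) abort(sprintf("no column '%s' in data.", group))
  g <- data[[group]]
  levels <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  if (length(levels) < 2L) abort("grouping must have at least two levels.")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(pairs, function(pr) {
      x <- data[[m]][g == pr[1]]
      y <- data[[m]][g == pr[2]]
      s1 <- summarise_side(x, m, pr[1])
      s2 <- summarise_side(y, m, pr[2])
      if (is.logical(x) || all(c(x, y) %in% c(0, 1))) {
        tab <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
        ht <- fisher_exact_2x2(tab)
      } else {
        ht <- mann_whitney(x, y)
      }
      tibble(
        measure = m, group1 = pr[1], group2 = pr[2],
        mean1 = s1$mean, sd1 = s1$sd, n1 = s1$n,
        mean2 = s2$mean, sd2 = s2$sd, n2 = s2$n,
        summary1 = fmt_ms(s1$mean, s1$sd), summary2 = fmt_ms(s2$mean, s2$sd),
        p_value = ht$p_value, method = ht$method
      )
    })
  })
}

paired_comparison <- function(data, measures, group, paired_by, timepoint) {
  if (is.null(timepoint) || !timepoint %in% names(data)) {
    abort("paired comparisons need a `timepoint` column.")
  }
  tps <- unique(as.character(data[[timepoint]]))
  if (length(tps) != 2L) abort("`timepoint` must have exactly two levels.")
  if (all(c("pre", "post") %in% tps)) tps <- c("pre", "post") else tps <- sort(tps)
  strata <- if (is.null(group)) list(all = data) else split(data, data[[group]])
  purrr::map_dfr(names(strata), function(gname) {
    d <- strata[[gname]]
    if (nrow(d) == 0L) abort(sprintf("group '%s' is empty.", gname))
    wide_ids <- intersect(
      d[[paired_by]][d[[timepoint]] == tps[1]],
      d[[paired_by]][d[[timepoint]] == tps[2]]
    )
    if (length(wide_ids) == 0L) {
      abort(sprintf("no paired subjects in group '%s'.", gname))
    }
    purrr::map_dfr(measures, function(m) {
      d1 <- d[d[[timepoint]] == tps[1], ]
      d2 <- d[d[[timepoint]] == tps[2], ]
      pre <- d1[[m]][match(wide_ids, d1[[paired_by]])]
      post <- d2[[m]][match(wide_ids, d2[[paired_by]])]
      s1 <- summarise_side(pre, m, paste(gname, tps[1]))
      s2 <- summarise_side(post, m, paste(gname, tps[2]))
      ht <- wilcoxon_signed_rank(pre, post)
      tibble(
        measure = m, group1 = paste(gname, tps[1]), group2 = paste(gname, tps[2]),
        mean1 = s1$mean, sd1 = s1$sd, n1 = s1$n,
        mean2 = s2$mean, sd2 = s2$sd, n2 = s2$n,
        summary1 = fmt_ms(s1$mean, s1$sd), summary2 = fmt_ms(s2$mean, s2$sd),
        p_value = ht$p_value, method = ht$method
      )
    })
  })
}

#' @method glance vm_comparison
#' @export
glance.vm_comparison <- function(x, ...) {
  tibble(
    n_measures = length(unique(x$measure)),
    n_contrasts = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' Plot a comparison table
#'
#' Group means with ±1 SD bars, one panel per measure (free y scales, since
#' the indices live on different scales).
#'
#' @param object A `vm_comparison` from [build_comparison_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vm_comparison
#' @export
autoplot.vm_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, measure = .data$measure, group = .data$group1,
                     mean = .data$mean1, sd = .data$sd1),
    dplyr::transmute(object, measure = .data$measure, group = .data$group2,
                     mean = .data$mean2, sd = .data$sd2)
  ) |> dplyr::distinct()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SD") +
    ggplot2::theme_minimal()
}

#' Plot cohort measure distributions by group
#'
#' @param data Cohort tibble (e.g. from [simulate_cohort()]).
#' @param measures Measure columns to plot.
#' @param group Grouping column (default `"group"`).
#' @return A ggplot object (boxplots, one panel per measure).
#' @export
plot_cohort_distributions <- function(data, measures, group = "group") {
  long <- tidyr::pivot_longer(as_tibble(data), dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
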