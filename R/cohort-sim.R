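#' Truncated normal draws by rejection
#'
#' Resample-until-valid truncated sampling (keeps the sample mean near the
#' nominal mean when truncation is mild, unlike clipping). Signals an error
#' if more than half of all draws fall outside the range, which indicates
#' inconsistent parameters.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lower,upper Truncation bounds (open interval).
#' @return Numeric vector of length `n`.
#' @export
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  drawn <- 0L
  while (length(out) < n) {
    m <- max(n - length(out), 32L)
    x <- rnorm(m, mean, sd)
    drawn <- drawn + m
    out <- c(out, x[x > lower & x < upper])
    if (drawn >= 64L && length(out) / drawn < 0.5) {
      abort(sprintf(
        "parameter inconsistency: truncation to (%g, %g) rejects more than half of N(%g, %g) draws.",
        lower, upper, mean, sd
      ))
    }
  }
  out[seq_len(n)]
}

# Multivariate truncated draws: n rows from N(mu, Sigma), rows redrawn
# until every component is inside its (open) range. Errors when any
# component rejects more than half of the draws.
draw_truncated_mvn <- function(n, mu, Sigma, lower, upper) {
  p <- length(mu)
  out <- matrix(NA_real_, n, p)
  need <- seq_len(n)
  drawn <- 0L
  bad_by_col <- numeric(p)
  while (length(need) > 0) {
    m <- max(length(need), 32L)
    x <- MASS::mvrnorm(m, mu, Sigma)
    x <- matrix(x, ncol = p)
    drawn <- drawn + m
    viol <- sweep(x, 2, lower, "<=") | sweep(x, 2, upper, ">=")
    bad_by_col <- bad_by_col + colSums(viol)
    ok <- which(rowSums(viol) == 0)
    take <- head(ok, length(need))
    if (length(take) > 0) {
      out[need[seq_along(take)], ] <- x[take, , drop = FALSE]
      need <- need[-seq_along(take)]
    }
    if (drawn >= 64L && any(bad_by_col / drawn > 0.5)) {
      abort(sprintf(
        "parameter inconsistency: truncation rejects more than half of the draws for measure '%s'.",
        colnames(Sigma)[which.max(bad_by_col)] %||% as.character(which.max(bad_by_col))
      ))
    }
  }
  out
}

equicorr <- function(p, rho) {
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}

#' Simulate a study cohort from registered parameters
#'
#' Draws per-subject morphometric measures from (multivariate) normal
#' distributions with the registered group means/SDs, truncated to each
#' measure's valid range by rejection. Measures within a subject share the
#' between-measure correlation `rho_between` on the Gaussian scale; in the
#' `"prepost"` design the two timepoints of the same measure additionally
#' share the within-subject correlation `rho_within` (the joint covariance
#' is the Kronecker product of the two correlation structures, scaled by
#' the per-cell SDs). Comorbidity items are independent Bernoulli draws at
#' the registered prevalences, constant within subject. The same seed
#' always reproduces the same table.
#'
#' @param params A [cohort_params()], e.g. [default_paper_params()].
#' @param design `"baseline"` (NPH/AD/HC single timepoint), `"prepost"`
#'   (Responder/Non-Responder x pre/post, with simulated outcome-change
#'   scores), or `"subtype"` (Classic/Complex single timepoint).
#' @param seed Integer seed (default: `params$seed`).
#' @return A tibble with one row per subject x timepoint: subject id,
#'   group, timepoint, one column per measure, the 11 mFI items, and (for
#'   `"prepost"`) outcome-change percentages and the true responder label.
#' @export
simulate_cohort <- function(params, design = c("baseline", "prepost", "subtype"),
                            seed = NULL) {
  design <- match.arg(design)
  validate_cohort_params(params)
  set.seed(seed %||% params$seed)
  switch(design,
    baseline = sim_single_timepoint(params, params$baseline, params$group_sizes),
    subtype = sim_single_timepoint(params, params$subtype_baseline,
                                   params$subtype_sizes),
    prepost = sim_prepost(params)
  )
}

sim_single_timepoint <- function(params, table, sizes) {
  if (is.null(table)) abort("params carry no parameters for this design.")
  measures <- unique(table$measure)
  rng <- range_bounds(params, measures)
  rows <- purrr::map_dfr(names(sizes), function(g) {
    n <- sizes[[g]]
    pars <- dplyr::filter(table, .data$group == !!g) |>
      dplyr::arrange(match(.data$measure, measures))
    if (nrow(pars) != length(measures)) {
      abort(sprintf("missing parameters for group %s.", g))
    }
    Sigma <- diag(pars$sd) %*% equicorr(length(measures), params$rho_between) %*%
      diag(pars$sd)
    colnames(Sigma) <- measures
    x <- draw_truncated_mvn(n, pars$mean, Sigma, rng$lower, rng$upper)
    colnames(x) <- measures
    dplyr::bind_cols(
      tibble(subject_id = sprintf("%s-%02d", g, seq_len(n)), group = g,
             timepoint = "baseline"),
      as_tibble(x)
    )
  })
  dplyr::bind_cols(rows, sim_comorbidities(params, nrow(rows)))
}

sim_prepost <- function(params) {
  tab <- params$responder_prepost
  measures <- unique(tab$measure)
  p <- length(measures)
  rng <- range_bounds(params, measures)
  C <- kronecker(equicorr(p, params$rho_between),
                 equicorr(2, params$rho_within))
  cells <- paste(rep(measures, each = 2), c("pre", "post"), sep = ".")
  rows <- purrr::map_dfr(names(params$responder_sizes), function(g) {
    n <- params$responder_sizes[[g]]
    pars <- dplyr::filter(tab, .data$group == !!g)
    mu <- sds <- numeric(2 * p)
    for (i in seq_along(measures)) {
      for (tp in 1:2) {
        row <- dplyr::filter(pars, .data$measure == measures[i],
                             .data$timepoint == c("pre", "post")[tp])
        mu[2 * (i - 1) + tp] <- row$mean
        sds[2 * (i - 1) + tp] <- row$sd
      }
    }
    Sigma <- diag(sds) %*% C %*% diag(sds)
    colnames(Sigma) <- cells
    lo <- rep(rng$lower, each = 2)
    hi <- rep(rng$upper, each = 2)
    x <- draw_truncated_mvn(n, mu, Sigma, lo, hi)
    colnames(x) <- cells
    com <- sim_comorbidities(params, n)
    out <- sim_outcomes(g, n)
    purrr::map_dfr(c("pre", "post"), function(tp) {
      xm <- x[, grepl(paste0("\\.", tp, "$"), cells), drop = FALSE]
      colnames(xm) <- measures
      dplyr::bind_cols(
        tibble(subject_id = sprintf("%s-%02d", g, seq_len(n)), group = g,
               timepoint = tp),
        as_tibble(xm), com, out
      )
    })
  })
  dplyr::arrange(rows, .data$group, .data$subject_id,
                 match(.data$timepoint, c("pre", "post")))
}

range_bounds <- function(params, measures) {
  lower <- vapply(measures, function(m) (params$ranges[[m]] %||% c(-Inf, Inf))[1],
                  numeric(1))
  upper <- vapply(measures, function(m) (params$ranges[[m]] %||% c(-Inf, Inf))[2],
                  numeric(1))
  list(lower = lower, upper = upper)
}

sim_comorbidities <- function(params, n) {
  items <- mfi11_items()
  prev <- params$prevalences[items]
  if (anyNA(prev)) {
    missing_items <- items[is.na(prev)]
    prev[is.na(prev)] <- 0
    names(prev) <- items
  }
  as_tibble(setNames(
    lapply(items, function(it) as.logical(rbinom(n, 1, prev[[it]]))),
    items
  ))
}

# Outcome-change scores consistent with the assigned responder label.
# These distributions are generator plumbing (the instrument scores are
# not modelled); draws violating the MCID rule for their label are redrawn.
sim_outcomes <- function(group, n) {
  is_resp <- group == "Responder"
  draw <- function(n, mean, sd) rnorm(n, mean, sd)
  ok <- function(g, b, c, f) pmax(g, b, c) >= 10 & f >= 20
  g <- b <- cg <- f <- numeric(n)
  need <- seq_len(n)
  for (iter in 1:1000) {
    m <- length(need)
    if (m == 0) break
    if (is_resp) {
      gg <- draw(m, 20, 8); bb <- draw(m, 15, 8); cc <- draw(m, 12, 8)
      ff <- draw(m, 32, 10)
      keep <- ok(gg, bb, cc, ff)
    } else {
      gg <- draw(m, 4, 5); bb <- draw(m, 3, 5); cc <- draw(m, 2, 5)
      ff <- draw(m, 8, 7)
      keep <- !ok(gg, bb, cc, ff)
    }
    g[need[keep]] <- gg[keep]; b[need[keep]] <- bb[keep]
    cg[need[keep]] <- cc[keep]; f[need[keep]] <- ff[keep]
    need <- need[!keep]
  }
  if (length(need) > 0) abort("failed to simulate outcome scores.")
  tibble(
    gait_improvement_pct = g, balance_improvement_pct = b,
    cognitive_improvement_pct = cg, functional_improvement_pct = f,
    true_responder = factor(if (is_resp) "Responder" else "Non-Responder",
                            levels = c("Responder", "Non-Responder"))
  )
}

#' Mann-Whitney power replicates at the registered group parameters
#'
#' For each replicate, draws two independent truncated-normal samples at
#' the registered baseline means/SDs for `measure` in `groups` and runs the
#' two-sided Mann-Whitney U test. Replicate `r` uses seed `seed + r - 1`,
#' so results are reproducible replicate-by-replicate.
#'
#' @param measure Measure name, e.g. `"z_evans"`.
#' @param groups Two group names (default NPH vs AD).
#' @param n_per_group Sample size per group (default 21).
#' @param reps Number of replicates.
#' @param seed Base seed.
#' @param params A [cohort_params()] (default [default_paper_params()]).
#' @return A tibble with columns `replicate`, `measure`, `p_value`.
#' @export
mw_power_replicates <- function(measure, groups = c("NPH", "AD"),
                                n_per_group = 21, reps = 200, seed = 1L,
                                params = default_paper_params()) {
  stopifnot(length(groups) == 2L)
  rng <- (params$ranges[[measure]] %||% c(-Inf, Inf))
  p1 <- param_lookup(params, groups[1], measure)
  p2 <- param_lookup(params, groups[2], measure)
  p_values <- vapply(seq_len(reps), function(r) {
    set.seed(seed + r - 1L)
    x <- rnorm_trunc(n_per_group, p1$mean, p1$sd, rng[1], rng[2])
    y <- rnorm_trunc(n_per_group, p2$mean, p2$sd, rng[1], rng[2])
    mann_whitney(x, y)$p_value
  }, numeric(1))
  tibble(replicate = seq_len(reps), measure = measure, p_value = p_values)
}
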