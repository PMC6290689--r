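#' Nonparametric dispersion summary
#'
#' Median, quartiles, 10th/90th percentiles and the quartile coefficient of
#' dispersion, `CoD = (Q3 - Q1)/(Q3 + Q1)`, the relative-spread measure used
#' throughout the cohort analysis. Quantiles default to linear interpolation
#' at rank `p(n+1)` clamped to `[1, n]` (R's type 6, GraphPad Prism's
#' convention); the estimator is configurable so alternatives can be
#' compared.
#'
#' @param values numeric vector, at least 3 finite values.
#' @param quantile_type quantile estimator passed to [stats::quantile()]
#'   (6 = rank `p(n+1)`, the default; 7 = R's default).
#' @return list with `n`, `median`, `q1`, `q3`, `cod`, `p10`, `p90`. When
#'   `q1 + q3 == 0` the CoD is undefined and returned as `NA` with attribute
#'   `cod_undefined = TRUE`.
#' @export
summary_stats <- function(values, quantile_type = 6L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("at least 3 finite values are required")
  q <- unname(stats::quantile(values, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                              type = quantile_type, names = FALSE))
  q1 <- q[2L]; q3 <- q[4L]
  cod <- if (q1 + q3 == 0) structure(NA_real_, cod_undefined = TRUE)
         else (q3 - q1) / (q3 + q1)
  list(n = n, median = q[3L], q1 = q1, q3 = q3, cod = cod,
       p10 = q[1L], p90 = q[5L])
}

#' Quartile coefficient of dispersion
#'
#' `(q3 - q1)/(q3 + q1)`; exposed directly so published quartiles can be
#' checked against published CoD values.
#'
#' @param q1,q3 first and third quartiles.
#' @return dimensionless CoD (fraction, not percent).
#' @export
cod <- function(q1, q3) {
  if (q1 + q3 == 0) return(NA_real_)
  (q3 - q1) / (q3 + q1)
}

#' Per-team case averages
#'
#' Mean of one parameter across the cases for each team. A team with a
#' missing value for any case of that parameter is excluded entirely from
#' the case-average set (the cohort's missing-data rule), so the returned
#' set may be smaller than the number of teams.
#'
#' @param table a [metrics_table()].
#' @param parameter parameter name.
#' @param cases optional character vector of case labels defining the
#'   complete set (defaults to all cases present in the table).
#' @return named numeric vector, team -> case-average value.
#' @export
case_average <- function(table, parameter, cases = NULL) {
  table <- metrics_table(as.data.frame(table))
  if (is.null(cases)) cases <- sort(unique(table$case))
  sub <- table[table$parameter == parameter & table$case %in% cases, ]
  out <- vapply(split(sub, sub$team), function(d) {
    v <- d$value[match(cases, d$case)]
    if (anyNA(v)) NA_real_ else mean(v)
  }, numeric(1L))
  out[!is.na(out)]
}

#' Symmetric percent difference
#'
#' `%diff = |b - a| / mean(a, b)`, in percent: `200 * |b - a| / (a + b)`.
#' Used for intra-team comparisons between paired submissions.
#'
#' @param a,b the two values; their sum must be positive.
#' @return percent difference.
#' @export
percent_diff <- function(a, b) {
  if (a + b <= 0) stop("percent_diff requires a + b > 0")
  200 * abs(b - a) / (a + b)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K^2 omnibus statistic combining the transformed skewness and kurtosis
#' z-scores (D'Agostino's skewness test and the Anscombe-Glynn kurtosis
#' test); p-value from the chi-squared distribution with 2 degrees of
#' freedom.
#'
#' @param values numeric vector, n >= 8.
#' @return list with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) stop("at least 8 observations are required")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

# tie-corrected Kruskal-Wallis H from a list of groups
.kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) h <- h / tie_corr
  h
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared p-value, followed by
#' Dunn's z-statistics for all pairwise group comparisons with a familywise
#' adjustment over all pairs (Bonferroni by default, configurable). If all
#' values are identical the test returns `H = 0, p = 1` rather than an
#' error.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty,
#'   total n >= 5).
#' @param adjust multiple-comparison adjustment method for the Dunn p-values
#'   (any method accepted by [stats::p.adjust()]).
#' @return list with `h`, `df`, `p`, and `pairwise`: a data frame with
#'   columns `group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
kruskal_wallis_dunn <- function(groups, adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 1L)) stop("every group must be nonempty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 5L) stop("total sample size must be at least 5")
  k <- length(groups)

  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(names(groups), 2L)
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = 0, p_unadjusted = 1, p_adjusted = 1,
                     stringsAsFactors = FALSE)
    return(list(h = 0, df = k - 1L, p = 1, pairwise = pw))
  }

  h <- .kw_h(groups)
  p <- stats::pchisq(h, df = k - 1L, lower.tail = FALSE)

  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- as.numeric(tapply(r, g, length))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(seq_len(k), 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    (rbar[i] - rbar[j]) / se
  })
  p_un <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  pw <- data.frame(group1 = names(groups)[pairs[1L, ]],
                   group2 = names(groups)[pairs[2L, ]],
                   z = as.numeric(z),
                   p_unadjusted = as.numeric(p_un),
                   p_adjusted = stats::p.adjust(p_un, method = adjust),
                   stringsAsFactors = FALSE)
  list(h = h, df = k - 1L, p = p, pairwise = pw)
}

#' Exhaustive permutation reference for the Kruskal-Wallis test
#'
#' Enumerates all assignments of the pooled observations to groups of the
#' given sizes and returns the exact permutation p-value of the
#' Kruskal-Wallis H statistic. Exponential in the total size; intended as an
#' independent oracle on tiny samples (total n <= 8).
#'
#' @param groups list of numeric vectors, total size <= 10.
#' @return list with `h` (observed), `p_exact`, `n_assignments`.
#' @export
kruskal_wallis_exact <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n > 10L) stop("exact enumeration is limited to total n <= 10")
  sizes <- lengths(groups)
  h_obs <- .kw_h(groups)

  idx_all <- seq_len(n)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, sizes_left, acc) {
    if (length(sizes_left) == 1L) {
      gs <- c(acc, list(remaining))
      h <- .kw_h(lapply(gs, function(i) x[i]))
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    pick <- utils::combn(remaining, sizes_left[1L])
    for (cidx in seq_len(ncol(pick))) {
      sel <- pick[, cidx]
      recurse(setdiff(remaining, sel), sizes_left[-1L],
              c(acc, list(sel)))
    }
  }
  recurse(idx_all, sizes, list())
  list(h = h_obs, p_exact = count / total, n_assignments = total)
}

#' Rank cases within each team
#'
#' For one parameter, ranks the cases from 1 (lowest value) to C (highest)
#' within every team that has a value for all cases; teams with any missing
#' case are excluded. Ties are broken deterministically by case-label order
#' and flagged.
#'
#' @param table a [metrics_table()].
#' @param parameter parameter name.
#' @param cases optional ordered case labels (defaults to sorted cases
#'   present).
#' @return data frame with columns `team`, `case`, `rank`, `tied`.
#' @export
rank_cases <- function(table, parameter, cases = NULL) {
  table <- metrics_table(as.data.frame(table))
  if (is.null(cases)) cases <- sort(unique(table$case))
  sub <- table[table$parameter == parameter & table$case %in% cases, ]
  out <- lapply(split(sub, sub$team), function(d) {
    v <- d$value[match(cases, d$case)]
    if (anyNA(v)) return(NULL)
    rk <- rank(v, ties.method = "first")  # case order breaks ties
    tied <- duplicated(v) | duplicated(v, fromLast = TRUE)
    data.frame(team = d$team[1L], case = cases, rank = as.integer(rk),
               tied = tied, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Rank-order consensus across teams
#'
#' Counts, for every (case, rank) cell, how many teams assigned that rank to
#' that case, and reports the majority case per rank: a case is the majority
#' only when strictly more than half of the ranked teams agree on it.
#'
#' @param ranks a data frame from [rank_cases()], optionally with an
#'   `experience` column for the per-cell breakdown.
#' @return list with `counts` (case x rank matrix), `majority` (named
#'   character vector, rank -> case label or `NA`), `n_teams`, and, when
#'   experience is available, `by_experience` (case x rank x experience
#'   array).
#' @export
rank_consensus <- function(ranks) {
  teams <- unique(ranks$team)
  cases <- sort(unique(ranks$case))
  n_ranks <- length(cases)
  counts <- table(factor(ranks$case, levels = cases),
                  factor(ranks$rank, levels = seq_len(n_ranks)))
  counts <- matrix(as.integer(counts), nrow = length(cases),
                   dimnames = list(case = cases, rank = seq_len(n_ranks)))
  stopifnot(all(rowSums(counts) == length(teams)),
            all(colSums(counts) == length(teams)))
  majority <- apply(counts, 2L, function(col) {
    top <- which.max(col)
    if (col[top] * 2L > length(teams)) cases[top] else NA_character_
  })
  out <- list(counts = counts, majority = majority, n_teams = length(teams))
  if ("experience" %in% names(ranks)) {
    levs <- unique(ranks$experience)
    out$by_experience <- table(
      factor(ranks$case, levels = cases),
      factor(ranks$rank, levels = seq_len(n_ranks)),
      factor(ranks$experience, levels = levs))
  }
  out
}

#' Ordinary least-squares check of reported vs. computed values
#'
#' Simple OLS with intercept plus the squared Pearson correlation, the
#' quality-assurance regression used to compare quantities reported by teams
#' against quantities recomputed from their submitted fields.
#'
#' @param x,y numeric vectors (n >= 3); `x` must have positive variance.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
ols_check <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least 3 paired values are required")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, n = length(x))
}
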