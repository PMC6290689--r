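test_that("summary quantiles use linear interpolation at rank p(n+1)", {
  s <- summary_stats(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 1.5)
  expect_equal(s$q3, 4.5)
  expect_equal(as.numeric(s$cod), 0.5)
  expect_equal(s$n, 5L)
  expect_lte(s$p10, s$q1)
  expect_gte(s$p90, s$q3)

  const <- summary_stats(rep(4.2, 6))
  expect_equal(as.numeric(const$cod), 0)

  expect_error(summary_stats(c(1, 2)), "3 finite")
  flagged <- summary_stats(c(-2, -1, 0, 1, 2))
  expect_true(is.na(flagged$cod))

  # permutation invariance
  set.seed(1)
  x <- rnorm(17)
  expect_equal(summary_stats(x), summary_stats(sample(x)))
})

test_that("CoD matches published quartile/CoD pairs and is scale invariant", {
  expect_equal(round(100 * cod(1.82, 2.91)), 23)  # cohort flow-rate row
  expect_equal(round(100 * cod(2.24, 6.31)), 48)  # cohort AWSS row
  x <- c(2.1, 3.3, 4.8, 5.0, 7.7)
  s <- summary_stats(x)
  s10 <- summary_stats(10 * x)
  expect_equal(as.numeric(s10$cod), as.numeric(s$cod))
  # no location invariance
  s_shift <- summary_stats(x + 5)
  expect_false(isTRUE(all.equal(as.numeric(s_shift$cod),
                                as.numeric(s$cod))))
})

test_that("case averages drop teams with any missing case", {
  cases <- paste0("case", 1:5)
  full <- data.frame(team = "A", case = cases, parameter = "awss",
                     value = 1:5)
  expect_equal(case_average(full, "awss"), c(A = 3))

  gap <- rbind(full,
               data.frame(team = "B", case = cases[-3], parameter = "awss",
                          value = rep(2, 4)))
  expect_equal(names(case_average(gap, "awss", cases = cases)), "A")

  na_gap <- rbind(full,
                  data.frame(team = "B", case = cases, parameter = "awss",
                             value = c(2, 2, NA, 2, 2)))
  expect_equal(names(case_average(na_gap, "awss")), "A")
})

test_that("the cohort's documented gaps give N = 27 and N = 25", {
  # 28 datasets; one lacks case 5 entirely, one lacks velocity everywhere,
  # one has velocity only for case 1
  cases <- paste0("case", 1:5)
  ids <- sprintf("T%02d", 1:28)
  grid <- expand.grid(team = ids, case = cases, stringsAsFactors = FALSE)
  wss <- data.frame(grid, parameter = "awss", value = 1)
  vel <- data.frame(grid, parameter = "velocity", value = 50)
  wss$value[wss$team == "T20" & wss$case == "case5"] <- NA
  vel$value[vel$team == "T20" & vel$case == "case5"] <- NA
  vel$value[vel$team == "T21"] <- NA
  vel$value[vel$team == "T24" & vel$case != "case1"] <- NA
  tab <- metrics_table(rbind(wss, vel))
  expect_equal(length(case_average(tab, "awss")), 27L)
  expect_equal(length(case_average(tab, "velocity")), 25L)
})

test_that("percent difference is symmetric and matches published rows", {
  expect_equal(round(percent_diff(1.84, 1.99)), 8)
  expect_equal(round(percent_diff(2.64, 4.05)), 42)
  expect_equal(percent_diff(3, 3), 0)
  expect_equal(percent_diff(2, 5), percent_diff(5, 2))
  expect_error(percent_diff(-2, 2), "> 0")
})

test_that("the omnibus normality K2 matches an independent implementation", {
  # frozen from scipy.stats.normaltest on the same draws
  set.seed(7)
  x <- round(rnorm(20, 5, 2), 4)
  r <- dagostino_pearson(x)
  expect_equal(r$k2, 2.5289744363, tolerance = 1e-9)
  expect_equal(r$p, 0.2823840604, tolerance = 1e-9)
  y <- round(rexp(15), 4)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$k2, 3.2090819162, tolerance = 1e-9)
  expect_equal(r2$p, 0.2009817928, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "at least 8")
})

test_that("the normality test holds its level and detects strong skew", {
  set.seed(2026)
  p_null <- vapply(1:100, function(i) dagostino_pearson(rnorm(1e4))$p,
                   numeric(1))
  expect_gte(mean(p_null > 0.05), 0.95)
  expect_lt(dagostino_pearson(rexp(1e4))$p, 1e-6)
})

test_that("Kruskal-Wallis H matches stats::kruskal.test including ties", {
  g <- list(c(1, 2, 3, 5, 5), c(4, 5, 6), c(2, 8, 9, 10))
  kw <- kruskal_wallis_dunn(g)
  ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(kw$h, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
  expect_equal(nrow(kw$pairwise), 3L)

  same <- kruskal_wallis_dunn(list(rep(2, 4), rep(2, 3)))
  expect_equal(same$h, 0)
  expect_equal(same$p, 1)
  expect_true(all(same$pairwise$p_adjusted == 1))
})

test_that("identical groups give Dunn p-values near one", {
  set.seed(9)
  x <- rnorm(6)
  kw <- kruskal_wallis_dunn(list(x, x, x))
  expect_lt(kw$h, 1e-10)
  expect_true(all(kw$pairwise$p_adjusted > 0.99))
})

test_that("exact enumeration reproduces the small-sample null", {
  ex <- kruskal_wallis_exact(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(ex$n_assignments, choose(6, 3))
  expect_equal(ex$p_exact, 2 / 20)  # the two fully separated assignments
  kw <- kruskal_wallis_dunn(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$h, ex$h)
})

test_that("case ranking and consensus follow the strict-majority rule", {
  cases <- paste0("case", 1:5)
  one <- data.frame(team = "A", case = cases, parameter = "awss",
                    value = c(10, 20, 30, 40, 50))
  r <- rank_cases(one, "awss")
  expect_equal(r$rank, 1:5)
  expect_false(any(r$tied))

  # identical tables across teams: perfect diagonal consensus
  many <- do.call(rbind, lapply(sprintf("T%02d", 1:9), function(id)
    transform(one, team = id)))
  rc <- rank_consensus(rank_cases(many, "awss"))
  expect_equal(diag(rc$counts), rep(9L, 5))
  expect_equal(unname(rc$majority), cases)

  # 26 teams, exactly half agreeing: no strict majority at that rank
  vals <- rbind(matrix(rep(c(1, 2, 3, 4, 5), 13), nrow = 13, byrow = TRUE),
                matrix(rep(c(5, 1, 2, 3, 4), 13), nrow = 13, byrow = TRUE))
  tab <- do.call(rbind, lapply(1:26, function(i)
    data.frame(team = sprintf("T%02d", i), case = cases,
               parameter = "awss", value = vals[i, ])))
  rc26 <- rank_consensus(rank_cases(tab, "awss"))
  expect_true(is.na(rc26$majority[["1"]]))  # 13 of 26 is not a majority

  # a team missing a case is excluded from ranking
  gap <- rbind(many, data.frame(team = "T99", case = cases[-1],
                                parameter = "awss", value = 1:4))
  expect_false("T99" %in% rank_cases(gap, "awss")$team)

  # ties broken by case order and flagged
  tied <- data.frame(team = "A", case = cases, parameter = "awss",
                     value = c(1, 1, 2, 3, 4))
  rt <- rank_cases(tied, "awss")
  expect_equal(rt$rank[1:2], c(1L, 2L))
  expect_true(all(rt$tied[1:2]))
})

test_that("the QA regression returns slope, intercept and R^2", {
  x <- c(1, 2, 3, 4, 5)
  f <- ols_check(x, 1.02 * x)
  expect_equal(f$slope, 1.02)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  expect_equal(ols_check(x, rep(2, 5))$r_squared, 0)
  expect_error(ols_check(rep(1, 5), x), "variance")

  set.seed(4)
  xx <- runif(200, 1, 5)
  f2 <- ols_check(xx, 2 * xx + rnorm(200, sd = 1e-8))
  expect_equal(f2$slope, 2, tolerance = 1e-6)
})
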