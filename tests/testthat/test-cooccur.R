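male_rates <- population_rates(hnscc_incidence = 0.000152)
female_rates <- population_rates(hnscc_incidence = 0.0000761)

test_that("population scaling reproduces the reference cells for both sexes", {
  tab_m <- build_population_table(male_rates, 127 / 692)
  expect_equal(c(tab_m$a, tab_m$b, tab_m$c, tab_m$d),
               c(279, 689721, 1241, 9308759))
  tab_f <- build_population_table(female_rates, 5 / 36)
  expect_equal(c(tab_f$a, tab_f$b, tab_f$c, tab_f$d),
               c(106, 689894, 655, 9309345))
})

test_that("zero joint probability puts the whole outcome margin in c", {
  tab <- build_population_table(male_rates, 0)
  expect_equal(tab$a, 0)
  expect_equal(tab$c, round(1e7 * 0.000152))
  expect_equal(tab$b, round(1e7 * 0.069))
  expect_equal(tab$d, 1e7 - tab$b - tab$c)
})

test_that("inconsistent rates are rejected instead of clipped", {
  tight <- population_rates(hnscc_incidence = 0.5, dm_prevalence = 1e-6,
                            population_size = 1e6)
  expect_error(build_population_table(tight, 1), "inconsistent rates")
})

test_that("OR and RR follow their closed forms with continuity handling", {
  expect_equal(odds_ratio(c(5, 5, 5, 5)), 1.0)
  tab_m <- build_population_table(male_rates, 127 / 692)
  expect_equal(round(odds_ratio(tab_m), 2), 3.03)
  expect_equal(round(relative_risk(tab_m), 2), 3.03)
  tab_f <- build_population_table(female_rates, 5 / 36)
  expect_equal(round(odds_ratio(tab_f), 2), 2.18)
  expect_equal(round(relative_risk(tab_f), 2), 2.18)
  # equal risks give RR exactly 1
  expect_equal(relative_risk(c(10, 90, 20, 180)), 1.0)
  expect_error(odds_ratio(c(1, 0, 2, 3)), "continuity")
  expect_equal(odds_ratio(c(1, 0, 2, 3), continuity = TRUE),
               (1.5 * 3.5) / (0.5 * 2.5))
})

test_that("two-sided fisher matches hand enumeration on tiny tables", {
  expect_equal(fisher_exact(c(3, 1, 1, 3)), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(c(2, 2, 2, 2)), 1.0)
})

test_that("log-space fisher equals exact enumeration for all tables N <= 40", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(4, 0.05, 1)))
    got <- fisher_exact(cells)
    want <- oracle_fisher_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(fisher_exact(cells, "greater"),
                 oracle_fisher_greater(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("fisher agrees with stats::fisher.test at moderate sizes", {
  set.seed(7)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(20:200, 1),
                                        prob = runif(4, 0.05, 1)))
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisher_exact(cells),
                 stats::fisher.test(m)$p.value, tolerance = 1e-7)
    expect_equal(fisher_exact(cells, "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-7)
  }
})

test_that("fisher stays finite and tiny at population scale", {
  p_m <- fisher_exact(c(279, 689721, 1241, 9308759))
  expect_gt(p_m, 0)
  expect_lt(p_m, 1e-45)
  p_f <- fisher_exact(c(106, 689894, 655, 9309345))
  expect_gt(p_f, 0)
  expect_lt(p_f, 1e-10)
})

test_that("built tables conserve margins over random parameter draws", {
  set.seed(101)
  for (i in 1:1000) {
    N <- round(runif(1, 1e4, 1e7))
    prev <- runif(1, 0.001, 0.3)
    inc <- runif(1, 1e-6, 1e-3)
    p <- runif(1)
    tab <- tryCatch(
      build_population_table(
        population_rates(inc, prev, N), p),
      error = function(e) NULL)
    if (is.null(tab)) next   # p implies a > exposure margin; rejected
    expect_identical(tab$a + tab$b, round(N * prev))
    expect_identical(tab$a + tab$c, round(N * inc))
    expect_identical(tab$a + tab$b + tab$c + tab$d, as.double(N))
  }
})

test_that("OR approximates RR for rare outcomes", {
  set.seed(202)
  for (i in 1:100) {
    inc <- runif(1, 1e-6, 1e-3)
    prev <- runif(1, 0.01, 0.3)
    p <- runif(1, 0, min(1, prev * 5))
    tab <- tryCatch(
      build_population_table(population_rates(inc, prev, 1e7), p),
      error = function(e) NULL)
    if (is.null(tab) || tab$a == 0 || tab$c == 0) next
    o <- odds_ratio(tab); r <- relative_risk(tab)
    expect_lt(abs(o - r) / r, 0.02)
  }
})

test_that("increasing a with fixed margins strictly increases the OR", {
  base <- c(10, 90, 30, 870)
  ors <- vapply(0:5, function(k) {
    odds_ratio(base + c(k, -k, -k, k))
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("multinomial sampling recovers the deterministic OR", {
  tab <- build_population_table(
    population_rates(0.01, 0.1, 1e6), 0.3)
  det_or <- odds_ratio(tab)
  draw <- build_population_table(
    population_rates(0.01, 0.1, 1e6), 0.3,
    method = "multinomial", seed = 99)
  est_or <- odds_ratio(draw)
  # approximate 95% CI of log OR from the sampled cells
  se <- sqrt(sum(1 / c(draw$a, draw$b, draw$c, draw$d)))
  expect_lt(abs(log(est_or) - log(det_or)), 1.96 * se)
})

test_that("the stratified runner reproduces the full per-sex report", {
  res <- run_cooccurrence(
    list(male = male_rates, female = female_rates),
    c(male = 127 / 692, female = 5 / 36))
  expect_s3_class(res, "cooccurrence_result")
  expect_equal(res$sex, c("male", "female"))
  expect_equal(res$a, c(279, 106))
  expect_equal(round(res$odds_ratio, 2), c(3.03, 2.18))
  # identical strata give identical rows
  sym <- run_cooccurrence(
    list(x = male_rates, y = male_rates), c(x = 0.2, y = 0.2))
  expect_equal(sym$odds_ratio[1], sym$odds_ratio[2])
  expect_equal(sym$p_value[1], sym$p_value[2])
})

test_that("an incidence-matched conditional probability gives OR near 1", {
  # solve p so that a/(a+b) = c/(c+d): outcome risk equal in both rows
  N <- 1e7; prev <- 0.069; inc <- 0.000152
  m_out <- round(N * inc); m_exp <- round(N * prev)
  # a = p * m_out with a / m_exp = (m_out - a) / (N - m_exp)
  a_star <- m_out * m_exp / N
  res <- run_cooccurrence(
    list(s = population_rates(inc, prev, N)),
    c(s = a_star / m_out))
  expect_lt(abs(res$odds_ratio - 1), 0.01)
})
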