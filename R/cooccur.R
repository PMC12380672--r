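#' Population rate parameters for one stratum
#'
#' Bundles the population size, exposure prevalence (DM), and outcome
#' incidence (HNSCC) used to scale observed cohort proportions to a
#' population 2x2 table. Defaults follow the reference analysis: a
#' simulated population of ten million per sex and a DM prevalence of
#' 6.9%; the incidence must be supplied per sex (0.000152 male /
#' 0.0000761 female in the reference analysis).
#'
#' @param hnscc_incidence Outcome incidence proportion for this stratum.
#' @param dm_prevalence Exposure prevalence proportion (default 0.069).
#' @param population_size Simulated population size (default 1e7).
#' @return A one-row tibble of class `population_rates`.
#' @export
#' @examples
#' population_rates(hnscc_incidence = 0.000152)
population_rates <- function(hnscc_incidence,
                             dm_prevalence = 0.069,
                             population_size = 1e7) {
  stopifnot(length(hnscc_incidence) == 1, length(dm_prevalence) == 1,
            population_size >= 1,
            dm_prevalence >= 0, dm_prevalence <= 1,
            hnscc_incidence >= 0, hnscc_incidence <= 1)
  if (dm_prevalence + hnscc_incidence > 1) {
    stop("dm_prevalence + hnscc_incidence must not exceed 1")
  }
  structure(tibble::tibble(population_size = as.double(population_size),
                           dm_prevalence = dm_prevalence,
                           hnscc_incidence = hnscc_incidence),
            class = c("population_rates", class(tibble::tibble())))
}

#' 2x2 contingency table constructor
#'
#' Cells follow the epidemiological convention: `a` = both conditions,
#' `b` = exposure only, `c` = outcome only, `d` = neither.
#'
#' @param a,b,c,d Non-negative counts.
#' @return One-row tibble of class `contingency_table` with the four
#'   cells and the margins.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cells must be non-negative")
  structure(tibble::tibble(a = a, b = b, c = c, d = d,
                           n = a + b + c + d,
                           exposure_margin = a + b,
                           outcome_margin = a + c),
            class = c("contingency_table", class(tibble::tibble())))
}

.as_cells <- function(table) {
  if (inherits(table, "data.frame")) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(table)), nrow(table) == 1)
    c(a = as.double(table$a), b = as.double(table$b),
      c = as.double(table$c), d = as.double(table$d))
  } else if (is.numeric(table) && length(table) == 4) {
    # double arithmetic: integer cells overflow in ad/bc at population scale
    stats::setNames(as.double(table), c("a", "b", "c", "d"))
  } else {
    stop("table must be a contingency_table row or a numeric vector of 4 cells")
  }
}

#' Scale an observed co-occurrence proportion to a population 2x2 table
#'
#' Allocates the expected cell counts of a population of size N given the
#' exposure prevalence, the outcome incidence, and the observed
#' conditional co-occurrence proportion from a clinical cohort. Margins
#' are fixed first — outcome margin `round(N * incidence)`, exposure
#' margin `round(N * prevalence)` — then the joint cell is
#' `a = round(p_obs * outcome_margin)` and the remaining cells follow by
#' subtraction. This deterministic expected-count allocation is what
#' reproduces published population-scaled tables cell for cell; a seeded
#' multinomial draw with the same cell probabilities is available via
#' `method = "multinomial"` for a simulation reading of the model.
#'
#' @param rates A [population_rates()] row.
#' @param p_cond Observed conditional proportion: either a single number
#'   in \[0, 1\] or a one-row result of [conditional_probability()].
#' @param method `"expected"` (deterministic rounding, default) or
#'   `"multinomial"` (one seeded multinomial draw of N individuals).
#' @param seed RNG seed, required for `method = "multinomial"`.
#' @return A [contingency_table()] row.
#' @export
#' @examples
#' rates <- population_rates(hnscc_incidence = 0.000152)
#' build_population_table(rates, 127 / 692)
build_population_table <- function(rates, p_cond,
                                   method = c("expected", "multinomial"),
                                   seed = NULL) {
  method <- match.arg(method)
  if (inherits(p_cond, "data.frame")) {
    stopifnot("value" %in% names(p_cond), nrow(p_cond) == 1)
    p_cond <- p_cond$value
  }
  stopifnot(is.numeric(p_cond), length(p_cond) == 1,
            p_cond >= 0, p_cond <= 1)
  N <- rates$population_size
  m_out <- round(N * rates$hnscc_incidence)
  m_exp <- round(N * rates$dm_prevalence)
  a <- round(p_cond * m_out)
  b <- m_exp - a
  c <- m_out - a
  d <- N - a - b - c
  if (any(c(a, b, c, d) < 0)) {
    stop("inconsistent rates: parameters imply a negative cell")
  }
  if (method == "multinomial") {
    if (is.null(seed)) stop("seed is required for method = 'multinomial'")
    pr <- c(a, b, c, d) / N
    draw <- withr::with_seed(seed, stats::rmultinom(1, size = N, prob = pr))
    a <- draw[1]; b <- draw[2]; c <- draw[3]; d <- draw[4]
  }
  contingency_table(a, b, c, d)
}

#' Odds ratio of a 2x2 table
#'
#' `OR = ad / bc`. With `continuity = TRUE` the Haldane–Anscombe 0.5
#' correction is added to every cell first; without it, a zero
#' denominator is an error rather than `Inf`.
#'
#' @param table A [contingency_table()] row or numeric vector `c(a,b,c,d)`.
#' @param continuity Apply the 0.5 cell correction (default `FALSE`).
#' @return Positive scalar.
#' @export
odds_ratio <- function(table, continuity = FALSE) {
  x <- .as_cells(table)
  if (continuity) x <- x + 0.5
  if (x["b"] * x["c"] == 0) {
    stop("undefined OR; enable continuity correction")
  }
  unname((x["a"] * x["d"]) / (x["b"] * x["c"]))
}

#' Relative risk of a 2x2 table
#'
#' `RR = (a / (a + b)) / (c / (c + d))`: the outcome risk among the
#' exposed relative to the unexposed.
#'
#' @inheritParams odds_ratio
#' @return Positive scalar.
#' @export
relative_risk <- function(table, continuity = FALSE) {
  x <- .as_cells(table)
  if (continuity) x <- x + 0.5
  if (x["a"] + x["b"] == 0 || x["c"] + x["d"] == 0) {
    stop("undefined RR: empty exposure row")
  }
  if (x["c"] == 0) stop("undefined RR; enable continuity correction")
  unname((x["a"] / (x["a"] + x["b"])) / (x["c"] / (x["c"] + x["d"])))
}

#' Fisher's exact test in log space
#'
#' Exact conditional test of independence on a 2x2 table via the
#' hypergeometric distribution with fixed margins. The two-sided p-value
#' uses the point-probability ("minlike") convention: the sum over all
#' tables with the observed margins whose point probability is at most
#' that of the observed table, with a relative tie tolerance of 1e-7.
#' All probability sums are accumulated in log space
#' (`dhyper(log = TRUE)` + log-sum-exp), so tables drawn from populations
#' of ten million are handled without underflow.
#'
#' @param table A [contingency_table()] row or numeric vector `c(a,b,c,d)`.
#' @param alternative `"two_sided"` (minlike), `"greater"` (enrichment of
#'   cell `a`), or `"less"`.
#' @return p-value in \[0, 1\] (possibly denormal-small; see
#'   [format_pvalue_bound()] for display).
#' @export
#' @examples
#' fisher_exact(c(3, 1, 1, 3))               # 34/70
#' fisher_exact(c(9, 186, 115, 19614), "greater")
fisher_exact <- function(table,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- .as_cells(table)
  a <- x["a"]
  m <- x["a"] + x["b"]   # exposure margin (white balls)
  n <- x["c"] + x["d"]   # non-exposure margin (black balls)
  k <- x["a"] + x["c"]   # outcome margin (drawn)
  if (alternative == "greater") {
    return(unname(stats::phyper(a - 1, m, n, k, lower.tail = FALSE)))
  }
  if (alternative == "less") {
    return(unname(stats::phyper(a, m, n, k, lower.tail = TRUE)))
  }
  support <- max(0, k - n):min(k, m)
  lp <- stats::dhyper(support, m, n, k, log = TRUE)
  l_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  keep <- lp <= l_obs + log1p(1e-7)
  ls <- lp[keep]
  mx <- max(ls)
  min(1, exp(mx) * sum(exp(ls - mx)))
}

#' Display bound for p-values below double-precision range
#'
#' Extremely enriched tables yield exact p-values smaller than the
#' smallest representable double; those are reported as a `"< floor"`
#' bound (default floor 4.95e-319, the convention used in the reference
#' tables) rather than `0`.
#'
#' @param p Numeric p-value(s).
#' @param floor Display floor.
#' @return Character vector.
#' @export
format_pvalue_bound <- function(p, floor = 4.95e-319) {
  ifelse(p < floor, sprintf("< %.3g", floor),
         sprintf("%.3g", p))
}

#' Sex-stratified population co-occurrence analysis
#'
#' Runs the full co-occurrence model for each stratum: builds the
#' population-scaled 2x2 table from that stratum's rates and observed
#' conditional proportion, then computes OR, RR, and the two-sided Fisher
#' exact p-value. The result mirrors the published per-sex association
#' table (cells, OR, RR, p).
#'
#' @param rates_by_sex Named list of [population_rates()] rows, e.g.
#'   `list(male = ..., female = ...)`.
#' @param p_cond_by_sex A [conditional_probability()] tibble (one row per
#'   sex), or a named numeric vector of proportions with the same names
#'   as `rates_by_sex`.
#' @inheritParams build_population_table
#' @return Tibble of class `cooccurrence_result`, one row per stratum:
#'   `sex`, `a`, `b`, `c`, `d`, `odds_ratio`, `relative_risk`, `p_value`.
#' @export
#' @examples
#' rates <- list(male = population_rates(0.000152),
#'               female = population_rates(0.0000761))
#' run_cooccurrence(rates, c(male = 127 / 692, female = 5 / 36))
run_cooccurrence <- function(rates_by_sex, p_cond_by_sex,
                             method = c("expected", "multinomial"),
                             seed = NULL) {
  method <- match.arg(method)
  if (inherits(p_cond_by_sex, "data.frame")) {
    p_cond_by_sex <- stats::setNames(p_cond_by_sex$value, p_cond_by_sex$sex)
  }
  strata <- names(rates_by_sex)
  if (is.null(strata) || !all(strata %in% names(p_cond_by_sex))) {
    stop("rates_by_sex and p_cond_by_sex must share stratum names")
  }
  rows <- purrr::map_dfr(strata, function(s) {
    tab <- build_population_table(rates_by_sex[[s]], p_cond_by_sex[[s]],
                                  method = method, seed = seed)
    tibble::tibble(
      sex = s,
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      odds_ratio = odds_ratio(tab),
      relative_risk = relative_risk(tab),
      p_value = fisher_exact(tab)
    )
  })
  structure(rows, class = c("cooccurrence_result", class(tibble::tibble())))
}

#' @rdname run_cooccurrence
#' @param x A `cooccurrence_result`.
#' @param ... Unused.
#' @method tidy cooccurrence_result
#' @export
tidy.cooccurrence_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname run_cooccurrence
#' @method glance cooccurrence_result
#' @export
glance.cooccurrence_result <- function(x, ...) {
  tibble::tibble(n_strata = nrow(x),
                 population_size = sum(x$a + x$b + x$c + x$d) / nrow(x),
                 min_p_value = min(x$p_value))
}
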