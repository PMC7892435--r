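# Demographic conversions and prevalence arithmetic accompanying a
# founder-allele dating analysis.

#' Exponential population growth rate
#'
#' Solves `T1 = T0 * exp(g * r)` for the per-generation growth rate `r`,
#' where `T0` is the population size at the founder event and `T1` the
#' present size.
#'
#' @param T0 population size at the founder event (> 0).
#' @param T1 present population size (> 0).
#' @param g generations elapsed (> 0).
#' @return `r = log(T1/T0) / g`.
#' @export
growth_rate <- function(T0, T1, g) {
  if (any(c(T0, T1, g) <= 0) || any(!is.finite(c(T0, T1, g)))) {
    stop("T0, T1 and g must be positive")
  }
  log(T1 / T0) / g
}

#' Convert generations to years and a calendar date
#'
#' Years are rounded to integers before subtracting from the anchor year
#' (the average birth year of the sampled carriers), so a point estimate of
#' 11.5 generations at 25 years/generation gives 287 years and the year
#' 1703. Intervals are converted endpoint-wise with the same rule.
#'
#' @param g generations (vectorized; interval endpoints welcome).
#' @param years_per_generation default 25.
#' @param anchor_year calendar year the count runs back from (default
#'   1990).
#' @return list with integer vectors `years` and `date`.
#' @export
generations_to_calendar <- function(g, years_per_generation = 25,
                                    anchor_year = 1990) {
  if (any(g < 0)) stop("g must be non-negative")
  if (years_per_generation <= 0) stop("years_per_generation must be positive")
  years <- round(g * years_per_generation)
  list(years = as.integer(years), date = as.integer(anchor_year - years))
}

#' Carrier frequency with exact binomial interval
#'
#' @param count carriers observed.
#' @param n sample size (> 0).
#' @param conf_level confidence level for the Clopper-Pearson interval.
#' @return Object of class `prevalence_result`: list with `count`, `n`,
#'   `freq`, `percent` and `ci95` (proportions).
#' @export
carrier_frequency <- function(count, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (count < 0 || count > n) stop("count must lie in [0, n]")
  bt <- stats::binom.test(count, n, conf.level = conf_level)
  structure(list(count = count, n = n, freq = count / n,
                 percent = 100 * count / n,
                 ci95 = as.numeric(bt$conf.int)),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("Carrier frequency: %d/%d = %.2f%% (exact 95%% CI %.2f-%.2f%%)\n",
              x$count, x$n, x$percent, 100 * x$ci95[1], 100 * x$ci95[2]))
  invisible(x)
}

#' Project a carrier frequency onto a population
#'
#' @param freq carrier frequency (proportion in \[0, 1\]; vectorized).
#' @param population_size target population size(s); a range in gives a
#'   range out.
#' @return Expected carrier count(s), rounded.
#' @export
project_carriers <- function(freq, population_size) {
  if (any(freq < 0 | freq > 1)) stop("freq must lie in [0, 1]")
  if (any(population_size < 0)) stop("population size must be non-negative")
  round(freq * population_size)
}

#' 2x2 table association statistics
#'
#' Odds ratio with Woolf (log-normal) 95% interval, chi-squared p-value and
#' Fisher exact p-value for the table `rbind(c(a, b), c(c, d))`. When any
#' cell is zero the Haldane-Anscombe +0.5 correction is applied to the OR
#' and its interval and flagged in the result.
#'
#' @param a,b,c,d non-negative integer cell counts (a/b = row 1, c/d =
#'   row 2).
#' @param correct continuity correction for the chi-squared test (default
#'   `FALSE`: plain Pearson chi-squared).
#' @return list with `or`, `ci95`, `p_chisq`, `p_fisher`, `corrected`,
#'   `table`.
#' @export
two_by_two <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("undefined table: a row or column sums to zero")
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  ci95 <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p_chisq <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  p_fisher <- stats::fisher.test(tab)$p.value
  list(or = or, ci95 = ci95, p_chisq = p_chisq, p_fisher = p_fisher,
       corrected = corrected, table = tab)
}
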