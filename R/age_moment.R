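# Moment estimators of founder-allele age.
#
# 1. Risch log-decay estimator: on disease chromosomes the ancestral allele
#    at a marker with recombination fraction theta survives each generation
#    with probability (1 - theta), so the LD index decays as
#    delta(g) = (1 - theta)^g and g = log(delta) / log(1 - theta).
# 2. Markov transition-matrix iteration: the per-generation transformation
#    of the marker allele on a disease chromosome is
#        K = theta * R + mu * M + (1 - theta - mu) * I
#    (recombination replaces the allele by a draw from the control
#    frequencies, a stepwise mutation moves it +/-1 repeat, otherwise it is
#    unchanged). Iterating the founder state vector through K until the
#    ancestral mass falls to the observed proportion counts generations,
#    correcting LD decay for marker mutation.

#' Convert genetic distance to recombination fraction
#'
#' @param dist_cM genetic distance(s) from the mutation in centimorgans.
#' @param map_function `"linear"` (theta = cM/100, used as-is without
#'   capping at 0.5 — the convention under which the published per-marker
#'   distances reproduce the published mean age), `"haldane"`
#'   (theta = (1 - exp(-2d))/2, d in Morgans) or `"kosambi"`
#'   (theta = tanh(2d)/2).
#' @return Recombination fraction(s).
#' @export
cm_to_theta <- function(dist_cM, map_function = c("linear", "haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(dist_cM) | dist_cM <= 0)) {
    stop("genetic distance must be positive")
  }
  d <- dist_cM / 100  # Morgans
  switch(map_function,
         linear = d,
         haldane = (1 - exp(-2 * d)) / 2,
         kosambi = tanh(2 * d) / 2)
}

#' Convert physical to genetic distance
#'
#' @param dist_bp physical distance in base pairs.
#' @param factor centimorgans per megabase (default 1.17, a genome-average
#'   sex-averaged recombination rate from the Marshfield map era).
#' @return Distance in centimorgans.
#' @export
bp_to_cm <- function(dist_bp, factor = 1.17) {
  if (any(!is.finite(dist_bp) | dist_bp < 0)) stop("distance must be non-negative")
  dist_bp * factor / 1e6
}

#' Risch moment estimator of allele age
#'
#' `g = log(delta) / log(1 - theta)`: the number of generations over which
#' complete association would decay to the observed LD index at the given
#' recombination fraction.
#'
#' @param delta Bengtsson-Thomson LD index, in (0, 1].
#' @param theta recombination fraction, in (0, 1).
#' @return Age in generations (real-valued; 0 when `delta = 1`).
#' @export
risch_age <- function(delta, theta) {
  if (any(!is.finite(delta) | delta <= 0)) {
    stop("non-informative marker: delta must be > 0")
  }
  if (any(delta > 1)) stop("delta must be <= 1")
  if (any(!is.finite(theta) | theta <= 0 | theta >= 1)) {
    stop("theta must lie strictly between 0 and 1")
  }
  log(delta) / log(1 - theta)
}

#' Aggregate per-marker ages
#'
#' @param per_marker_g numeric vector of per-marker age estimates.
#' @return list with `mean`, `sd` (n-1 denominator) and `n`.
#' @export
aggregate_moment <- function(per_marker_g) {
  g <- per_marker_g[is.finite(per_marker_g)]
  if (length(g) < 2) stop("need >= 2 finite per-marker estimates to aggregate")
  list(mean = mean(g), sd = stats::sd(g), n = length(g))
}

#' Build the per-generation transition matrix for one marker
#'
#' States are ordered repeat numbers. `R` replaces the allele by a draw
#' from the control frequencies (every row equals `control_freqs`), `M` is
#' a stepwise +/-1 mutation with probability 1/2 per direction, reflecting
#' at the boundary states so no probability mass leaves the range, and `I`
#' is the identity. `K = theta R + mu M + (1 - theta - mu) I`.
#'
#' @param states ordered integer repeat numbers.
#' @param theta recombination fraction mutation-to-marker.
#' @param mu per-meiosis stepwise mutation rate of the marker.
#' @param control_freqs probability vector over `states` (control
#'   population allele frequencies), summing to 1 within 1e-9.
#' @return Object of class `markov_model`: list with `states`, `R`, `M`,
#'   `I`, `K`, `theta`, `mu`, `control_freqs`.
#' @export
build_markov <- function(states, theta, mu, control_freqs) {
  n <- length(states)
  stopifnot(n >= 1)
  if (is.unsorted(states, strictly = TRUE)) stop("states must be strictly increasing")
  if (length(control_freqs) != n) stop("control_freqs must match states")
  if (abs(sum(control_freqs) - 1) > 1e-9 || any(control_freqs < 0)) {
    stop("control_freqs must be a probability vector (sum 1 within 1e-9)")
  }
  if (theta < 0 || mu < 0 || theta + mu > 1) stop("need theta, mu >= 0 and theta + mu <= 1")
  I <- diag(n)
  R <- matrix(rep(control_freqs, each = n), nrow = n)
  M <- matrix(0, n, n)
  if (n == 1) {
    M[1, 1] <- 1  # single state: a step has nowhere to go
  } else {
    for (i in seq_len(n)) {
      down <- i - 1; up <- i + 1
      if (down >= 1) M[i, down] <- M[i, down] + 0.5 else M[i, up] <- M[i, up] + 0.5
      if (up <= n) M[i, up] <- M[i, up] + 0.5 else M[i, down] <- M[i, down] + 0.5
    }
  }
  K <- theta * R + mu * M + (1 - theta - mu) * I
  structure(list(states = states, R = R, M = M, I = I, K = K,
                 theta = theta, mu = mu, control_freqs = control_freqs),
            class = "markov_model")
}

#' Markov transition-matrix age estimator
#'
#' Starts from a point mass on the ancestral state (split equally across a
#' multi-allele ancestral set) and multiplies by `K` until the summed mass
#' on the ancestral states falls to the observed proportion of ancestral
#' haplotypes on carrier chromosomes. The number of multiplications is the
#' age in generations.
#'
#' @param p_obs observed ancestral proportion, in (0, 1].
#' @param model a [build_markov()] model.
#' @param anc_states integer vector of ancestral repeat numbers (must be in
#'   `model$states`).
#' @param max_iter iteration cap (default 10000); if the chain's ancestral
#'   mass never reaches `p_obs` (target below the stationary mass) an error
#'   reports the value the chain levelled off at.
#' @return Integer number of generations (smallest t with ancestral mass
#'   <= `p_obs`; 0 when `p_obs = 1`).
#' @export
markov_age <- function(p_obs, model, anc_states, max_iter = 10000) {
  stopifnot(inherits(model, "markov_model"))
  if (!is.finite(p_obs) || p_obs <= 0 || p_obs > 1) stop("p_obs must lie in (0, 1]")
  idx <- match(anc_states, model$states)
  if (anyNA(idx)) stop("ancestral state(s) not in model states")
  v <- numeric(length(model$states))
  v[idx] <- 1 / length(idx)
  t <- 0L
  mass <- sum(v[idx])
  while (mass > p_obs) {
    if (t >= max_iter) {
      stop(sprintf(paste0("markov_age did not reach p_obs = %.4g within %d ",
                          "iterations; ancestral mass levelled off at %.4g ",
                          "(target below the chain's stationary mass?)"),
                   p_obs, max_iter, mass))
    }
    v <- as.numeric(v %*% model$K)
    t <- t + 1L
    mass <- sum(v[idx])
  }
  t
}

.mu_default <- function(repeat_unit) {
  # per-meiosis stepwise rates by repeat class: tetra- vs dinucleotide
  ifelse(repeat_unit >= 4, 2.1e-3, 5.6e-4)
}

.age_estimate <- function(method, per_marker, g_mean, g_sd = NA_real_,
                          ci95 = NULL, years_per_generation = 25,
                          anchor_year = 1990) {
  cal <- generations_to_calendar(g_mean, years_per_generation, anchor_year)
  structure(list(method = method,
                 g_point = g_mean,
                 g_sd = g_sd,
                 ci95 = ci95,
                 per_marker = per_marker,
                 years = cal$years,
                 date = cal$date,
                 years_sd = if (is.na(g_sd)) NA_real_ else round(g_sd * years_per_generation),
                 years_per_generation = years_per_generation,
                 anchor_year = anchor_year),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("Founder allele age (", x$method, " method)\n", sep = "")
  if (!is.na(x$g_sd)) {
    cat(sprintf("  g = %.1f +/- %.2f generations (mean +/- SD over %d markers)\n",
                x$g_point, x$g_sd, length(x$per_marker)))
  } else if (!is.null(x$ci95)) {
    cat(sprintf("  g = %d generations (95%%: %d-%d)\n",
                round(x$g_point), x$ci95[1], x$ci95[2]))
  } else {
    cat(sprintf("  g = %.1f generations (single marker, no dispersion)\n", x$g_point))
  }
  cat(sprintf("  years = %d (at %g y/generation), founder event ~ year %d\n",
              x$years, x$years_per_generation, x$date))
  invisible(x)
}

#' Moment-method age from a published delta table
#'
#' Runs the Risch estimator directly on per-marker (delta, cM) values —
#' e.g. a printed LD table — without requiring raw haplotypes.
#'
#' @param delta_table data.frame with columns `marker`, `dist_cM`, `delta`
#'   (a [compute_delta()] table joined to a map works too if `dist_cM` is
#'   present).
#' @param map_function map function for [cm_to_theta()] (default linear).
#' @param years_per_generation,anchor_year calendar conversion constants
#'   (defaults 25 and 1990).
#' @param drop_noninformative drop markers with `delta <= 0` or `NA`
#'   (with a warning) instead of erroring.
#' @return An `age_estimate`.
#' @export
moment_age_from_delta <- function(delta_table,
                                  map_function = "linear",
                                  years_per_generation = 25,
                                  anchor_year = 1990,
                                  drop_noninformative = TRUE) {
  stopifnot(all(c("marker", "dist_cM", "delta") %in% names(delta_table)))
  tab <- as.data.frame(delta_table)
  bad <- is.na(tab$delta) | tab$delta <= 0
  if (any(bad)) {
    if (!drop_noninformative) stop("non-informative delta for marker(s): ",
                                   paste(tab$marker[bad], collapse = ", "))
    warning("dropping non-informative marker(s): ",
            paste(tab$marker[bad], collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  theta <- cm_to_theta(tab$dist_cM, map_function)
  g <- risch_age(tab$delta, theta)
  names(g) <- tab$marker
  if (length(g) >= 2) {
    agg <- aggregate_moment(g)
    .age_estimate("risch", g, agg$mean, agg$sd,
                  years_per_generation = years_per_generation,
                  anchor_year = anchor_year)
  } else {
    .age_estimate("risch", g, unname(g),
                  years_per_generation = years_per_generation,
                  anchor_year = anchor_year)
  }
}

#' Moment-method age from a phased haplotype set
#'
#' End-to-end pipeline: ancestral allele-set frequencies on carrier and
#' control chromosomes, then either the Risch log-decay estimator on the
#' per-marker LD indices (`method = "risch"`) or the mutation-corrected
#' Markov transition-matrix iteration on the per-marker ancestral
#' proportions (`method = "markov"`), aggregated across informative markers
#' as mean +/- SD and converted to years and a calendar date.
#'
#' @param set a [haplotype_set()].
#' @param anc an [ancestral_haplotype()]; default [infer_ancestral()] on
#'   `set`.
#' @param method `"risch"` or `"markov"`.
#' @param map_function map function for [cm_to_theta()].
#' @param independent_only use only independent carrier chromosomes.
#' @param state_pad Markov method: pad the observed repeat range by this
#'   many steps on each side (default 2; results are insensitive to the
#'   padding because the added states start with negligible mass).
#' @param mu optional named vector of per-marker mutation rates overriding
#'   the map's `mu` column (Markov method).
#' @param years_per_generation,anchor_year calendar conversion constants.
#' @return An `age_estimate` with per-marker generations.
#' @export
moment_pipeline <- function(set, anc = infer_ancestral(set),
                            method = c("risch", "markov"),
                            map_function = "linear",
                            independent_only = TRUE,
                            state_pad = 2,
                            mu = NULL,
                            years_per_generation = 25,
                            anchor_year = 1990) {
  method <- match.arg(method)
  stopifnot(inherits(set, "haplotype_set"))
  map <- set$map
  if (method == "risch") {
    dt <- compute_delta(set, anc, independent_only = independent_only)
    dt$dist_cM <- map$dist_cM[match(dt$marker, map$marker)]
    keep <- dt$informative
    if (!any(keep)) stop("all markers non-informative (delta <= 0)")
    est <- moment_age_from_delta(dt[keep, c("marker", "dist_cM", "delta")],
                                 map_function = map_function,
                                 years_per_generation = years_per_generation,
                                 anchor_year = anchor_year)
    return(est)
  }
  # markov
  theta <- cm_to_theta(map$dist_cM, map_function)
  g <- rep(NA_real_, nrow(map))
  names(g) <- map$marker
  for (i in seq_len(nrow(map))) {
    m <- map$marker[i]
    prop <- ancestral_proportion(set, anc, m, independent_only = independent_only)
    ctrl <- allele_frequencies(set, "control", m)
    observed <- sort(unique(c(ctrl$allele, anc[[m]])))
    states <- seq(min(observed) - state_pad, max(observed) + state_pad)
    q <- numeric(length(states))
    q[match(ctrl$allele, states)] <- ctrl$freq
    mu_i <- if (!is.null(mu) && m %in% names(mu)) mu[[m]] else map$mu[i]
    model <- build_markov(states, theta[i], mu_i, q)
    g[i] <- tryCatch(markov_age(prop$p_obs, model, anc[[m]]),
                     error = function(e) {
                       warning("marker ", m, " skipped: ", conditionMessage(e))
                       NA_real_
                     })
  }
  g <- g[is.finite(g)]
  if (length(g) == 0) stop("all markers non-informative for the Markov method")
  if (length(g) >= 2) {
    agg <- aggregate_moment(g)
    .age_estimate("markov", g, agg$mean, agg$sd,
                  years_per_generation = years_per_generation,
                  anchor_year = anchor_year)
  } else {
    .age_estimate("markov", g, unname(g),
                  years_per_generation = years_per_generation,
                  anchor_year = anchor_year)
  }
}
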