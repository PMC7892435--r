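# Forward-in-time generator of founder-haplotype panels under the exact
# generative model the estimators assume (star genealogy, per-marker
# recombination fraction, stepwise STR mutation), plus a parameter-recovery
# harness.
#
# Each carrier chromosome descends from the founder through g independent
# meioses. In the default mode each marker retains the founder allele with
# probability (1 - theta_k) per meiosis, independently across markers, so
# the generator is the exact null model of every estimator in the package
# (all of them treat markers as independent given g); retained alleles take
# stepwise +/-1 mutations at rate mu_k per meiosis; lost alleles are drawn
# from the control allele-frequency distributions. The `positional` mode
# instead places a single crossover per meiosis at an exponential genetic
# distance, which makes marker survival nested within a side (the
# biologically faithful picture) and deliberately mis-specifies the
# estimators — use it to probe robustness, not calibration. Control
# chromosomes are marker-wise draws from the control distributions.

#' Default founder haplotype for a map
#'
#' A plain repeat number per marker (20 for dinucleotide loci, 13 for
#' tetranucleotide), purely a convenient anchor for simulations.
#'
#' @param map a [marker_map()].
#' @return Named integer vector, one allele per marker.
#' @export
default_founder <- function(map) {
  stats::setNames(ifelse(map$repeat_unit >= 4, 13L, 20L), map$marker)
}

#' Default control allele-frequency distributions
#'
#' A discretized triangular distribution over seven repeat numbers centred
#' two steps above the founder allele, so the mode is non-ancestral and
#' the founder allele segregates at frequency 2/16 = 0.125 among controls
#' — a realistic identity-by-state floor for an STR with heterozygosity
#' above 0.7.
#'
#' @param map a [marker_map()].
#' @param founder named founder alleles (see [default_founder()]).
#' @return Named list of named probability vectors (names = repeat
#'   numbers).
#' @export
default_control_freqs <- function(map, founder = default_founder(map)) {
  out <- lapply(map$marker, function(m) {
    mode <- founder[[m]] + 2L
    support <- (mode - 3L):(mode + 3L)
    w <- c(1, 2, 3, 4, 3, 2, 1)
    stats::setNames(w / sum(w), support)
  })
  names(out) <- map$marker
  out
}

#' Simulation configuration
#'
#' @param g_true generations since the founder event (>= 0).
#' @param map a [marker_map()].
#' @param founder named integer vector of founder alleles (singleton
#'   ancestral states), one per map marker.
#' @param control_freqs named list of per-marker allele-frequency vectors
#'   (names = repeat numbers, values summing to 1); default
#'   [default_control_freqs()].
#' @param n_carriers,n_controls chromosome counts.
#' @param mutate apply stepwise mutation at the map's per-marker `mu`
#'   (default `TRUE`; set `FALSE` for a pure-recombination null model).
#' @param map_function map function converting the map's cM distances to
#'   the per-meiosis survival probabilities (default `"linear"`, making
#'   the generator the exact null model of [risch_age()] and of the
#'   first-discordance composite likelihood).
#' @param positional if `TRUE`, place a single crossover per meiosis at an
#'   exponential genetic distance (Poisson crossover process; the founder
#'   segment survives a marker at d Morgans with per-meiosis probability
#'   exp(-d), and survival is nested within a side) instead of independent
#'   per-marker survival at 1 - theta_k; a robustness mode that
#'   deliberately mis-specifies the estimators' independence assumption.
#' @param seed RNG seed; fixed seed implies bit-reproducible output.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(g_true, map, founder = default_founder(map),
                              control_freqs = default_control_freqs(map, founder),
                              n_carriers = 30, n_controls = 100,
                              mutate = TRUE, map_function = "linear",
                              positional = FALSE, seed = 1) {
  stopifnot(inherits(map, "marker_map"))
  if (g_true < 0 || g_true != round(g_true)) stop("g_true must be a non-negative integer")
  if (!setequal(names(founder), map$marker)) stop("founder must name exactly the map markers")
  if (!setequal(names(control_freqs), map$marker)) {
    stop("control_freqs must name exactly the map markers")
  }
  for (m in map$marker) {
    q <- control_freqs[[m]]
    if (abs(sum(q) - 1) > 1e-9 || any(q < 0) || is.null(names(q))) {
      stop("control_freqs[['", m, "']] must be a named probability vector")
    }
  }
  if (n_carriers < 1 || n_controls < 0) stop("need n_carriers >= 1, n_controls >= 0")
  structure(list(g_true = as.integer(g_true), map = map,
                 founder = founder[map$marker],
                 control_freqs = control_freqs[map$marker],
                 n_carriers = as.integer(n_carriers),
                 n_controls = as.integer(n_controls),
                 mutate = isTRUE(mutate), map_function = map_function,
                 positional = isTRUE(positional), seed = as.integer(seed)),
            class = "sim_config")
}

.draw_allele <- function(freqs, n = 1) {
  as.integer(sample(names(freqs), n, replace = TRUE, prob = freqs))
}

#' Simulate a founder-haplotype panel
#'
#' @param config a [simulation_config()].
#' @return A [haplotype_set()]; carriers are tagged independent (the star
#'   genealogy has no within-family structure).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- config$map
  g <- config$g_true
  mu <- if (config$mutate) map$mu else rep(0, nrow(map))
  names(mu) <- map$marker
  sides <- lapply(.sides, function(s) {
    sm <- map_side(map, s)
    if (nrow(sm) == 0) return(NULL)
    list(markers = sm$marker,
         theta = cm_to_theta(sm$dist_cM, config$map_function),
         morgans = sm$dist_cM / 100)
  })
  names(sides) <- .sides

  sim_one_carrier <- function() {
    alleles <- integer(nrow(map))
    names(alleles) <- map$marker
    for (s in .sides) {
      sd <- sides[[s]]
      if (is.null(sd)) next
      if (g == 0) {
        survived <- rep(TRUE, length(sd$markers))
      } else if (config$positional) {
        cut <- min(stats::rexp(g))            # closest crossover, Morgans
        survived <- sd$morgans < cut
      } else {
        # independent per-marker survival (1 - theta_k)^g: the exact null
        # model of the marker-independent estimators
        survived <- stats::runif(length(sd$markers)) < (1 - sd$theta)^g
      }
      for (i in seq_along(sd$markers)) {
        m <- sd$markers[i]
        if (survived[i]) {
          a <- config$founder[[m]]
          if (g > 0 && mu[[m]] > 0) {
            nmut <- stats::rbinom(1, g, mu[[m]])
            if (nmut > 0) a <- a + sum(sample(c(-1L, 1L), nmut, replace = TRUE))
          }
          alleles[m] <- max(1L, a)
        } else {
          alleles[m] <- .draw_allele(config$control_freqs[[m]])
        }
      }
    }
    alleles
  }

  carrier_mat <- matrix(vapply(seq_len(config$n_carriers),
                               function(i) sim_one_carrier(),
                               integer(nrow(map))),
                        ncol = nrow(map), byrow = TRUE,
                        dimnames = list(NULL, map$marker))
  control_mat <- if (config$n_controls > 0) {
    vapply(map$marker,
           function(m) .draw_allele(config$control_freqs[[m]], config$n_controls),
           integer(config$n_controls))
  } else {
    matrix(integer(0), nrow = 0, ncol = nrow(map),
           dimnames = list(NULL, map$marker))
  }
  if (config$n_controls == 1) control_mat <- matrix(control_mat, nrow = 1,
                                                    dimnames = list(NULL, map$marker))
  ids_car <- sprintf("CAR%04d", seq_len(config$n_carriers))
  ids_ctl <- sprintf("CTL%04d", seq_len(config$n_controls))
  records <- data.frame(
    chrom_id = c(ids_car, ids_ctl),
    family_id = c(ids_car, ids_ctl),
    group = c(rep("carrier", config$n_carriers),
              rep("control", config$n_controls)),
    independent = TRUE,
    stringsAsFactors = FALSE)
  allele_df <- as.data.frame(rbind(carrier_mat, control_mat))
  names(allele_df) <- map$marker
  haplotype_set(map, cbind(records, allele_df))
}

#' Founder haplotype of a simulation as an ancestral haplotype
#'
#' @param config a [simulation_config()].
#' @return An [ancestral_haplotype()] of singleton sets.
#' @export
founder_ancestral <- function(config) {
  ancestral_haplotype(as.list(config$founder), config$map)
}

# one estimator applied to one simulated set; returns c(g_hat, lo, hi)
.apply_estimator <- function(estimator, set, anc, g_grid) {
  switch(estimator,
    risch = {
      est <- moment_pipeline(set, anc, method = "risch")
      c(est$g_point, NA_real_, NA_real_)
    },
    markov = {
      est <- moment_pipeline(set, anc, method = "markov")
      c(est$g_point, NA_real_, NA_real_)
    },
    mrca_mle = {
      fit <- mrca_mle(set, anc, g_grid = g_grid)
      c(fit$g_hat, fit$ci95)
    },
    bayes = {
      fit <- bayes_posterior(set, anc, config = bayes_config(g_grid = g_grid))
      c(fit$mode, fit$ci95)
    },
    stop("unknown estimator: ", estimator))
}

#' Parameter-recovery experiment
#'
#' Simulates replicate panels under each configuration, runs the requested
#' estimators, and summarizes bias, RMSE, median absolute error and 95%
#' interval coverage against the generating truth. The founder haplotype
#' is passed to the estimators as the ancestral haplotype (isolating
#' estimator error from ancestral-inference error) unless
#' `use_inferred = TRUE`.
#'
#' @param configs list of [simulation_config()] objects (their `seed`
#'   fields are ignored; replicate seeds derive from `seed`).
#' @param estimators subset of `c("risch", "markov", "mrca_mle", "bayes")`.
#' @param n_replicates replicates per configuration.
#' @param seed master seed for the experiment.
#' @param g_grid grid for the likelihood-based estimators.
#' @param use_inferred infer the ancestral haplotype from each simulated
#'   panel instead of using the generator's founder.
#' @return Object of class `recovery_report`: list with `results` (one row
#'   per config x replicate x estimator: `g_true`, `replicate`,
#'   `estimator`, `g_hat`, `lo`, `hi`, `ok`) and `summary` (per config x
#'   estimator: `n_ok`, `fail_rate`, `bias`, `rmse`, `median_abs_err`,
#'   `coverage`; coverage is `NA` for estimators without intervals).
#' @export
recovery_experiment <- function(configs, estimators = c("risch", "mrca_mle"),
                                n_replicates = 50, seed = 1, g_grid = 1:200,
                                use_inferred = FALSE) {
  estimators <- match.arg(estimators,
                          c("risch", "markov", "mrca_mle", "bayes"),
                          several.ok = TRUE)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1,
                          length(configs) * n_replicates)
  rows <- list()
  k <- 0
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (rep in seq_len(n_replicates)) {
      k <- k + 1
      cfg_rep <- cfg
      cfg_rep$seed <- rep_seeds[k]
      sim <- simulate_haplotypes(cfg_rep)
      anc <- if (use_inferred) infer_ancestral(sim) else founder_ancestral(cfg)
      for (est in estimators) {
        res <- tryCatch(
          suppressWarnings(.apply_estimator(est, sim, anc, g_grid)),
          error = function(e) c(NA_real_, NA_real_, NA_real_))
        rows[[length(rows) + 1]] <- data.frame(
          config = ci, g_true = cfg$g_true, replicate = rep, estimator = est,
          g_hat = res[1], lo = res[2], hi = res[3], ok = is.finite(res[1]))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results,
                                         list(results$config, results$estimator),
                                         drop = TRUE), function(d) {
    ok <- d[d$ok, , drop = FALSE]
    has_ci <- any(is.finite(ok$lo))
    data.frame(config = d$config[1], g_true = d$g_true[1],
               estimator = d$estimator[1],
               n_ok = nrow(ok), fail_rate = 1 - nrow(ok) / nrow(d),
               bias = mean(ok$g_hat - ok$g_true),
               rmse = sqrt(mean((ok$g_hat - ok$g_true)^2)),
               median_abs_err = stats::median(abs(ok$g_hat - ok$g_true)),
               coverage = if (has_ci)
                 mean(ok$lo <= ok$g_true & ok$g_true <= ok$hi) else NA_real_)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", length(unique(x$results$replicate)),
      "replicates:\n")
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}
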