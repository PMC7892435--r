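# 2 proximal + 3 distal map for discordance scans
disc_map <- function() {
  marker_map(data.frame(
    marker = c("p1", "p2", "d1", "d2", "d3"),
    side = c("proximal", "proximal", "distal", "distal", "distal"),
    dist_cM = c(1, 4, 0.8, 2, 5),
    repeat_unit = 2,
    mu = 5.6e-4))
}

test_that("first_discordance scans outward, skipping missing alleles", {
  map <- disc_map()
  anc <- ancestral_haplotype(list(p1 = 15, p2 = 16, d1 = c(24, 25),
                                  d2 = 11, d3 = 20), map)
  # identical to the ancestral haplotype: j = m + 1 on both sides
  rec <- list(p1 = 15, p2 = 16, d1 = 24, d2 = 11, d3 = 20)
  prof <- first_discordance(rec, anc, map)
  expect_equal(prof$distal$j, 4L)
  expect_equal(prof$proximal$j, 3L)

  # distal (24, 11, 19) vs ({24,25}, {11}, {20}): first mismatch at 3
  rec2 <- list(p1 = 15, p2 = 16, d1 = 24, d2 = 11, d3 = 19)
  expect_equal(first_discordance(rec2, anc, map)$distal$j, 3L)

  # proximal mismatch at the first marker
  rec3 <- list(p1 = 99, p2 = 16, d1 = 24, d2 = 11, d3 = 20)
  expect_equal(first_discordance(rec3, anc, map)$proximal$j, 1L)

  # missing allele is skipped, not treated as discordant
  rec4 <- list(p1 = 15, p2 = 16, d1 = NA, d2 = 11, d3 = 19)
  p4 <- first_discordance(rec4, anc, map)$distal
  expect_equal(p4$m, 2L)
  expect_equal(p4$j, 2L)            # among observed markers (d2, d3)
  expect_equal(p4$skipped, "d1")
})

test_that("sharing_probability has its closed forms and IBS floor", {
  expect_equal(sharing_probability(0.3, 0.01, 0.2, 0), 1)
  expect_equal(sharing_probability(0.01, 0, 0, 10), 0.99^10)
  expect_equal(sharing_probability(0.01, 0, 0, 10), 0.9044, tolerance = 1e-4)
  # g -> infinity: s -> f
  expect_equal(sharing_probability(0.05, 1e-3, 0.5, 5000), 0.5, tolerance = 1e-9)
  expect_error(sharing_probability(0.01, 0, 0, -1), "non-negative")
})

test_that("side_loglik matches hand values and normalizes over j", {
  # single marker with s(g) = 0.8: P(j = 1) = 0.2
  # theta = 0.2, mu = 0, f = 0, g = 1 gives s = 0.8
  expect_equal(side_loglik(1, 0.2, 0, 0, 1), log(0.2))
  expect_equal(side_loglik(2, 0.2, 0, 0, 1), log(0.8))
  # all markers shared with s = 1 (theta = mu = 0): log(1) = 0
  expect_equal(side_loglik(3, c(0, 0), c(0, 0), c(0, 0), 7), 0)

  set.seed(21)
  for (g in c(1, 5, 20)) {
    m <- 4
    theta <- sort(runif(m, 0.005, 0.3))
    mu <- runif(m, 0, 5e-3)
    f <- runif(m, 0, 0.5)
    total <- sum(vapply(1:(m + 1),
                        function(j) exp(side_loglik(j, theta, mu, f, g)),
                        numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12, info = paste("g =", g))
  }
})

test_that("degenerate likelihoods hit the grid boundaries with warnings", {
  map <- disc_map()
  anc_alleles <- c(p1 = 15L, p2 = 16L, d1 = 24L, d2 = 11L, d3 = 20L)
  anc <- ancestral_haplotype(as.list(anc_alleles), map)
  f0 <- setNames(rep(0, 5), map$marker)

  # every chromosome fully shared, f = 0: likelihood decreasing, ghat = 1
  shared <- matrix(rep(anc_alleles[map$marker], each = 4), nrow = 4)
  set <- make_set(map, shared)
  expect_warning(fit <- mrca_mle(set, anc, f = f0), "boundary")
  expect_equal(fit$g_hat, 1)

  # single distal marker, both chromosomes discordant at j = 1, theta = 0.1:
  # lnL = 2 log(1 - 0.9^g) is increasing, ghat at grid max
  map1 <- marker_map(data.frame(marker = "d1", side = "distal", dist_cM = 10,
                                repeat_unit = 2, mu = 0))
  set1 <- make_set(map1, matrix(c(30L, 31L), ncol = 1))
  anc1 <- ancestral_haplotype(list(d1 = 20), map1)
  expect_warning(fit1 <- mrca_mle(set1, anc1, f = c(d1 = 0), g_grid = 1:50),
                 "boundary")
  expect_equal(fit1$g_hat, 50)
})

test_that("mrca_mle is invariant to f = 1 markers", {
  map <- disc_map()
  set.seed(8)
  cfg <- simulation_config(g_true = 10, map = map, n_carriers = 20,
                           n_controls = 80, seed = 8)
  sim <- simulate_haplotypes(cfg)
  anc <- founder_ancestral(cfg)
  fit <- mrca_mle(sim, anc)

  # add a marker where every control carries the ancestral allele (f = 1)
  map2 <- marker_map(data.frame(
    marker = c("p1", "p2", "d1", "d2", "d3", "dup"),
    side = c("proximal", "proximal", "distal", "distal", "distal", "distal"),
    dist_cM = c(1, 4, 0.8, 2, 5, 3),
    repeat_unit = 2, mu = 5.6e-4))
  rec2 <- sim$records
  rec2$dup <- 42L
  sim2 <- haplotype_set(map2, rec2)
  anc2 <- ancestral_haplotype(c(unclass(anc), list(dup = 42)), map2)
  expect_warning(fit2 <- mrca_mle(sim2, anc2), "no information")
  expect_equal(fit2$g_hat, fit$g_hat)
  expect_equal(fit2$loglik_curve$loglik, fit$loglik_curve$loglik)
  expect_equal(fit2$ci95, fit$ci95)
})

test_that("posterior with uniform prior peaks at the MLE", {
  map <- atbp3_marker_map()
  cfg <- simulation_config(g_true = 14, map = map, n_carriers = 30,
                           n_controls = 100, seed = 13)
  sim <- simulate_haplotypes(cfg)
  anc <- founder_ancestral(cfg)
  fit <- mrca_mle(sim, anc)
  post <- bayes_posterior(sim, anc, config = bayes_config(prior = "uniform"))
  expect_equal(post$mode, fit$g_hat)
  expect_equal(sum(post$posterior$prob), 1, tolerance = 1e-12)
  expect_true(post$ci95[1] <= post$mode && post$mode <= post$ci95[2])
})

test_that("flat likelihood isolates the prior", {
  # a marker at negligible distance with mu = 0 and full sharing gives a
  # likelihood flat in g, so the posterior is the (normalized) prior
  map <- marker_map(data.frame(marker = "m", side = "distal", dist_cM = 1e-9,
                               repeat_unit = 2, mu = 0))
  set <- make_set(map, matrix(rep(20L, 4), ncol = 1),
                  matrix(c(20L, rep(25L, 9)), ncol = 1))
  anc <- ancestral_haplotype(list(m = 20), map)

  grid <- 1:100
  post_u <- bayes_posterior(set, anc,
                            config = bayes_config(prior = "uniform", g_grid = grid))
  expect_equal(post_u$posterior$prob, rep(1 / 100, 100), tolerance = 1e-6)
  expect_gte(diff(post_u$ci95) + 1, 95)  # credible set spans >= 95% of grid

  r <- 0.079
  post_g <- bayes_posterior(set, anc,
                            config = bayes_config(prior = "growth", r = r,
                                                  g_grid = grid))
  expected <- exp(-r * grid) / sum(exp(-r * grid))
  expect_equal(post_g$posterior$prob, expected, tolerance = 1e-6)
  expect_equal(post_g$mode, 1)
})

test_that("mrca_mle recovers a simulated truth (quick check)", {
  map <- atbp3_marker_map()
  cfg <- simulation_config(g_true = 14, map = map, n_carriers = 30,
                           n_controls = 100)
  rep <- recovery_experiment(list(cfg), estimators = "mrca_mle",
                             n_replicates = 20, seed = 5)
  expect_lte(rep$summary$median_abs_err, 3)
  expect_gte(rep$summary$coverage, 0.85)
})
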