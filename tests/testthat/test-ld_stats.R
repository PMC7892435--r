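test_that("allele_frequencies counts and normalizes correctly", {
  map <- toy_map()
  carriers <- matrix(rep(c(20L, 11L, 30L), each = 4), ncol = 3)
  carriers[4, 1] <- 21L  # carriers at P1: {20,20,20,21}
  controls <- matrix(rep(c(12L, 12L, 12L), each = 10), ncol = 3)
  set <- make_set(map, carriers, controls)

  ctl <- allele_frequencies(set, "control", "P1")
  expect_equal(ctl$allele, 12L)
  expect_equal(ctl$freq, 1.0)

  car <- allele_frequencies(set, "carrier", "P1")
  expect_equal(setNames(car$freq, car$allele), c("20" = 0.75, "21" = 0.25))
  expect_equal(attr(car, "n"), 4)
  expect_equal(sum(car$freq), 1)

  # all-missing group errors
  miss <- carriers; miss[, 2] <- NA
  set2 <- make_set(map, miss, controls)
  expect_error(allele_frequencies(set2, "carrier", "P2"), "no usable")
})

test_that("infer_ancestral takes modes, keeps near-ties, honors strict mode", {
  map <- toy_map()
  identical5 <- matrix(rep(c(20L, 11L, 30L), each = 5), ncol = 3)
  set <- make_set(map, identical5)
  anc <- infer_ancestral(set)
  expect_equal(anc$P1, 20L)
  expect_equal(anc$P2, 11L)
  expect_equal(anc$D1, 30L)

  # exact tie at D1 (24,24,25,25) keeps both
  tied <- matrix(c(rep(20L, 4), rep(11L, 4), 24L, 24L, 25L, 25L), ncol = 3)
  set_t <- make_set(map, tied)
  expect_equal(infer_ancestral(set_t)$D1, c(24L, 25L))
  # strict mode resolves the tie toward the smaller repeat number
  expect_equal(infer_ancestral(set_t, strict = TRUE)$D1, 24L)

  # near-tie: 5 vs 4 (>= 0.8 * 5) keeps both; 5 vs 3 does not
  near <- matrix(c(rep(20L, 9), rep(11L, 9), rep(24L, 5), rep(25L, 4)), ncol = 3)
  expect_equal(infer_ancestral(make_set(map, near))$D1, c(24L, 25L))
  far <- matrix(c(rep(20L, 8), rep(11L, 8), rep(24L, 5), rep(25L, 3)), ncol = 3)
  expect_equal(infer_ancestral(make_set(map, far))$D1, 24L)

  # only independent carriers count
  set_dep <- make_set(map, tied, carrier_independent = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(infer_ancestral(set_dep)$D1, 24L)
  expect_error(infer_ancestral(make_set(map, tied, carrier_independent = FALSE)),
               "independent")
})

test_that("infer_ancestral recovers the founder exactly at g = 0", {
  map <- atbp3_marker_map()
  for (seed in c(2, 9)) {
    cfg <- simulation_config(g_true = 0, map = map, n_carriers = 10,
                             n_controls = 50, seed = seed)
    sim <- simulate_haplotypes(cfg)
    anc <- infer_ancestral(sim)
    expect_equal(unclass(anc), lapply(as.list(cfg$founder), as.integer),
                 info = paste("seed", seed))
  }
})

test_that("compute_delta matches the Bengtsson-Thomson formula", {
  map <- toy_map()
  # carriers: 19 of 20 ancestral at P1; controls: 10 of 100
  carriers <- matrix(c(rep(20L, 19), 21L, rep(11L, 20), rep(30L, 20)), ncol = 3)
  controls <- matrix(c(rep(20L, 10), rep(25L, 90),
                       rep(11L, 10), rep(26L, 90),
                       rep(30L, 10), rep(27L, 90)), ncol = 3)
  set <- make_set(map, carriers, controls)
  anc <- ancestral_haplotype(list(P1 = 20, P2 = 11, D1 = 30), map)
  dt <- compute_delta(set, anc)
  p1 <- dt[dt$marker == "P1", ]
  expect_equal(p1$p_D, 0.95)
  expect_equal(p1$p_N, 0.10)
  expect_equal(p1$delta, 0.85 / 0.90, tolerance = 1e-12)
  expect_equal(c(p1$n_D, p1$n_N), c(20L, 100L))
  # full association: p_D = 1 gives delta = 1
  expect_equal(dt$delta[dt$marker == "P2"], 1.0)
})

test_that("delta edge cases: no association, p_N = 1, non-informative flags", {
  map <- toy_map()
  carriers <- matrix(c(rep(c(20L, 20L, 20L, 21L, 21L, 21L, 21L, 22L, 22L, 22L)),
                       rep(11L, 10), rep(30L, 10)), ncol = 3)
  controls <- matrix(c(rep(c(20L, 20L, 20L, 21L, 21L, 21L, 21L, 22L, 22L, 22L)),
                       rep(11L, 10),  # p_N = 1 at P2
                       rep(31L, 10)), ncol = 3)
  set <- make_set(map, carriers, controls)
  anc <- ancestral_haplotype(list(P1 = 20, P2 = 11, D1 = 30), map)
  expect_warning(expect_warning(dt <- compute_delta(set, anc),
                                "p_N = 1"),
                 "non-informative")
  expect_equal(dt$delta[dt$marker == "P1"], 0)     # p_D = p_N = 0.3
  expect_false(dt$informative[dt$marker == "P1"])
  expect_true(is.na(dt$delta[dt$marker == "P2"]))
})

test_that("delta is monotone in p_D and ancestral-set frequency is additive", {
  # monotonicity at fixed p_N
  p_N <- 0.2
  deltas <- vapply(seq(0.25, 1, by = 0.05),
                   function(p_D) (p_D - p_N) / (1 - p_N), numeric(1))
  expect_true(all(diff(deltas) > 0))

  # p over a set equals the sum of member-allele frequencies
  map <- toy_map()
  set.seed(31)
  carriers <- matrix(sample(24:27, 60, TRUE), ncol = 3)
  controls <- matrix(sample(24:27, 90, TRUE), ncol = 3)
  set <- make_set(map, carriers, controls)
  anc <- ancestral_haplotype(list(P1 = c(24, 25), P2 = 24, D1 = 26), map)
  dt <- suppressWarnings(compute_delta(set, anc))
  fr <- allele_frequencies(set, "carrier", "P1", independent_only = TRUE)
  expect_equal(dt$p_D[dt$marker == "P1"],
               sum(fr$freq[fr$allele %in% c(24, 25)]))
})

test_that("ancestral_proportion returns ratio with counts", {
  map <- toy_map()
  carriers <- matrix(c(rep(20L, 41), rep(23L, 3), rep(11L, 44), rep(30L, 44)),
                     ncol = 3)
  set <- make_set(map, carriers)
  anc <- ancestral_haplotype(list(P1 = 20, P2 = 11, D1 = 30), map)
  pr <- ancestral_proportion(set, anc, "P1")
  expect_equal(pr$p_obs, 41 / 44, tolerance = 1e-12)
  expect_equal(pr$count, 41)
  expect_equal(pr$n, 44)
  carriers[, 1] <- NA
  set2 <- make_set(map, carriers)
  expect_error(ancestral_proportion(set2, anc, "P1"), "non-missing")
})
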