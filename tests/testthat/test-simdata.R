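test_that("simulation config validates its inputs", {
  expect_error(sim_config(theta0 = 1, theta1 = 1), "seed")
  expect_error(sim_config(theta0 = 0, seed = 1))
  expect_error(sim_config(L = 0, seed = 1))
})

test_that("genealogies are reproducible and internally consistent", {
  cfg <- sim_config(n_per_pop = c(A = 6, B = 6), n_demes = 2, M = 1,
                    theta0 = 1, theta1 = 1, tau = 0, seed = 12)
  g1 <- simulate_genealogy(cfg)
  g2 <- simulate_genealogy(cfg)
  expect_identical(g1, g2)
  expect_equal(g1$n_tips, 12)
  expect_equal(sum(g1$parent == 0), 1)       # single root
  expect_true(all(g1$blen >= 0))
  expect_equal(g1$total_blen, sum(g1$blen))
})

test_that("pair coalescence time matches the closed form E[T2] = 1", {
  set.seed(101)
  theta <- 4
  tm <- replicate(2000, simulate_genealogy(
    list(n = 2, theta0 = theta, theta1 = theta, tau = 0))$tmrca)
  # E[T2] = 1 coalescent unit -> theta/2 mutational units per lineage
  expect_equal(mean(tm), 1, tolerance = 0.05)
  expect_equal(mean(tm) * theta / 2, theta / 2, tolerance = 0.05 * theta)
})

test_that("very high migration approaches panmixia for a pair", {
  # at M -> infinity the two demes act as one population twice the size,
  # so a pair starting apart and a pair starting together are
  # indistinguishable (diversity ratio -> 1)
  cfg_apart <- sim_config(n_per_pop = c(A = 1, B = 1), n_demes = 2,
                          M = 200, theta0 = 2, theta1 = 2, tau = 0,
                          deme_of = c(A = 1L, B = 2L), seed = 1)
  cfg_together <- sim_config(n_per_pop = c(A = 1, B = 1), n_demes = 2,
                             M = 200, theta0 = 2, theta1 = 2, tau = 0,
                             deme_of = c(A = 1L, B = 1L), seed = 1)
  apart <- vapply(1:200, function(s)
    simulate_genealogy(cfg_apart, seed = 10000 + s)$tmrca, 0)
  together <- vapply(1:200, function(s)
    simulate_genealogy(cfg_together, seed = 20000 + s)$tmrca, 0)
  expect_equal(mean(apart) / mean(together), 1, tolerance = 0.2)
  # and both match the pooled-size closed form E[T2] = 2 (units of N)
  expect_equal(mean(apart), 2, tolerance = 0.2)
})

test_that("mutation dropping respects rate and bias limits", {
  cfg <- sim_config(n_per_pop = c(A = 5), theta0 = 1e-9, theta1 = 1e-9,
                    tau = 0, L = 100, seed = 3)
  g <- simulate_genealogy(cfg)
  a <- drop_mutations(g, L = 100, kappa = 1, seed = 4)
  expect_equal(length(unique(alignment_strings(a))), 1) # ~zero mutations

  # kappa -> infinity: all observed changes are transitions
  cfg2 <- sim_config(n_per_pop = c(A = 10), theta0 = 5, theta1 = 5,
                     tau = 0, L = 200, seed = 5)
  g2 <- simulate_genealogy(cfg2)
  a2 <- drop_mutations(g2, L = 200, kappa = 1e6, seed = 6)
  st <- count_site_types(a2)
  expect_gt(st$S, 0)
  expect_equal(st$tv, 0)
})

test_that("segregating sites track total branch length", {
  # theta large enough that genealogical variance dominates the Poisson
  # mutation noise; L large enough that repeat hits barely saturate S
  set.seed(55)
  res <- t(replicate(200, {
    g <- simulate_genealogy(list(n = 8, theta0 = 10, theta1 = 10,
                                 tau = 0))
    a <- mitopop:::drop_mutations_internal(g, L = 1000, theta = 10,
                                           kappa = 1)
    c(tbl = g$total_blen, S = count_site_types(a)$S)
  }))
  expect_gt(stats::cor(res[, "tbl"], res[, "S"]), 0.9)
})

test_that("simulate_dataset is deterministic and self-consistent", {
  cfg <- sim_config(n_per_pop = c(E = 5, S = 5, W = 5), L = 100,
                    theta0 = 0.5, theta1 = 20, tau = 2, n_demes = 2,
                    M = 5, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(alignment_strings(d1$alignment),
                   alignment_strings(d2$alignment))
  expect_equal(names(d1$popmap), rownames(d1$alignment))
  expect_equal(as.integer(table(d1$popmap)), c(5L, 5L, 5L))
  expect_equal(d1$truth$tau, 2)
  expect_true(is.finite(d1$truth$tmrca))
})

test_that("study-like fixture has the study's shape", {
  ds <- make_study_like_fixture(seed = 1)
  expect_equal(n_samples(ds$alignment), 45)
  expect_equal(n_sites(ds$alignment), 473)
  expect_equal(sort(unique(unname(ds$popmap))), c("E", "S", "W"))
  expect_equal(as.integer(table(ds$popmap)), c(15L, 15L, 15L))

  # realized summaries for the default seed sit in the tuned bands
  d <- pairwise_differences(ds$alignment)
  pi <- nucleotide_diversity(ds$alignment, d)$pi
  pooled <- pool_populations(ds$popmap, list(ES = c("E", "S")))
  fst <- amova_two_level(d, pooled, n_perm = 1, seed = 1)$fst
  expect_gt(pi, 0.001); expect_lt(pi, 0.01)
  expect_gt(fst, 0.25); expect_lt(fst, 0.6)
})
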