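test_that("pairwise_differences matches per-site brute force", {
  a <- mt_alignment(c(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT"))
  d <- pairwise_differences(a)
  expect_equal(d["s1", "s3"], 0L)
  expect_equal(d["s1", "s2"], 1L)
  expect_true(isSymmetric(unname(d)))

  set.seed(9)
  for (rep in 1:10) {
    r <- random_alignment(6, 20)
    expect_equal(unclass(pairwise_differences(r)), oracle_hamming(r))
  }
})

test_that("AMOVA on fully fixed toy data attributes 100% among", {
  b <- mt_alignment(c(p1 = "AAAA", p2 = "AAAA", q1 = "TTTT", q2 = "TTTT"))
  d <- pairwise_differences(b)
  pm <- c(p1 = "P", p2 = "P", q1 = "Q", q2 = "Q")
  r <- amova_two_level(d, pm, n_perm = 200, seed = 1)
  # hand arithmetic: SSD_total = 4*16/4 = 16... within = 0
  expect_equal(r$ssd_within, 0)
  expect_equal(r$fst, 1)
  expect_equal(r$pct_among, 100)
  expect_equal(r$df_among, 1)
  expect_equal(r$df_within, 2)
})

test_that("AMOVA components match the independent oracle", {
  set.seed(21)
  for (rep in 1:10) {
    a <- random_alignment(sample(6:8, 1), 25)
    pm <- stats::setNames(
      sample(rep(c("P", "Q"), length.out = nrow(a))), rownames(a))
    d <- pairwise_differences(a)
    r <- amova_two_level(d, pm, n_perm = 1, seed = 5)
    o <- oracle_amova(d, unname(pm[rownames(d)]))
    expect_equal(r$ssd_among, o$ssd_among, tolerance = 1e-10)
    expect_equal(r$ssd_within, o$ssd_within, tolerance = 1e-10)
    expect_equal(r$sigma2_a, o$sigma2_a, tolerance = 1e-10)
    expect_equal(r$fst, o$fst, tolerance = 1e-10)
  }
})

test_that("no structure by construction gives small Phi_ST, p > 0.05", {
  cfg <- sim_config(n_per_pop = c(A = 16), theta0 = 3, theta1 = 3,
                    tau = 0, L = 300, seed = 31)
  ds <- simulate_dataset(cfg)
  set.seed(99)
  pm <- stats::setNames(sample(rep(c("P", "Q"), each = 8)),
                        rownames(ds$alignment))
  d <- pairwise_differences(ds$alignment)
  r <- amova_two_level(d, pm, n_perm = 500, seed = 17)
  expect_lt(abs(r$fst), 0.2)
  expect_gt(r$p_value, 0.05)
})

test_that("Phi_ST is invariant to label and sample order", {
  set.seed(13)
  a <- random_alignment(8, 25)
  pm <- stats::setNames(rep(c("P", "Q"), each = 4), rownames(a))
  d <- pairwise_differences(a)
  f1 <- amova_two_level(d, pm, n_perm = 1, seed = 1)$fst
  perm <- sample(rownames(a))
  f2 <- amova_two_level(d[perm, perm], pm, n_perm = 1, seed = 1)$fst
  pm_sw <- stats::setNames(ifelse(pm == "P", "Z", "A"), names(pm))
  f3 <- amova_two_level(d, pm_sw, n_perm = 1, seed = 1)$fst
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("amova_two_level at P = 2 equals pairwise_phist exactly", {
  set.seed(15)
  a <- random_alignment(10, 30)
  pm <- stats::setNames(rep(c("P", "Q"), each = 5), rownames(a))
  d <- pairwise_differences(a)
  r1 <- amova_two_level(d, pm, n_perm = 100, seed = 8)
  r2 <- pairwise_phist(d, pm, c("P", "Q"), n_perm = 100, seed = 8)
  expect_equal(r1$fst, r2$fst)
  expect_equal(r1$p_value, r2$p)
})

test_that("AMOVA input validation and degenerate cases", {
  a <- mt_alignment(c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA", s4 = "AAAA"))
  d <- pairwise_differences(a)
  pm <- c(s1 = "P", s2 = "P", s3 = "Q", s4 = "Q")
  expect_warning(r <- amova_two_level(d, pm, n_perm = 10, seed = 1),
                 "identical")
  expect_equal(r$fst, 0)
  expect_error(amova_two_level(d, c(s1 = "P", s2 = "P", s3 = "P",
                                    s4 = "Q"), n_perm = 10, seed = 1),
               ">= 2 samples")
  expect_error(amova_two_level(d, pm, n_perm = 0, seed = 1), ">= 1")
})

test_that("permutation p-values are reproducible given the seed", {
  set.seed(77)
  a <- random_alignment(10, 25)
  pm <- stats::setNames(rep(c("P", "Q"), each = 5), rownames(a))
  d <- pairwise_differences(a)
  p1 <- amova_two_level(d, pm, n_perm = 200, seed = 4)$p_value
  p2 <- amova_two_level(d, pm, n_perm = 200, seed = 4)$p_value
  expect_identical(p1, p2)
})

test_that("gene_flow implements Wright's transformation and grading", {
  expect_equal(gene_flow(0.5), list(nm = 0.5, category = "medium"))
  expect_equal(gene_flow(1.0), list(nm = 0.0, category = "low"))
  g <- gene_flow(0.4557)
  expect_equal(g$nm, 0.597, tolerance = 1e-3)
  expect_equal(g$category, "medium")
  expect_equal(gene_flow(0.2)$category, "high")
  expect_error(gene_flow(0), "fst <= 0")
  expect_error(gene_flow(1.2), "domain|outside")

  # inverse identity: fst = 1/(2 nm + 1) recovers input
  for (fst in c(0.01, 0.1, 0.4557, 0.9, 1)) {
    nm <- gene_flow(fst)$nm
    expect_equal(1 / (2 * nm + 1), fst, tolerance = 1e-12)
  }
})

test_that("phist_matrix fills a symmetric matrix with p-values", {
  set.seed(5)
  a <- random_alignment(12, 30)
  pm <- stats::setNames(rep(c("E", "S", "W"), each = 4), rownames(a))
  d <- pairwise_differences(a)
  fm <- phist_matrix(d, pm, n_perm = 50, seed = 2)
  expect_equal(fm$populations, c("E", "S", "W"))
  expect_equal(fm$fst["E", "S"], fm$fst["S", "E"])
  expect_true(all(fm$p[upper.tri(fm$p)] >= 0 & fm$p[upper.tri(fm$p)] <= 1))
})
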