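mini_ht <- function(seqs, pops = NULL) {
  ids <- paste0("s", seq_along(seqs))
  if (is.null(pops)) pops <- rep("p", length(seqs))
  a <- mt_alignment(stats::setNames(seqs, ids))
  collapse_haplotypes(a, stats::setNames(pops, ids))
}

test_that("MSN basic topologies", {
  # two haplotypes at distance 1: single edge
  n1 <- minimum_spanning_network(mini_ht(c("AAA", "AAT")))
  expect_equal(nrow(n1$edges), 1)
  expect_equal(n1$edges$weight, 1)

  # distances 1,1,2: path of two weight-1 edges, weight-2 edge excluded
  n2 <- minimum_spanning_network(mini_ht(c("AAA", "ATA", "AAC")))
  expect_equal(nrow(n2$edges), 2)
  expect_true(all(n2$edges$weight == 1))

  # mutual distance 1 (triangle of ties): all three edges retained
  n3 <- minimum_spanning_network(mini_ht(c("AAT", "AAC", "AAG")))
  expect_equal(nrow(n3$edges), 3)
})

test_that("MSN edge set matches the minimax-path oracle", {
  set.seed(41)
  for (rep in 1:10) {
    a <- random_alignment(sample(4:6, 1), 12)
    ht <- collapse_haplotypes(
      a, stats::setNames(rep("p", nrow(a)), rownames(a)))
    if (length(ht$sequences) < 2) next
    net <- minimum_spanning_network(ht)
    got <- net$edges[, c("from", "to", "weight")]
    ora <- oracle_msn_edges(unname(ht$sequences))
    ora$from <- names(ht$sequences)[ora$from]
    ora$to <- names(ht$sequences)[ora$to]
    key <- function(df) sort(paste(df$from, df$to, df$weight))
    expect_equal(key(got), key(ora))
  }
})

test_that("median joining adds no vector when the median is observed", {
  mj <- median_joining(mini_ht(c("AAA", "ATA", "AAC")))
  expect_equal(sum(mj$nodes$kind == "median_vector"), 0)
  expect_equal(nrow(mj$nodes), 3)
})

test_that("two haplotypes two steps apart stay a single weight-2 edge", {
  mj <- median_joining(mini_ht(c("AA", "TT")))
  expect_equal(nrow(mj$nodes), 2)
  expect_equal(mj$edges$weight, 2)
  expect_equal(mj$edges$positions, "1,2")
})

test_that("median vectors connect distant triplets", {
  # three haplotypes pairwise 2 apart around the unobserved center AAA
  mj <- median_joining(mini_ht(c("TTA", "GAC", "ACA")))
  meds <- mj$nodes$sequence[mj$nodes$kind == "median_vector"]
  hull <- oracle_qm_hull(c("TTA", "GAC", "ACA"))
  expect_true(all(meds %in% hull))
  # every observed haplotype still present exactly once
  expect_equal(sum(mj$nodes$kind == "observed"), 3)
})

test_that("MJN keeps observed nodes connected at epsilon = 0", {
  set.seed(43)
  for (rep in 1:5) {
    a <- random_alignment(6, 10)
    ht <- collapse_haplotypes(
      a, stats::setNames(rep("p", nrow(a)), rownames(a)))
    mj <- median_joining(ht)
    g <- as_igraph(mj)
    expect_true(igraph::is_connected(g))
    meds <- mj$nodes$sequence[mj$nodes$kind == "median_vector"]
    if (length(meds)) {
      expect_true(all(meds %in% oracle_qm_hull(unname(ht$sequences))))
    }
  }
})

test_that("duplicating a haplotype changes frequencies, not topology", {
  ht1 <- mini_ht(c("AAA", "ATA", "AAC"))
  ht2 <- mini_ht(c("AAA", "AAA", "ATA", "AAC"))
  n1 <- median_joining(ht1); n2 <- median_joining(ht2)
  key <- function(net) {
    e <- net$edges
    s <- net$nodes$sequence[match(e$from, net$nodes$node_id)]
    t <- net$nodes$sequence[match(e$to, net$nodes$node_id)]
    sort(paste(pmin(s, t), pmax(s, t), e$weight))
  }
  expect_equal(key(n1), key(n2))
  expect_equal(sum(n2$nodes$frequency), 4)
})

test_that("network export round-trips and rejects unknown formats", {
  net <- median_joining(mini_ht(c("AAA", "ATA", "AAC"),
                                pops = c("E", "E", "W")))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "edge_tsv")
  back <- read_network_tsv(f)
  expect_equal(back$nodes$sequence, net$nodes$sequence)
  expect_equal(back$edges$weight, net$edges$weight)
  expect_equal(back$edges$positions, net$edges$positions)

  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, g, "graphml")
  expect_true(file.size(g) > 0)
  expect_error(export_network(net, f, "dot"), "arg")

  # single-node network exports cleanly
  one <- minimum_spanning_network(mini_ht("AAA"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  export_network(one, f1, "edge_tsv")
  b1 <- read_network_tsv(f1)
  expect_equal(nrow(b1$nodes), 1)
  expect_equal(nrow(b1$edges), 0)
})
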