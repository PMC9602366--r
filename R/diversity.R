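# Molecular diversity indices. Variance formulas follow Nei (1987):
# eq. 8.12 for haplotype diversity, eq. 10.7 for nucleotide diversity
# (total variance including the stochastic term).

#' Haplotype (gene) diversity with standard error
#'
#' Nei's unbiased estimator \eqn{h = n/(n-1) (1 - \sum p_i^2)} with its
#' sampling variance (Nei 1987, eq. 8.12):
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   (\sum p_i^2)^2\right] + \sum p_i^2 - (\sum p_i^2)^2\right\}}
#'
#' @param counts Integer vector of haplotype counts (any order).
#' @param n Sample size; defaults to `sum(counts)`.
#' @return List with `h` and `se_h`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  if (sum(counts) != n) stop("counts must sum to n", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, se_h = sqrt(max(v, 0)))
}

#' Pairwise Hamming distances on analyzed sites
#'
#' @param a A masked [mt_alignment].
#' @return Symmetric integer matrix of pairwise nucleotide difference
#'   counts with zero diagonal, labelled by sample id.
#' @export
pairwise_differences <- function(a) {
  m <- unclass(a)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  # one indicator matrix per base keeps this vectorized at 473 sites
  acc <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    acc <- acc + tcrossprod(ind)
  }
  d[] <- as.integer(round(ncol(m) - acc))
  diag(d) <- 0L
  d
}

#' Nucleotide diversity with standard error
#'
#' \eqn{\pi} is the mean number of pairwise differences per site,
#' \eqn{\hat k / L}. The total sampling variance follows Nei (1987,
#' eq. 10.7): \eqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}
#' {9n(n-1)}\pi^2}.
#'
#' @param a A masked [mt_alignment] (or any object accepted by
#'   [pairwise_differences()]).
#' @param d Optional precomputed distance matrix.
#' @return List with `pi`, `se_pi` and `k_hat` (mean pairwise differences
#'   per sequence).
#' @export
nucleotide_diversity <- function(a, d = NULL) {
  n <- nrow(a)
  L <- ncol(a)
  if (n < 2) stop("nucleotide diversity undefined for n < 2", call. = FALSE)
  if (is.null(d)) d <- pairwise_differences(a)
  k_hat <- sum(d[upper.tri(d)]) / choose(n, 2)
  pi <- k_hat / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, se_pi = sqrt(max(v, 0)), k_hat = k_hat)
}

#' Classify polymorphic sites into transitions and transversions
#'
#' Every polymorphic column contributes one count per observed unordered
#' state pair: `A/G` and `C/T` are transitions, the other four pairs are
#' transversions. A biallelic column therefore contributes exactly one
#' count; a triallelic column contributes three.
#'
#' @param a A masked [mt_alignment].
#' @return List with `S` (number of segregating sites), `ti`, `tv`, and
#'   `positions` (1-based analyzed-coordinate indices of polymorphic
#'   columns).
#' @export
count_site_types <- function(a) {
  m <- unclass(a)
  ti <- 0L; tv <- 0L; seg <- integer(0)
  transitions <- c("A|G", "C|T")
  for (j in seq_len(ncol(m))) {
    st <- sort(unique(m[, j]))
    st <- st[st %in% c("A", "C", "G", "T")]
    if (length(st) < 2) next
    seg <- c(seg, j)
    prs <- utils::combn(st, 2)
    for (k in seq_len(ncol(prs))) {
      pair <- paste(prs[, k], collapse = "|")
      if (pair %in% transitions) ti <- ti + 1L else tv <- tv + 1L
    }
  }
  list(S = length(seg), ti = ti, tv = tv, positions = seg)
}

#' Per-population diversity summary
#'
#' Computes, for each population (and optionally the pooled total), the
#' sample size, haplotype count, haplotype diversity and nucleotide
#' diversity with standard errors, segregating sites, mean pairwise
#' differences, and transition/transversion site counts.
#'
#' @param a A masked [mt_alignment].
#' @param pm Population map (see [match_popmap()]).
#' @param total Also include a pooled `Total` row? Default `TRUE`.
#' @return `data.frame` with one row per population.
#' @export
diversity_table <- function(a, pm, total = TRUE) {
  pm <- match_popmap(a, pm)
  pops <- sort(unique(unname(pm)))
  groups <- lapply(pops, function(p) names(pm)[pm == p])
  names(groups) <- pops
  if (total && length(pops) > 1) groups$Total <- names(pm)
  rows <- lapply(names(groups), function(g) {
    sub <- subset_alignment(a, groups[[g]])
    ht <- collapse_haplotypes(sub, stats::setNames(rep("x", nrow(sub)),
                                                   rownames(sub)))
    hd <- haplotype_diversity(as.vector(ht$counts))
    nd <- nucleotide_diversity(sub)
    st <- count_site_types(sub)
    data.frame(population = g, n = nrow(sub),
               nh = length(ht$sequences),
               h = hd$h, se_h = hd$se_h,
               pi = nd$pi, se_pi = nd$se_pi,
               k_hat = nd$k_hat, S = st$S, ti = st$ti, tv = st$tv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
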