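# Distance-based AMOVA (Excoffier, Smouse & Quattro 1992) with pairwise
# nucleotide differences used as squared Euclidean distances, the
# formulation behind Arlequin's Phi-ST for sequence data; studies often
# print this statistic simply as "F_ST".

amova_ssd <- function(d2, idx_list) {
  # SSD of a group = sum of squared distances over pairs / group size
  vapply(idx_list, function(ix) {
    if (length(ix) < 2) return(0)
    sub <- d2[ix, ix, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(ix)
  }, 0)
}

amova_components <- function(d2, pop) {
  pops <- unique(pop)
  P <- length(pops)
  N <- length(pop)
  idx <- lapply(pops, function(p) which(pop == p))
  ssd_within <- sum(amova_ssd(d2, idx))
  ssd_total <- amova_ssd(d2, list(seq_len(N)))
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1
  df_within <- N - P
  sizes <- lengths(idx)
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  sigma2_w <- ssd_within / df_within
  sigma2_a <- (ssd_among / df_among - sigma2_w) / n_bar
  denom <- sigma2_a + sigma2_w
  fst <- if (denom > 0) sigma2_a / denom else 0
  list(df_among = df_among, df_within = df_within,
       ssd_among = ssd_among, ssd_within = ssd_within, ssd_total = ssd_total,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w, n_bar = n_bar, fst = fst)
}

#' Two-level AMOVA with permutation test
#'
#' Decomposes molecular variance among and within populations from a
#' matrix of pairwise nucleotide differences (treated as squared
#' distances), yielding the fixation index \eqn{\Phi_{ST} =
#' \sigma^2_a / (\sigma^2_a + \sigma^2_w)}. Significance is assessed by
#' permuting individuals among populations holding sample sizes fixed; the
#' p-value uses the \eqn{(x+1)/(n+1)} estimator with ties counted as
#' extreme (`>=` observed). Negative variance components are retained, so
#' \eqn{\Phi_{ST}} may be slightly negative; reports do not clamp.
#'
#' @param d Symmetric matrix of pairwise difference counts
#'   ([pairwise_differences()]).
#' @param pm Population map restricted to the rows of `d`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed (required, logged in the result).
#' @return List of class `amova_result`: degrees of freedom, sums of
#'   squared deviations, variance components `sigma2_a`/`sigma2_w`,
#'   percentages, `fst`, `p_value`, `n_perm`, `seed`.
#' @export
amova_two_level <- function(d, pm, n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_perm < 1) stop("permutation count must be >= 1", call. = FALSE)
  ids <- rownames(d)
  pop <- unname(pm[ids])
  if (any(is.na(pop))) stop("unassigned samples in distance matrix",
                            call. = FALSE)
  sizes <- table(pop)
  if (length(sizes) < 2) stop("need >= 2 populations", call. = FALSE)
  if (any(sizes < 2)) stop("every population needs >= 2 samples",
                           call. = FALSE)
  if (all(d == 0)) {
    warning("all sequences identical; Phi_ST reported as 0")
    obs <- amova_components(d, pop)
    obs$fst <- 0
  } else {
    obs <- amova_components(d, pop)
  }
  rng <- local_rng(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pop)
    if (amova_components(d, perm)$fst >= obs$fst) hits <- hits + 1L
  }
  restore_rng(rng)
  tot <- obs$sigma2_a + obs$sigma2_w
  structure(c(obs, list(
    pct_among = 100 * obs$sigma2_a / tot,
    pct_within = 100 * obs$sigma2_w / tot,
    p_value = (hits + 1) / (n_perm + 1),
    n_perm = n_perm, seed = seed,
    populations = names(sizes))), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", paste(x$populations, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  among:  df=%d  SSD=%.3f  sigma2=%.4f  (%.2f%%)\n",
              x$df_among, x$ssd_among, x$sigma2_a, x$pct_among))
  cat(sprintf("  within: df=%d  SSD=%.3f  sigma2=%.4f  (%.2f%%)\n",
              x$df_within, x$ssd_within, x$sigma2_w, x$pct_within))
  cat(sprintf("  Phi_ST = %.4f   p = %.4g  (%d permutations)\n",
              x$fst, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise Phi-ST between two populations
#'
#' [amova_two_level()] restricted to one pair of labels.
#'
#' @inheritParams amova_two_level
#' @param pair Character vector of two population labels.
#' @return List with `fst` and `p`.
#' @export
pairwise_phist <- function(d, pm, pair, n_perm = 10000, seed) {
  stopifnot(length(pair) == 2)
  ids <- names(pm)[pm %in% pair]
  res <- amova_two_level(d[ids, ids, drop = FALSE], pm[ids],
                         n_perm = n_perm, seed = seed)
  list(fst = res$fst, p = res$p_value)
}

#' All pairwise Phi-ST values and p-values
#'
#' @inheritParams amova_two_level
#' @return List of class `fst_matrix` with `populations`, symmetric `fst`
#'   matrix and `p` matrix (diagonal `NA`).
#' @export
phist_matrix <- function(d, pm, n_perm = 10000, seed) {
  pops <- sort(unique(unname(pm[rownames(d)])))
  k <- length(pops)
  fst <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  prs <- utils::combn(pops, 2)
  for (i in seq_len(ncol(prs))) {
    pr <- prs[, i]
    # independent sub-seed per pair keeps results order-invariant
    r <- pairwise_phist(d, pm, pr, n_perm = n_perm,
                        seed = sub_seed(seed, i))
    fst[pr[1], pr[2]] <- fst[pr[2], pr[1]] <- r$fst
    p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- r$p
  }
  structure(list(populations = pops, fst = fst, p = p), class = "fst_matrix")
}

#' Gene flow from a fixation index
#'
#' Wright's island-model transformation \eqn{Nm = (1/F_{ST} - 1)/2},
#' graded as high (\eqn{\ge 1.0}), medium (0.250--0.99) or low
#' (0.0--0.249).
#'
#' @param fst Fixation index in (0, 1].
#' @return List with `nm` and `category`.
#' @export
gene_flow <- function(fst) {
  if (!is.finite(fst) || fst <= 0) {
    stop("gene flow undefined for fst <= 0 (infinite migration)",
         call. = FALSE)
  }
  if (fst > 1) stop("fst > 1 is outside the domain", call. = FALSE)
  nm <- (1 / fst - 1) / 2
  category <- if (nm >= 1.0) "high" else if (nm >= 0.250) "medium" else "low"
  list(nm = nm, category = category)
}
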