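# Neutrality tests: Tajima's D (Tajima 1989) and Fu's Fs (Fu 1997) with
# significance from constant-size coalescent simulation (lower tail, as
# both statistics flag population growth through negative values).

#' Tajima (1989) normalizing constants
#'
#' @param n Sample size (>= 4).
#' @return List of `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires n >= 4", call. = FALSE)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

tajima_d_from_summary <- function(n, S, k_hat) {
  cst <- tajima_constants(n)
  (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' \eqn{D = (\hat k - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} contrasting the
#' pairwise-difference and segregating-sites estimators of \eqn{\theta}.
#' Optionally attaches a simulated lower-tail p-value from a constant-size
#' neutral coalescent null conditioned on `n` and the observed \eqn{\hat k}.
#'
#' @param a A masked [mt_alignment].
#' @param n_sims Coalescent replicates for the p-value; `0` skips it.
#' @param seed RNG seed (required when `n_sims > 0`).
#' @return List of class `tajima_d`: `n`, `S`, `k_hat`, the constants, `D`,
#'   and (when simulated) `p_value` and `significant` (p < 0.05).
#' @export
tajimas_d <- function(a, n_sims = 0, seed = NULL) {
  n <- nrow(a)
  st <- count_site_types(a)
  S <- st$S
  if (S < 1) stop("Tajima's D undefined with no segregating sites",
                  call. = FALSE)
  nd <- nucleotide_diversity(a)
  D <- tajima_d_from_summary(n, S, nd$k_hat)
  out <- c(list(n = n, S = S, k_hat = nd$k_hat, D = D),
           tajima_constants(n))
  if (n_sims > 0) {
    p <- neutrality_significance("D", n = n, theta = nd$k_hat,
                                 observed = D, L = ncol(a),
                                 n_sims = n_sims, seed = seed)
    out$p_value <- p
    out$significant <- p < 0.05
  }
  structure(out, class = "tajima_d")
}

#' @export
print.tajima_d <- function(x, ...) {
  cat(sprintf("Tajima's D = %.4f  (n = %d, S = %d, k_hat = %.3f)\n",
              x$D, x$n, x$S, x$k_hat))
  if (!is.null(x$p_value))
    cat(sprintf("  simulated p = %.4g%s\n", x$p_value,
                if (isTRUE(x$significant)) "  (significant at 0.05)" else ""))
  invisible(x)
}

#' Ewens sampling formula: distribution of the number of alleles
#'
#' \eqn{\Pr(K = k) = |S_1(n,k)|\,\theta^k / \theta_{(n)}} where
#' \eqn{|S_1|} are unsigned Stirling numbers of the first kind and
#' \eqn{\theta_{(n)} = \theta(\theta+1)\cdots(\theta+n-1)}. Computed in log
#' space via the recurrence \eqn{|S_1(n,k)| = |S_1(n-1,k-1)| +
#' (n-1)|S_1(n-1,k)|} so that n = 45 and beyond do not overflow.
#'
#' @param n Sample size (>= 1).
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities over K = 1..n (sums to 1).
#' @export
ewens_pmf <- function(n, theta) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ls <- log_stirling1(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(logp - max(logp))
  p / sum(p)
}

# log |S1(n, k)| for k = 1..n by the standard triangular recurrence,
# carried in log space with log1p-style accumulation
log_stirling1 <- function(n) {
  prev <- 0 # log|S1(1,1)|
  if (n == 1) return(prev)
  for (m in 2:n) {
    cur <- numeric(m)
    # k = 1: |S1(m,1)| = (m-1)!
    cur[1] <- prev[1] + log(m - 1)
    if (m > 2) {
      k <- 2:(m - 1)
      a <- prev[k - 1]                      # |S1(m-1,k-1)|
      b <- log(m - 1) + prev[k]             # (m-1)|S1(m-1,k)|
      hi <- pmax(a, b)
      cur[k] <- hi + log1p(exp(pmin(a, b) - hi))
    }
    cur[m] <- 0 # |S1(m,m)| = 1
    prev <- cur
  }
  prev
}

#' Fu's Fs
#'
#' With \eqn{\hat\theta = \hat k} (the mean pairwise differences), let
#' \eqn{S' = \Pr(K \ge k_0 \mid \hat\theta, n)} under the Ewens sampling
#' formula, where \eqn{k_0} is the observed number of haplotypes. Then
#' \eqn{F_s = \ln(S' / (1 - S'))}. Large negative values indicate an
#' excess of haplotypes, as expected after population expansion.
#' Significance (convention: p < 0.02) can be attached by coalescent
#' simulation.
#'
#' @inheritParams tajimas_d
#' @return List of class `fu_fs`: `n`, `k0`, `theta_hat`, `s_prime`, `fs`,
#'   and (when simulated) `p_value` and `significant` (p < 0.02).
#' @export
fus_fs <- function(a, n_sims = 0, seed = NULL) {
  n <- nrow(a)
  if (n < 2) stop("Fu's Fs requires n >= 2", call. = FALSE)
  nd <- nucleotide_diversity(a)
  ht <- collapse_haplotypes(a, stats::setNames(rep("x", n), rownames(a)))
  k0 <- length(ht$sequences)
  fs <- fs_from_summary(n, k0, nd$k_hat)
  out <- list(n = n, k0 = k0, theta_hat = nd$k_hat,
              s_prime = fs$s_prime, fs = fs$fs)
  if (n_sims > 0) {
    p <- neutrality_significance("Fs", n = n, theta = nd$k_hat,
                                 observed = fs$fs, L = ncol(a),
                                 n_sims = n_sims, seed = seed)
    out$p_value <- p
    out$significant <- p < 0.02
  }
  structure(out, class = "fu_fs")
}

fs_from_summary <- function(n, k0, k_hat) {
  if (k_hat <= 0) stop("Fu's Fs undefined for monomorphic data (k_hat = 0)",
                       call. = FALSE)
  pmf <- ewens_pmf(n, k_hat)
  s_prime <- sum(pmf[k0:n])
  if (s_prime >= 1 || s_prime <= 0) {
    if (k0 == 1) stop("degenerate: single haplotype with k_hat > 0",
                      call. = FALSE)
    s_prime <- min(max(s_prime, .Machine$double.xmin), 1 - 1e-16)
  }
  list(s_prime = s_prime, fs = log(s_prime / (1 - s_prime)))
}

#' @export
print.fu_fs <- function(x, ...) {
  cat(sprintf("Fu's Fs = %.4f  (n = %d, k0 = %d, theta_hat = %.3f)\n",
              x$fs, x$n, x$k0, x$theta_hat))
  if (!is.null(x$p_value))
    cat(sprintf("  simulated p = %.4g%s\n", x$p_value,
                if (isTRUE(x$significant)) "  (significant at 0.02)" else ""))
  invisible(x)
}

#' Simulated significance for a neutrality statistic
#'
#' Simulates a constant-size neutral coalescent sample of size `n` with
#' scaled mutation parameter `theta` (finite sites of length `L`), computes
#' the chosen statistic for each replicate, and returns the lower-tail
#' p-value \eqn{\Pr(stat_{sim} \le stat_{obs})}.
#'
#' @param stat `"D"` or `"Fs"`.
#' @param n Sample size.
#' @param theta Scaled mutation parameter of the null.
#' @param observed Observed statistic value.
#' @param L Sequence length for the finite-sites simulation.
#' @param n_sims Number of replicates (>= 100 recommended; >= 1 required).
#' @param seed RNG seed (required).
#' @return Lower-tail p-value.
#' @export
neutrality_significance <- function(stat = c("D", "Fs"), n, theta, observed,
                                    L = 473, n_sims = 1000, seed) {
  stat <- match.arg(stat)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  hits <- 0L
  used <- 0L
  for (b in seq_len(n_sims)) {
    g <- simulate_genealogy(list(n = n, theta0 = theta, theta1 = theta,
                                 tau = 0))
    sim <- drop_mutations_internal(g, L = L, theta = theta, kappa = 1)
    val <- tryCatch({
      if (stat == "D") {
        st <- count_site_types(sim)
        if (st$S < 1) NA_real_
        else tajima_d_from_summary(n, st$S,
                                   nucleotide_diversity(sim)$k_hat)
      } else {
        nd <- nucleotide_diversity(sim)
        if (nd$k_hat <= 0) NA_real_
        else {
          k0 <- length(unique(alignment_strings(sim)))
          fs_from_summary(n, k0, nd$k_hat)$fs
        }
      }
    }, error = function(e) NA_real_)
    if (!is.na(val)) {
      used <- used + 1L
      if (val <= observed) hits <- hits + 1L
    }
  }
  if (used == 0L) return(NA_real_)
  hits / used
}
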