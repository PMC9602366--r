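# Mismatch distributions and the sudden-expansion model of Rogers &
# Harpending (1992). The model: a population at equilibrium theta0
# instantaneously grows to theta1 at mutational time tau before present;
# the distribution of pairwise differences j is
#   F_j = Fhat_j(theta1) + exp(-tau (theta1+1)/theta1) *
#         sum_{i=0..j} tau^i/i! * (Fhat_{j-i}(theta0) - Fhat_{j-i}(theta1))
# with the equilibrium geometric law Fhat_j(theta) = theta^j/(theta+1)^(j+1).

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all within-subset pairs.
#'
#' @param d Pairwise difference matrix ([pairwise_differences()]).
#' @param members Sample ids to include (default: all rows of `d`).
#' @return List of class `mismatch_distribution` with `counts` (named
#'   vector indexed `"0"..."j_max"`, including zero cells) and `n_pairs`.
#' @export
observed_mismatch <- function(d, members = rownames(d)) {
  if (length(members) < 2) stop("need >= 2 members", call. = FALSE)
  sub <- d[members, members, drop = FALSE]
  diffs <- sub[upper.tri(sub)]
  j_max <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = j_max + 1L)
  names(counts) <- 0:j_max
  structure(list(counts = counts, n_pairs = length(diffs)),
            class = "mismatch_distribution")
}

# log-space: theta^j/(theta+1)^(j+1) overflows double at j ~ hundreds
equilibrium_mismatch <- function(theta, j) {
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' @param tau Mutational time since expansion (>= 0).
#' @param theta0 Pre-expansion scaled mutation parameter (> 0).
#' @param theta1 Post-expansion scaled mutation parameter (> 0).
#' @param j_max Largest difference count to evaluate.
#' @return Numeric vector `F_0..F_{j_max}`; the (small) truncation mass
#'   `1 - sum` is available as `attr(, "truncation")`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, j_max) {
  if (theta0 <= 0 || theta1 <= 0) stop("theta must be > 0", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  j <- 0:j_max
  f0 <- equilibrium_mismatch(theta0, j)
  f1 <- equilibrium_mismatch(theta1, j)
  # log-space Poisson weights; exp factor folded in to avoid overflow at
  # large tau
  lw <- -tau * (theta1 + 1) / theta1 + j * log(max(tau, .Machine$double.xmin)) -
    lgamma(j + 1)
  if (tau == 0) lw <- c(0, rep(-Inf, j_max))
  w <- exp(lw)
  delta <- f0 - f1
  conv <- vapply(j, function(jj) sum(w[1:(jj + 1)] * delta[(jj + 1):1]), 0)
  out <- f1 + conv
  out[out < 0] <- 0
  attr(out, "truncation") <- max(0, 1 - sum(out))
  out
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations between observed relative pair
#' frequencies and the model probabilities over \eqn{(\tau, \theta_0,
#' \theta_1)} by multi-start Nelder-Mead refinement of a coarse grid
#' (parameters optimized on log/sqrt transformed scales within bounds).
#' Deterministic given `seed`. Ties are broken by lowest SSD, then lowest
#' \eqn{\tau}.
#'
#' @param mm A `mismatch_distribution` from [observed_mismatch()].
#' @param bounds List with elements `tau`, `theta0`, `theta1`, each
#'   `c(lo, hi)`. Defaults: tau in \[0, 50\], theta0 in \[1e-6, 50\],
#'   theta1 in \[1e-6, 20000\] (theta1 additionally constrained >= theta0).
#' @param n_starts Number of random multi-starts beyond the grid (default
#'   20).
#' @param seed RNG seed for the random starts.
#' @return List of class `expansion_fit`: `tau`, `theta0`, `theta1`,
#'   `ssd`, `converged`, `bounds_hit` (named logical vector).
#' @export
fit_expansion <- function(mm,
                          bounds = list(tau = c(0, 50),
                                        theta0 = c(1e-6, 50),
                                        theta1 = c(1e-6, 20000)),
                          n_starts = 20, seed = 1) {
  obs <- mm$counts / mm$n_pairs
  j_max <- length(obs) - 1L
  ssd_fun <- function(par) {
    tau <- par[1]; th0 <- par[2]; th1 <- par[3]
    if (tau < bounds$tau[1] || tau > bounds$tau[2] ||
        th0 < bounds$theta0[1] || th0 > bounds$theta0[2] ||
        th1 < bounds$theta1[1] || th1 > bounds$theta1[2] || th1 < th0)
      return(1e9)
    f <- expected_mismatch(tau, th0, th1, j_max)
    sum((obs - f)^2)
  }
  # transform: tau raw, thetas on log scale for the optimizer
  to_t <- function(p) c(p[1], log(p[2]), log(p[3]))
  from_t <- function(t) c(t[1], exp(t[2]), exp(t[3]))
  obj <- function(t) ssd_fun(from_t(t))

  k_bar <- sum(as.numeric(names(mm$counts)) * obs)
  grid <- expand.grid(tau = unique(pmin(bounds$tau[2],
                                        c(0.5, 1, 2, k_bar, 2 * k_bar + 1))),
                      theta0 = c(1e-4, 0.1, 1),
                      theta1 = c(1, 10, 100, 5000))
  rng <- local_rng(seed)
  extra <- data.frame(
    tau = stats::runif(n_starts, bounds$tau[1], min(bounds$tau[2], 4 * k_bar + 1)),
    theta0 = exp(stats::runif(n_starts, log(bounds$theta0[1]), log(bounds$theta0[2]))),
    theta1 = exp(stats::runif(n_starts, 0, log(bounds$theta1[2]))))
  restore_rng(rng)
  starts <- rbind(grid, extra)
  starts$theta1 <- pmax(starts$theta1, starts$theta0)

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    fit <- tryCatch(
      stats::optim(to_t(st), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    cand <- list(par = from_t(fit$par), ssd = fit$value,
                 converged = fit$convergence == 0)
    if (is.null(best) || cand$ssd < best$ssd - 1e-15 ||
        (abs(cand$ssd - best$ssd) <= 1e-15 && cand$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) stop("non-convergence: all optimizer starts failed",
                          call. = FALSE)
  par <- best$par
  tol <- 1e-6
  bh <- c(tau = par[1] <= bounds$tau[1] + tol || par[1] >= bounds$tau[2] - tol,
          theta0 = par[2] <= bounds$theta0[1] * (1 + 1e-3) ||
            par[2] >= bounds$theta0[2] * (1 - 1e-3),
          theta1 = par[3] <= bounds$theta1[1] * (1 + 1e-3) ||
            par[3] >= bounds$theta1[2] * (1 - 1e-3))
  structure(list(tau = par[1], theta0 = par[2], theta1 = par[3],
                 ssd = best$ssd, converged = any_conv, bounds_hit = bh),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau = %.3f, theta0 = %.4f, theta1 = %.3f (SSD = %.3g)\n",
              x$tau, x$theta0, x$theta1, x$ssd))
  if (any(x$bounds_hit))
    cat("  bound saturated:", paste(names(x$bounds_hit)[x$bounds_hit],
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Convert an expansion time tau to calendar years
#'
#' Uses \eqn{\tau = 2ut} with the per-sequence per-year rate \eqn{u = L r},
#' where `r` is the sequence divergence rate per site per year used
#' directly (e.g. 3.6% per million years = 3.6e-8). Hence
#' \eqn{t = \tau / (2 L r)}.
#'
#' @param tau Mutational time since expansion (>= 0).
#' @param L Number of sites.
#' @param rate_per_site_per_year Divergence rate r (> 0), default 3.6e-8.
#' @return List with `t_years`, `tau`, `L`, `rate_per_site_per_year`, `u`.
#' @export
expansion_time <- function(tau, L, rate_per_site_per_year = 3.6e-8) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (rate_per_site_per_year <= 0) stop("rate must be > 0", call. = FALSE)
  u <- L * rate_per_site_per_year
  list(t_years = tau / (2 * u), tau = tau, L = L,
       rate_per_site_per_year = rate_per_site_per_year, u = u)
}
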